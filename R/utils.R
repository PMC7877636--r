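# Internal helpers shared across modules.

# Deterministic child seeds: fold/repeat/restart streams are derived from one
# master seed so that reports are reproducible run-to-run. Values stay well
# below .Machine$integer.max.
derive_seed <- function(master_seed, offset) {
  (as.integer(master_seed) %% 1000003L) * 2017L + as.integer(offset) * 7919L
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into k folds, so class proportions are preserved up to
# integer rounding. Returns an integer fold id per sample.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Mann-Whitney AUC with explicit positive class; ties count one half.
# pROC is used for the same quantity in the CV harness; this closed form
# backs the monotone-invariance property and orientation checks.
rank_auc <- function(scores, positive) {
  stopifnot(any(positive), any(!positive))
  r <- rank(scores)
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

format_score <- function(x) sprintf("%.12g", x)
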
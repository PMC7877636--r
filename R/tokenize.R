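#' Quantize expression profiles into class-annotated tokens
#'
#' Each gene's profile is standardized to zero mean and unit variance over
#' samples, then every sample is assigned one of `quantization_levels` bins
#' using global equal-frequency edges computed on the pooled standardized
#' values of all genes. A token is the pair (bin, sample condition), giving
#' a vocabulary of `2 * quantization_levels` tokens; the count matrix
#' n(gene, token) is the low-dimensional descriptor the topic model is
#' fitted on. Constant (zero-variance) genes put all their mass in the
#' middle bin and are flagged with a message.
#'
#' @param dataset An [expression_dataset()] (TPM recommended) containing
#'   both tumor and normal samples.
#' @param quantization_levels Number of bins Q (default 6, so 12 tokens).
#' @param pseudocount Added before the log2 transform of abundances.
#' @return A `token_counts`: list with `features` (gene ids), `vocabulary`
#'   (tibble of `bin`, `class`), and `counts` (genes x tokens integer
#'   matrix; every row sums to the number of samples).
#' @export
tokenize_features <- function(dataset, quantization_levels = 6,
                              pseudocount = 1) {
  q_lev <- as.integer(quantization_levels)
  stopifnot(q_lev >= 2)
  cond <- dataset$meta$condition
  if (length(unique(cond)) < 2) {
    abort("tokenization needs both tumor and normal samples")
  }
  x <- log2(dataset$values + pseudocount)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  constant <- sdv == 0
  if (any(constant)) {
    inform(paste0(sum(constant), " constant gene(s): mass placed in middle bin"))
    sdv[constant] <- 1
  }
  z <- (x - mu) / sdv
  edges <- if (all(constant)) {
    seq(-1, 1, length.out = q_lev - 1)
  } else {
    quantile(as.vector(z[!constant, , drop = FALSE]),
             probs = seq_len(q_lev - 1) / q_lev, names = FALSE, type = 7)
  }
  bins <- matrix(findInterval(z, edges) + 1L, nrow = nrow(z))
  middle <- as.integer(ceiling(q_lev / 2))
  bins[constant, ] <- middle
  vocab <- tidyr::expand_grid(bin = seq_len(q_lev),
                              class = c("normal", "tumor"))
  cls_idx <- ifelse(cond == "tumor", 2L, 1L)
  tok <- sweep((bins - 1L) * 2L, 2, cls_idx, "+")
  counts <- vapply(seq_len(2L * q_lev),
                   function(t) rowSums(tok == t), numeric(nrow(z)))
  counts <- matrix(as.integer(counts), nrow(z), nrow(vocab),
                   dimnames = list(rownames(dataset$values),
                                   paste0("bin", vocab$bin, "_", vocab$class)))
  structure(list(features = rownames(dataset$values), vocabulary = vocab,
                 counts = counts),
            class = "token_counts")
}

#' @export
print.token_counts <- function(x, ...) {
  cat(sprintf("<token_counts> %d features x %d tokens (m = %d samples)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts[1, ])))
  invisible(x)
}
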
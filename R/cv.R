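#' Repeated, rebalanced cross-validated classification of top-ranked genes
#'
#' Measures the predictive value of the leading `top_k` genes of a ranking.
#' Per repeat: samples are split into stratified folds; within each fold
#' iteration the training folds are rebalanced with ADASYN
#' ([adasyn_oversample()]) — synthetic records never enter a test fold —
#' features are standardized with training-fold statistics, a linear
#' soft-margin SVM (cost `svm_c`) is fitted, and the untouched test fold is
#' scored. A repeat's AUC and F1 are the means over its folds; AUC uses the
#' SVM decision values oriented so that larger means tumor, F1 treats tumor
#' as the positive class at the decision threshold 0.
#'
#' Classification should be run on samples never used for feature
#' selection; pass the validation partition.
#'
#' @param dataset An [expression_dataset()] (FPKM is converted to TPM;
#'   classification uses log2(TPM + 1)).
#' @param ranking A `gene_ranking` from [rank_features()] (or a character
#'   vector of genes, best first).
#' @param top_k Number of leading genes to use (default 100; capped at the
#'   ranking length).
#' @param folds Number of CV folds (default 5).
#' @param repeats Number of CV repetitions (default 100).
#' @param seed Master seed; per-repeat seeds are derived from it.
#' @param svm_c Soft-margin cost of the linear SVM (default 1).
#' @param adasyn_k,adasyn_beta ADASYN neighborhood size and balance target
#'   passed to [adasyn_oversample()].
#' @return An `evaluation_report`: list with `per_repeat` (tibble of
#'   `repeat`, `auc`, `f1`), `mean_auc`, `mean_f1`, and `config`.
#' @export
run_cv_evaluation <- function(dataset, ranking, top_k = 100, folds = 5,
                              repeats = 100, seed = 1, svm_c = 1,
                              adasyn_k = 5, adasyn_beta = 1.0) {
  genes <- if (is.data.frame(ranking)) ranking$gene else as.character(ranking)
  top <- head(genes, top_k)
  tpm <- fpkm_to_tpm(dataset)
  x <- t(log2(tpm$values[top, , drop = FALSE] + 1))
  y <- factor(tpm$meta$condition, levels = c("normal", "tumor"))
  if (nlevels(droplevels(y)) < 2) abort("evaluation needs both classes")
  per_repeat <- purrr::map_dfr(seq_len(repeats), function(rep_i) {
    res <- cv_one_repeat(x, y, folds, derive_seed(seed, rep_i), svm_c,
                         adasyn_k, adasyn_beta, retry = TRUE)
    tibble::tibble(`repeat` = rep_i, auc = res$auc, f1 = res$f1)
  })
  structure(list(
    per_repeat = per_repeat,
    mean_auc = mean(per_repeat$auc),
    mean_f1 = mean(per_repeat$f1),
    config = list(top_k = length(top), folds = folds, repeats = repeats,
                  svm_c = svm_c, adasyn_k = adasyn_k,
                  adasyn_beta = adasyn_beta, seed = seed)),
    class = "evaluation_report")
}

cv_one_repeat <- function(x, y, folds, seed, svm_c, adasyn_k, adasyn_beta,
                          retry) {
  fold_id <- stratified_folds(as.character(y), folds, seed)
  if (any(tapply(as.character(y), fold_id, function(l) length(unique(l))) < 2)) {
    if (retry) {
      return(cv_one_repeat(x, y, folds, seed + 104729L, svm_c, adasyn_k,
                           adasyn_beta, retry = FALSE))
    }
    abort("a CV fold contains a single class even after re-seeding")
  }
  fold_auc <- numeric(folds)
  fold_f1 <- numeric(folds)
  for (f in seq_len(folds)) {
    test_idx <- which(fold_id == f)
    train_idx <- which(fold_id != f)
    train <- tibble::as_tibble(as.data.frame(x[train_idx, , drop = FALSE]))
    train$label <- as.character(y[train_idx])
    balanced <- suppressMessages(
      adasyn_oversample(train, label_col = "label", k_neighbors = adasyn_k,
                        beta = adasyn_beta, seed = derive_seed(seed, f)))
    # synthetic records exist only in the training table; the test fold is
    # indexed straight from the original matrix
    stopifnot(all(!balanced$.synthetic[seq_along(train_idx)]))
    xb <- as.matrix(balanced[, colnames(x), drop = FALSE])
    yb <- factor(balanced$label, levels = levels(y))
    centers <- colMeans(xb)
    scales <- apply(xb, 2, sd)
    scales[scales == 0] <- 1
    xb_s <- scale(xb, center = centers, scale = scales)
    xt_s <- scale(x[test_idx, , drop = FALSE], center = centers,
                  scale = scales)
    fit <- e1071::svm(xb_s, yb, kernel = "linear", cost = svm_c,
                      scale = FALSE)
    pred <- stats::predict(fit, xt_s, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    score <- if (grepl("^tumor", colnames(dv)[1])) dv[, 1] else -dv[, 1]
    y_test <- y[test_idx]
    roc_obj <- pROC::roc(response = y_test, predictor = as.numeric(score),
                         levels = c("normal", "tumor"), direction = "<",
                         quiet = TRUE)
    fold_auc[f] <- as.numeric(pROC::auc(roc_obj))
    pred_pos <- score > 0
    tp <- sum(pred_pos & y_test == "tumor")
    fp <- sum(pred_pos & y_test == "normal")
    fn <- sum(!pred_pos & y_test == "tumor")
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    fold_f1[f] <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
  }
  list(auc = mean(fold_auc), f1 = mean(fold_f1))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> %d repeats x %d-fold CV on top %d genes\n",
    x$config$repeats, x$config$folds, x$config$top_k))
  cat(sprintf("  mean AUC %.4f  mean F1 %.4f\n", x$mean_auc, x$mean_f1))
  invisible(x)
}

#' Per-repeat AUC and F1 of an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return The `per_repeat` tibble.
#' @export
tidy.evaluation_report <- function(x, ...) x$per_repeat

#' One-row summary of an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return Tibble with `mean_auc`, `mean_f1`, `repeats`, `folds`, `top_k`.
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(mean_auc = x$mean_auc, mean_f1 = x$mean_f1,
                 repeats = x$config$repeats, folds = x$config$folds,
                 top_k = x$config$top_k)
}

#' Plot the AUC distribution across CV repeats
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot violin/box plot of per-repeat AUCs.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- object$per_repeat
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$auc)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "per-repeat AUC") +
    ggplot2::theme_minimal()
}

#' Write an evaluation report as TSV
#'
#' Per-repeat rows followed by commented summary lines; identical config
#' and seed give a byte-identical file.
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("repeat\tauc\tf1", con)
  with(report$per_repeat, writeLines(
    sprintf("%d\t%s\t%s", `repeat`, format_score(auc), format_score(f1)),
    con))
  writeLines(sprintf("# mean_auc\t%s", format_score(report$mean_auc)), con)
  writeLines(sprintf("# mean_f1\t%s", format_score(report$mean_f1)), con)
  cfg <- report$config
  writeLines(sprintf("# config\t%s", paste(
    sprintf("%s=%s", names(cfg), unlist(cfg)), collapse = " ")), con)
  invisible(path)
}
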
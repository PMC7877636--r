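#' Per-gene paired t-test between tumor and normal samples
#'
#' For every paired patient the tumor-minus-normal difference of
#' log2(TPM + pseudocount) is formed; each gene is tested with a two-sided
#' one-sample t-test on those differences (df = number of pairs - 1).
#' The log2 fold change is the mean of the per-pair log differences —
#' consistent with the statistic being tested — and p-values are adjusted
#' across genes by the Benjamini-Hochberg step-up procedure.
#'
#' Genes whose pair differences have zero variance are flagged: their
#' p-value is 0 when the mean difference is non-zero (the effect is exact)
#' and 1 otherwise.
#'
#' @param dataset An [expression_dataset()]; FPKM input is converted to TPM
#'   first. At least two paired patients are required.
#' @param pseudocount Added before the log2 transform (default 1).
#' @param log_transform Test log2(TPM + pseudocount) (default) or raw TPM.
#' @return A `differential_result` tibble with columns `gene`,
#'   `t_statistic`, `p_value`, `q_value`, `log2_fold_change` and `n_pairs`,
#'   in the dataset's gene order.
#' @export
paired_t_test <- function(dataset, pseudocount = 1, log_transform = TRUE) {
  tpm <- fpkm_to_tpm(dataset)
  patients <- paired_patients(tpm)
  if (length(patients) < 2) {
    abort("paired t-test needs at least 2 paired patients")
  }
  meta <- tpm$meta
  # explicit pair lookup: one tumor and one normal column per patient
  tum <- vapply(patients, function(p) {
    meta$sample_id[meta$patient_id == p & meta$condition == "tumor"]
  }, character(1))
  nor <- vapply(patients, function(p) {
    meta$sample_id[meta$patient_id == p & meta$condition == "normal"]
  }, character(1))
  x <- tpm$values
  if (log_transform) x <- log2(x + pseudocount)
  diffs <- x[, tum, drop = FALSE] - x[, nor, drop = FALSE]
  n <- length(patients)
  m <- rowMeans(diffs)
  s <- apply(diffs, 1, sd)
  t_stat <- m / (s / sqrt(n))
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  degenerate <- s == 0
  if (any(degenerate)) {
    inform(paste0(sum(degenerate),
                  " gene(s) with zero variance of pair differences"))
    t_stat[degenerate] <- ifelse(m[degenerate] != 0, Inf, 0)
    p[degenerate] <- ifelse(m[degenerate] != 0, 0, 1)
  }
  out <- tibble::tibble(
    gene = rownames(x),
    t_statistic = unname(t_stat),
    p_value = unname(p),
    q_value = unname(p.adjust(p, method = "BH")),
    log2_fold_change = unname(m),
    n_pairs = n)
  class(out) <- c("differential_result", class(out))
  out
}

#' Select differential genes by FDR and fold-change cut-offs
#'
#' Keeps genes with `q_value < fdr_cutoff` and `|log2_fold_change| >
#' lfc_cutoff`; both inequalities are strict. Optionally caps the selection
#' at the `max_genes` smallest q-values.
#'
#' @param result A `differential_result` from [paired_t_test()].
#' @param fdr_cutoff BH-adjusted significance cut-off (default 0.05).
#' @param lfc_cutoff Absolute log2 fold-change cut-off (default 1).
#' @param max_genes Optional cap on the number of selected genes.
#' @return Character vector of selected gene ids (dataset order).
#' @export
select_differential_genes <- function(result, fdr_cutoff = 0.05,
                                      lfc_cutoff = 1, max_genes = NULL) {
  hits <- result |>
    dplyr::filter(.data$q_value < fdr_cutoff,
                  abs(.data$log2_fold_change) > lfc_cutoff)
  if (!is.null(max_genes) && nrow(hits) > max_genes) {
    hits <- hits |>
      dplyr::arrange(.data$q_value, dplyr::desc(abs(.data$t_statistic))) |>
      dplyr::slice_head(n = max_genes)
    hits <- hits[order(match(hits$gene, result$gene)), ]
  }
  if (nrow(hits) == 0) inform("no genes pass the differential screen")
  hits$gene
}
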
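#' Convert raw read counts to FPKM
#'
#' FPKM_i = N_i / (M * L_i) * 1e9, where N_i is the read count of gene i,
#' L_i its length in base pairs (sum of exon lengths) and M the total number
#' of reads mapped to protein-coding genes. The 1e9 scalar accounts for the
#' kilobase and per-million-mapped-reads units.
#'
#' @param read_counts Non-negative numeric vector of per-gene read counts.
#' @param gene_lengths_bp Positive numeric vector of gene lengths (bp).
#' @param total_mapped_reads Single positive number M.
#' @return Numeric vector of FPKM values, names carried over.
#' @export
counts_to_fpkm <- function(read_counts, gene_lengths_bp, total_mapped_reads) {
  stopifnot(length(read_counts) == length(gene_lengths_bp),
            length(total_mapped_reads) == 1, total_mapped_reads > 0)
  if (any(gene_lengths_bp <= 0)) {
    abort("gene lengths must be positive (zero-length gene present)")
  }
  if (any(read_counts < 0)) abort("read counts must be non-negative")
  read_counts / (total_mapped_reads * gene_lengths_bp) * 1e9
}

#' Convert FPKM to TPM
#'
#' Per sample j, TPM_ij = FPKM_ij / sum_k FPKM_kj * 1e6, so every sample
#' column sums to one million and abundances are comparable across samples.
#' The transform is invariant to rescaling any sample's FPKM column by a
#' positive constant.
#'
#' @param fpkm Either a genes x samples numeric matrix of FPKM values or an
#'   [expression_dataset()] in FPKM units.
#' @return Same shape as the input: a TPM matrix, or an `expression_dataset`
#'   tagged with TPM units.
#' @export
fpkm_to_tpm <- function(fpkm) {
  if (inherits(fpkm, "expression_dataset")) {
    if (fpkm$units == "TPM") return(fpkm)
    out <- fpkm
    out$values <- fpkm_to_tpm(fpkm$values)
    out$units <- "TPM"
    return(out)
  }
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0)) abort("FPKM values must be non-negative")
  totals <- colSums(fpkm)
  zero <- which(totals == 0)
  if (length(zero) > 0) {
    abort(paste0("all-zero expression in sample(s): ",
                 paste(colnames(fpkm)[zero] %||% zero, collapse = ", ")))
  }
  sweep(fpkm, 2, totals, "/") * 1e6
}
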
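#' Construct an expression dataset
#'
#' Bundles a gene x sample abundance matrix with per-sample metadata
#' (patient pairing and tumor/normal condition). This is the container every
#' analysis step consumes; build it directly from in-memory objects or via
#' [read_expression()].
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique rownames (gene symbols) and colnames (sample ids). All entries
#'   must be finite and non-negative.
#' @param meta Data frame with one row per sample and columns `sample_id`,
#'   `patient_id`, `condition` (`"tumor"` or `"normal"`, case-insensitive).
#'   An optional `partition` column tags samples as `"selection"` or
#'   `"validation"`.
#' @param units Abundance units of `values`, `"FPKM"` or `"TPM"`.
#'
#' @return An `expression_dataset`: a list with elements `values` (matrix),
#'   `meta` (tibble, ordered as the matrix columns) and `units`.
#' @export
expression_dataset <- function(values, meta, units = c("FPKM", "TPM")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  meta <- tibble::as_tibble(meta)
  required <- c("sample_id", "patient_id", "condition")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("expression matrix must have gene rownames and sample colnames")
  }
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g) > 0) {
    abort(paste0("duplicate gene identifier(s): ", paste(dup_g, collapse = ", ")))
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s) > 0) {
    abort(paste0("duplicate sample identifier(s): ", paste(dup_s, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) {
    abort(paste0("duplicate sample identifier(s) in metadata: ",
                 paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
                       collapse = ", ")))
  }
  if (!is.numeric(values)) {
    abort("expression values must be numeric")
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-finite or negative expression value at gene '%s', sample '%s'",
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  }
  meta$condition <- tolower(as.character(meta$condition))
  bad_cond <- setdiff(unique(meta$condition), c("tumor", "normal"))
  if (length(bad_cond) > 0) {
    abort(paste0("condition must be 'tumor' or 'normal', got: ",
                 paste(bad_cond, collapse = ", ")))
  }
  # keep samples present in both objects; matrix header fixes the order
  shared <- intersect(colnames(values), meta$sample_id)
  dropped <- setdiff(union(colnames(values), meta$sample_id), shared)
  if (length(dropped) > 0) {
    inform(paste0("dropping ", length(dropped),
                  " sample(s) absent from matrix or metadata: ",
                  paste(dropped, collapse = ", ")))
  }
  if (length(shared) == 0) abort("no samples shared between matrix and metadata")
  values <- values[, shared, drop = FALSE]
  meta <- meta[match(shared, meta$sample_id), , drop = FALSE]
  rownames(values) <- toupper(rownames(values))
  structure(list(values = values, meta = meta, units = units),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$units))
  cat(sprintf("  tumor: %d  normal: %d  paired patients: %d\n",
              sum(x$meta$condition == "tumor"),
              sum(x$meta$condition == "normal"),
              length(paired_patients(x))))
  invisible(x)
}

#' Patients with exactly one tumor and one normal sample
#'
#' @param dataset An [expression_dataset()].
#' @return Character vector of patient ids with a complete tumor/normal pair.
#' @export
paired_patients <- function(dataset) {
  m <- dataset$meta
  tab <- table(m$patient_id, m$condition)
  conds <- colnames(tab)
  ok <- rep(TRUE, nrow(tab))
  for (cond in c("tumor", "normal")) {
    ok <- ok & if (cond %in% conds) tab[, cond] == 1 else FALSE
  }
  rownames(tab)[ok]
}

#' Per-sample metadata as a tibble
#'
#' @param x An `expression_dataset`.
#' @param ... Unused.
#' @return A tibble with one row per sample.
#' @export
tidy.expression_dataset <- function(x, ...) {
  x$meta
}

#' Restrict an expression dataset to a subset of genes and/or samples
#'
#' @param dataset An [expression_dataset()].
#' @param genes Optional character vector of gene ids to keep (order kept).
#' @param samples Optional character vector of sample ids to keep.
#' @param partition Optional partition tag (`"selection"` or `"validation"`);
#'   requires a `partition` column in the metadata.
#' @return A smaller `expression_dataset`.
#' @export
filter_dataset <- function(dataset, genes = NULL, samples = NULL,
                           partition = NULL) {
  values <- dataset$values
  meta <- dataset$meta
  if (!is.null(partition)) {
    if (!"partition" %in% names(meta)) {
      abort("dataset metadata has no 'partition' column")
    }
    samples <- intersect(samples %||% meta$sample_id,
                         meta$sample_id[meta$partition == partition])
  }
  if (!is.null(samples)) {
    keep <- intersect(colnames(values), samples)
    values <- values[, keep, drop = FALSE]
    meta <- meta[match(keep, meta$sample_id), , drop = FALSE]
  }
  if (!is.null(genes)) {
    genes <- toupper(genes)
    missing_g <- setdiff(genes, rownames(values))
    if (length(missing_g) > 0) {
      abort(paste0("gene(s) not in dataset: ", paste(head(missing_g, 5),
                                                     collapse = ", ")))
    }
    values <- values[genes, , drop = FALSE]
  }
  structure(list(values = values, meta = meta, units = dataset$units),
            class = "expression_dataset")
}
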
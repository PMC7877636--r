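#' Read an expression matrix and its sample metadata
#'
#' The matrix file is tab-separated with genes in rows: first column `gene`,
#' header row of sample ids, non-negative numeric abundances (FPKM or TPM).
#' The metadata file is tab-separated with columns `sample_id`, `patient_id`,
#' `condition` and, optionally, `partition`. Samples present in only one of
#' the two files are dropped with a message; the matrix header fixes the
#' sample order. Gene symbols are upper-cased so they match interaction
#' networks and oncogene lists.
#'
#' @param matrix_path Path to the expression TSV.
#' @param metadata_path Path to the metadata TSV.
#' @param units Abundance units of the matrix, `"FPKM"` (default) or `"TPM"`.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, metadata_path, units = "FPKM") {
  mat_df <- readr::read_tsv(matrix_path, show_col_types = FALSE,
                            progress = FALSE)
  if (ncol(mat_df) < 2) abort("expression matrix needs a gene column plus samples")
  genes <- as.character(mat_df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    abort(paste0("duplicate gene identifier(s): ", paste(dup, collapse = ", ")))
  }
  values <- as.matrix(mat_df[, -1, drop = FALSE])
  if (!is.numeric(values)) {
    bad <- which(is.na(suppressWarnings(apply(mat_df[, -1], 2, as.numeric))),
                 arr.ind = TRUE)
    loc <- if (length(bad) > 0) {
      sprintf(" (row %d, column '%s')", bad[1, 1], colnames(mat_df)[-1][bad[1, 2]])
    } else ""
    abort(paste0("non-numeric expression value", loc))
  }
  rownames(values) <- genes
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  expression_dataset(values, meta, units = units)
}

#' Read a functional-interaction network edge list
#'
#' Parses a Reactome-FI-style tab-separated file with header columns `Gene1`,
#' `Gene2` and a direction column (`Direction`, `Annotation` or the third
#' column). Direction tokens are reduced to three classes: a token with only
#' a right-pointing arrowhead (`->`, `-|`) is `forward`, only a left-pointing
#' one (`<-`, `|-`) is `backward`, and tokens with both arrowheads or none
#' (`<->`, `|-|`, `<-|`, `|->`, `-`) are `bidirectional`. Activating and
#' inhibiting arrowheads are treated identically: only direction is kept.
#' Self-edges are removed and duplicate records for the same unordered gene
#' pair are merged (directions OR-ed, so `forward` + `backward` becomes
#' `bidirectional`).
#'
#' @param path Path to the network TSV.
#' @return A `fi_network`: a tibble with columns `gene_a`, `gene_b`,
#'   `direction` (one row per unordered pair, `gene_a < gene_b`).
#' @export
read_fi_network <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("Gene1", "Gene2")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("network file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dir_col <- intersect(c("Direction", "direction", "Annotation"), names(df))
  dir_raw <- if (length(dir_col) > 0) {
    df[[dir_col[1]]]
  } else if (ncol(df) >= 3) {
    df[[3]]
  } else {
    rep("-", nrow(df))
  }
  fi_network(tibble::tibble(
    gene_a = toupper(df$Gene1),
    gene_b = toupper(df$Gene2),
    direction = vapply(dir_raw, classify_direction, character(1),
                       USE.NAMES = FALSE)
  ))
}

# Map an arrow token to forward / backward / bidirectional.
classify_direction <- function(token) {
  token <- trimws(token)
  right <- grepl(">", token, fixed = TRUE) ||
    grepl("-\\|$", token) || grepl("-\\|;", token)
  left <- grepl("<", token, fixed = TRUE) || grepl("^\\|-", token)
  if (!grepl("^[<>|;-]+$", token)) {
    abort(paste0("unrecognized direction token: '", token, "'"))
  }
  if (right && !left) "forward"
  else if (left && !right) "backward"
  else "bidirectional"
}

#' Construct a functional-interaction network from an edge tibble
#'
#' Normalizes an edge list to one record per unordered gene pair: self-edges
#' are dropped, pairs are ordered lexicographically (flipping the direction
#' when the pair is swapped), and duplicate records are merged by OR-ing
#' their directions.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `direction`.
#' @return A `fi_network` tibble.
#' @export
fi_network <- function(edges) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("gene_a", "gene_b", "direction") %in% names(edges)))
  bad <- setdiff(unique(edges$direction),
                 c("forward", "backward", "bidirectional"))
  if (length(bad) > 0) {
    abort(paste0("unknown direction class: ", paste(bad, collapse = ", ")))
  }
  edges <- dplyr::filter(edges, .data$gene_a != .data$gene_b)
  swap <- edges$gene_a > edges$gene_b
  if (any(swap)) {
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
    edges$direction[swap] <- dplyr::case_match(
      edges$direction[swap],
      "forward" ~ "backward", "backward" ~ "forward",
      .default = "bidirectional")
  }
  edges <- edges |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(
      direction = if (dplyr::n_distinct(.data$direction) == 1) {
        .data$direction[1]
      } else "bidirectional",
      .groups = "drop") |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  class(edges) <- c("fi_network", class(edges))
  edges
}

#' Node degrees of an interaction network
#'
#' Degree counts distinct interaction partners, so a bidirectional edge
#' contributes one to each endpoint.
#'
#' @param network A `fi_network` (see [read_fi_network()]).
#' @return A tibble with columns `gene` and `degree`, degree descending.
#' @export
network_degrees <- function(network) {
  tibble::tibble(gene = c(network$gene_a, network$gene_b)) |>
    dplyr::count(.data$gene, name = "degree") |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$gene)
}

#' Read a plain-text gene list
#'
#' One symbol per line; `#` starts a comment; blank lines are skipped;
#' symbols are upper-cased and de-duplicated.
#'
#' @param path Path to the list file.
#' @return Character vector of unique upper-cased gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  genes <- unique(toupper(lines[nzchar(lines)]))
  if (length(genes) == 0) warn(paste0("gene list '", path, "' is empty"))
  genes
}

#' Write a gene ranking to a TSV file
#'
#' Columns `rank`, `gene`, `score`, `origin`, `isolated`; scores are printed
#' with 12 significant digits so the file round-trips losslessly through
#' [read_ranking()].
#'
#' @param ranking A `gene_ranking` tibble from [rank_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(nrow(ranking) > 0)
  out <- data.frame(rank = ranking$rank, gene = ranking$gene,
                    score = format_score(ranking$score),
                    origin = ranking$origin,
                    isolated = tolower(as.character(ranking$isolated)))
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE),
    error = function(e) abort(paste0("cannot write ranking to '", path, "': ",
                                     conditionMessage(e))))
  invisible(path)
}

#' Read a gene ranking written by [write_ranking()]
#'
#' @param path Path to a ranking TSV.
#' @return A `gene_ranking` tibble.
#' @export
read_ranking <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = "icdcl")
  class(df) <- c("gene_ranking", class(df))
  df
}
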
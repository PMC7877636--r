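#' Select hub genes by interaction-network degree
#'
#' Hubs are genes with strictly more than `min_degree` distinct interaction
#' partners; they are central nodes that connect paths through the network
#' even when not differentially expressed themselves.
#'
#' @param network A `fi_network` (see [read_fi_network()]).
#' @param min_degree Strict degree threshold (default 100).
#' @return Character vector of hub gene ids.
#' @export
select_hub_genes <- function(network, min_degree = 100) {
  deg <- network_degrees(network)
  deg$gene[deg$degree > min_degree]
}

#' Combine differential and hub genes into a candidate set
#'
#' The candidate set T is the union of the differential genes (N) and the
#' network hubs (M); each gene is tagged with its origin.
#'
#' @param differential_genes Character vector (the N genes).
#' @param hub_genes Character vector (the M genes).
#' @return A `candidate_set` tibble with columns `gene` and
#'   `origin` in `{differential, hub, both}`, differential-first order.
#' @export
candidate_set <- function(differential_genes, hub_genes) {
  differential_genes <- toupper(differential_genes)
  hub_genes <- toupper(hub_genes)
  genes <- c(differential_genes, setdiff(hub_genes, differential_genes))
  out <- tibble::tibble(
    gene = genes,
    origin = dplyr::case_when(
      genes %in% differential_genes & genes %in% hub_genes ~ "both",
      genes %in% differential_genes ~ "differential",
      TRUE ~ "hub"))
  class(out) <- c("candidate_set", class(out))
  out
}

#' Reconstruct the interaction network over a candidate gene set
#'
#' Builds the binary directed adjacency A_F over the candidate order: an
#' edge (a, b) is retained only when both endpoints are candidates. A
#' forward edge sets A_F[a, b] = 1, a backward edge A_F[b, a] = 1 and a
#' bidirectional edge both. The diagonal is always zero.
#'
#' @param network A `fi_network`.
#' @param candidates A `candidate_set` (or character vector of genes).
#' @return A `network_mask`: list with `genes` (character) and `matrix`
#'   (binary, genes x genes, dimnames set).
#' @export
reconstruct_network <- function(network, candidates) {
  genes <- if (is.data.frame(candidates)) candidates$gene else toupper(candidates)
  stopifnot(length(genes) > 0, !anyDuplicated(genes))
  a_f <- matrix(0, length(genes), length(genes),
                dimnames = list(genes, genes))
  keep <- network$gene_a %in% genes & network$gene_b %in% genes
  kept <- network[keep, , drop = FALSE]
  for (k in seq_len(nrow(kept))) {
    i <- kept$gene_a[k]
    j <- kept$gene_b[k]
    if (kept$direction[k] %in% c("forward", "bidirectional")) a_f[i, j] <- 1
    if (kept$direction[k] %in% c("backward", "bidirectional")) a_f[j, i] <- 1
  }
  if (sum(a_f) == 0) {
    warn("no interaction edges retained within the candidate set")
  }
  structure(list(genes = genes, matrix = a_f), class = "network_mask")
}

#' @export
print.network_mask <- function(x, ...) {
  cat(sprintf("<network_mask> %d genes, %d directed arcs\n",
              length(x$genes), sum(x$matrix)))
  invisible(x)
}
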
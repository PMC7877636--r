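#' Build the relevance-weighted feature graph
#'
#' Edges of the fully connected feature graph are weighted by the joint
#' probability that both endpoint genes belong to the relevant topic:
#' A_p[i, j] = p(relevant | f_i) * p(relevant | f_j) for i != j. The
#' diagonal is forced to zero (self-loops would dominate the path series),
#' so A_p is symmetric with entries in [0, 1].
#'
#' @param model A `plsa_model` from [fit_plsa()].
#' @return A `relevance_graph`: list with `genes`, `weights` (square
#'   matrix), and `masked = FALSE`.
#' @export
weight_graph <- function(model) {
  p <- unname(model$relevance)
  w <- outer(p, p)
  diag(w) <- 0
  dimnames(w) <- list(model$features, model$features)
  structure(list(genes = model$features, weights = w, masked = FALSE),
            class = "relevance_graph")
}

#' Mask the relevance graph with the interaction-network adjacency
#'
#' Hadamard (element-wise) product A = A_p o A_F: a relevance edge survives
#' only where the reconstructed interaction network has a directed arc, so
#' paths are confined to known regulatory relationships. The directed mask
#' is used as-is by default, which can make A asymmetric; set
#' `symmetrize = TRUE` to OR the mask with its transpose first.
#'
#' @param graph A `relevance_graph` from [weight_graph()].
#' @param mask A `network_mask` from [reconstruct_network()] over the
#'   identical ordered gene list.
#' @param symmetrize Symmetrize the mask before multiplying (default FALSE).
#' @return A masked `relevance_graph`.
#' @export
apply_network_mask <- function(graph, mask, symmetrize = FALSE) {
  if (!identical(graph$genes, mask$genes)) {
    abort("relevance graph and network mask must share the same gene order")
  }
  m <- mask$matrix
  if (symmetrize) m <- pmax(m, t(m))
  out <- graph
  out$weights <- graph$weights * m
  out$masked <- TRUE
  out
}

#' Path energies by explicit enumeration (oracle)
#'
#' Sums, over every node sequence v_0 = i, v_1, ..., v_l = j, the product
#' of edge weights along the sequence — the joint probability that the
#' traversed feature subset is good. Exponential in `length`, so it is
#' restricted to graphs of at most 8 nodes; it exists to certify that the
#' matrix-power computation used by [rank_features()] is exact:
#' C_l(i, j) = A^l[i, j].
#'
#' @param graph A `relevance_graph` or a square numeric matrix.
#' @param length Path length l >= 1.
#' @return Square matrix C_l of summed path energies.
#' @export
enumerate_path_energy <- function(graph, length) {
  a <- if (inherits(graph, "relevance_graph")) graph$weights else as.matrix(graph)
  n <- nrow(a)
  stopifnot(ncol(a) == n, length >= 1)
  if (n > 8) abort("path enumeration is exponential; at most 8 nodes allowed")
  c_l <- matrix(0, n, n, dimnames = dimnames(a))
  interior <- as.matrix(expand.grid(rep(list(seq_len(n)), length - 1)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (length == 1) {
        c_l[i, j] <- a[i, j]
        next
      }
      total <- 0
      for (row in seq_len(nrow(interior))) {
        path <- c(i, interior[row, ], j)
        total <- total + prod(a[cbind(path[-(length + 1)], path[-1])])
      }
      c_l[i, j] <- total
    }
  }
  c_l
}

# Spectral radius of |A|; the convergence bound must hold for the series of
# absolute values actually summed when A is asymmetric.
spectral_radius <- function(a) {
  if (all(a == 0)) return(0)
  max(abs(eigen(abs(a), only.values = TRUE)$values))
}

#' Rank genes by infinite-path energy through the masked graph
#'
#' Accumulates the energy of paths of every length via the regularized
#' geometric series C = sum_{l>=1} r^l A^l = (I - rA)^{-1} - I, with
#' r = alpha / rho(|A|) so the series always converges (r = alpha when A is
#' all-zero). The score of gene i marginalizes the accumulated energy over
#' end points: s(i) = rowSums(C). Genes are ordered by score descending;
#' ties — including all isolated genes, whose score is exactly 0 — are
#' broken by |t statistic| descending, then gene id ascending, giving a
#' deterministic total order.
#'
#' Isolated genes (no retained incident arc) are scored 0 exactly by
#' construction: the inversion is performed on the non-isolated subgraph.
#'
#' @param graph A masked `relevance_graph`.
#' @param alpha Fraction of the convergence limit to use, in (0, 1)
#'   (default 0.9).
#' @param candidates Optional `candidate_set` supplying per-gene origin
#'   flags.
#' @param differential Optional `differential_result` supplying the
#'   t statistics used for tie-breaking (0 when absent).
#' @param r Optional explicit regularizer overriding `alpha / rho(|A|)`;
#'   must satisfy `r * rho(|A|) < 1`.
#' @return A `gene_ranking` tibble with columns `rank`, `gene`, `score`,
#'   `origin`, `isolated`, ordered by rank.
#' @export
rank_features <- function(graph, alpha = 0.9, candidates = NULL,
                          differential = NULL, r = NULL) {
  a <- graph$weights
  genes <- graph$genes
  n <- length(genes)
  rho <- spectral_radius(a)
  if (is.null(r)) {
    stopifnot(alpha > 0, alpha < 1)
    r <- if (rho > 0) alpha / rho else alpha
  }
  if (r * rho >= 1) {
    abort(sprintf("series diverges: r * rho(A) = %.4f >= 1", r * rho))
  }
  live <- which(rowSums(a != 0) + colSums(a != 0) > 0)
  scores <- numeric(n)
  if (length(live) > 0) {
    a_live <- a[live, live, drop = FALSE]
    c_check <- solve(diag(length(live)) - r * a_live) - diag(length(live))
    scores[live] <- rowSums(c_check)
  }
  isolated <- !(seq_len(n) %in% live)
  t_abs <- rep(0, n)
  if (!is.null(differential)) {
    idx <- match(genes, differential$gene)
    t_abs <- abs(differential$t_statistic[idx])
    t_abs[is.na(t_abs)] <- 0
  }
  origin <- rep(NA_character_, n)
  if (!is.null(candidates)) {
    origin <- candidates$origin[match(genes, candidates$gene)]
  }
  ord <- order(-scores, -t_abs, genes)
  out <- tibble::tibble(
    rank = seq_len(n),
    gene = genes[ord],
    score = scores[ord],
    origin = origin[ord],
    isolated = isolated[ord])
  attr(out, "r") <- r
  attr(out, "spectral_radius") <- rho
  class(out) <- c("gene_ranking", class(out))
  out
}

#' Plot a gene ranking's score profile
#'
#' @param object A `gene_ranking`.
#' @param top_k Number of leading genes to annotate by origin (default 50).
#' @param ... Unused.
#' @return A ggplot of score against rank, colored by candidate origin.
#' @export
autoplot.gene_ranking <- function(object, top_k = 50, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      origin = dplyr::coalesce(.data$origin, "unknown"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score,
                                   colour = .data$origin)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = top_k, linetype = "dashed") +
    ggplot2::labs(x = "rank", y = "path-energy score s(i)",
                  colour = "origin") +
    ggplot2::theme_minimal()
}
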
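#' Adaptive synthetic (ADASYN) oversampling of the minority class
#'
#' Generates synthetic minority records so the class counts become close to
#' balanced, placing more synthetic points near minority samples that are
#' hard to learn. For every minority record i, r_i is the fraction of
#' majority samples among its `k_neighbors` nearest neighbors (Euclidean,
#' over all records); the total synthetic budget
#' G = (n_majority - n_minority) * beta is split proportionally to the
#' normalized r_i, and each synthetic point is an interpolation
#' x = x_i + lambda * (x_z - x_i), lambda ~ U(0, 1), toward a random one of
#' i's `k_neighbors` nearest minority neighbors. When no minority point has
#' a majority neighbor (r_i all zero) the budget is spread uniformly.
#' Majority records are never altered or dropped.
#'
#' @param records Data frame: one row per sample, numeric feature columns
#'   plus a label column.
#' @param label_col Name of the label column (default `"label"`); must have
#'   exactly two classes.
#' @param k_neighbors Neighborhood size k (default 5; shrunk with a message
#'   when fewer neighbors exist).
#' @param beta Fraction of the class gap to fill (default 1 balances the
#'   classes).
#' @param seed Integer seed.
#' @return A tibble: the original records (in order) followed by the
#'   synthetic ones, with a logical `.synthetic` column.
#' @export
adasyn_oversample <- function(records, label_col = "label", k_neighbors = 5,
                              beta = 1.0, seed = 1) {
  records <- tibble::as_tibble(records)
  stopifnot(label_col %in% names(records))
  labels <- as.character(records[[label_col]])
  classes <- sort(unique(labels))
  if (length(classes) != 2) {
    abort("ADASYN needs exactly two classes in the input")
  }
  counts <- table(labels)
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(classes, minority)
  n_min <- sum(labels == minority)
  n_maj <- sum(labels == majority)
  feat_cols <- setdiff(names(records), label_col)
  x <- as.matrix(records[, feat_cols, drop = FALSE])
  storage.mode(x) <- "double"
  out <- dplyr::mutate(records, .synthetic = FALSE)
  g_total <- round((n_maj - n_min) * beta)
  if (g_total <= 0) return(out)
  if (n_min < 2) abort("ADASYN needs at least 2 minority records")
  k <- min(k_neighbors, nrow(x) - 1, n_min - 1)
  if (k < k_neighbors) {
    inform(sprintf("ADASYN: k shrunk from %d to %d (too few neighbors)",
                   k_neighbors, k))
  }
  min_idx <- which(labels == minority)
  d <- as.matrix(stats::dist(x))
  # hardness of each minority point: majority share of its k-NN (all classes)
  k_all <- min(k_neighbors, nrow(x) - 1)
  r <- vapply(min_idx, function(i) {
    nn <- order(d[i, -i])  # indices into the reduced vector
    others <- setdiff(seq_len(nrow(x)), i)
    nn_idx <- others[nn][seq_len(k_all)]
    mean(labels[nn_idx] == majority)
  }, numeric(1))
  if (sum(r) == 0) {
    inform("ADASYN: no borderline minority points; uniform allocation")
    r_hat <- rep(1 / length(r), length(r))
  } else {
    r_hat <- r / sum(r)
  }
  g_i <- round(r_hat * g_total)
  set.seed(seed)
  synth <- vector("list", length(min_idx))
  for (ii in seq_along(min_idx)) {
    if (g_i[ii] == 0) next
    i <- min_idx[ii]
    other_min <- setdiff(min_idx, i)
    nn_min <- other_min[order(d[i, other_min])][seq_len(k)]
    z <- nn_min[sample.int(length(nn_min), g_i[ii], replace = TRUE)]
    lambda <- runif(g_i[ii])
    synth[[ii]] <- x[rep(i, g_i[ii]), , drop = FALSE] +
      lambda * (x[z, , drop = FALSE] - x[rep(i, g_i[ii]), , drop = FALSE])
  }
  synth <- do.call(rbind, synth)
  if (is.null(synth) || nrow(synth) == 0) return(out)
  synth_df <- tibble::as_tibble(as.data.frame(synth))
  names(synth_df) <- feat_cols
  synth_df[[label_col]] <- minority
  synth_df$.synthetic <- TRUE
  dplyr::bind_rows(out, synth_df[, names(out)])
}

#' F1 score from precision and recall
#'
#' Harmonic mean F1 = 2 * precision * recall / (precision + recall);
#' defined as 0 when both are 0.
#'
#' @param precision,recall Values in \[0, 1\].
#' @return The F1 score.
#' @export
f1_score <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  out <- numeric(length(precision))
  both_zero <- precision + recall == 0
  if (any(both_zero)) inform("F1 undefined (precision = recall = 0); set to 0")
  ok <- !both_zero
  out[ok] <- 2 * precision[ok] * recall[ok] / (precision[ok] + recall[ok])
  out
}
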
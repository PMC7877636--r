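#' Hypergeometric enrichment of known oncogenes in a selected gene set
#'
#' Tests whether the selected genes (for example the top 100 of a ranking)
#' contain more known oncogenes than expected when drawing the same number
#' of genes at random from the universe. The p-value is the upper tail
#' P(X >= k) of a hypergeometric distribution with population `|universe|`,
#' `|oncogenes in universe|` successes and `|selected|` draws, where k is
#' the observed overlap. Oncogenes outside the universe are ignored.
#'
#' @param selected Character vector of selected genes (must lie in
#'   `universe`).
#' @param oncogenes Character vector of known oncogene symbols.
#' @param universe Character vector: every gene that could have been
#'   selected.
#' @return A one-row tibble with `top_k`, `universe_size`,
#'   `oncogenes_in_universe`, `oncogenes_selected`, `p_value`.
#' @export
hypergeometric_enrichment <- function(selected, oncogenes, universe) {
  selected <- unique(toupper(selected))
  oncogenes <- unique(toupper(oncogenes))
  universe <- unique(toupper(universe))
  if (length(universe) == 0) abort("empty gene universe")
  stray <- setdiff(selected, universe)
  if (length(stray) > 0) {
    abort(paste0("selected gene(s) outside the universe: ",
                 paste(head(stray, 5), collapse = ", ")))
  }
  onc <- intersect(oncogenes, universe)
  k <- length(intersect(selected, onc))
  # P(X >= k); phyper's lower.tail=FALSE gives P(X > q), so q = k - 1
  p <- phyper(k - 1, m = length(onc), n = length(universe) - length(onc),
              k = length(selected), lower.tail = FALSE)
  tibble::tibble(
    top_k = length(selected),
    universe_size = length(universe),
    oncogenes_in_universe = length(onc),
    oncogenes_selected = k,
    p_value = p)
}
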
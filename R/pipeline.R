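#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its default; input paths have no
#' default and must be supplied. Unknown keys are rejected by
#' [run_config()].
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    expression = NULL, metadata = NULL, network = NULL, oncogenes = NULL,
    out_dir = ".",
    fdr_cutoff = 0.05, lfc_cutoff = 1.0, min_degree = 100,
    max_differential_genes = NULL, pseudocount = 1.0,
    quantization_levels = 6L, plsa_restarts = 3L, plsa_max_iter = 200L,
    plsa_tol = 1e-6, alpha = 0.9, symmetrize_mask = FALSE,
    top_k = 100L, folds = 5L, repeats = 100L, svm_c = 1.0,
    adasyn_k = 5L, adasyn_beta = 1.0, master_seed = 1L,
    evaluate = TRUE)
}

#' Build and validate a pipeline configuration
#'
#' @param ... Key-value overrides of [default_run_config()].
#' @param config Optional named list of overrides (e.g. from
#'   [read_run_config()]); `...` wins over it.
#' @return A validated `run_config` list.
#' @export
run_config <- function(..., config = list()) {
  overrides <- utils::modifyList(config, list(...))
  defaults <- default_run_config()
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  out <- utils::modifyList(defaults, overrides)
  for (key in c("expression", "metadata", "network")) {
    if (is.null(out[[key]])) abort(paste0("config key '", key, "' is required"))
    if (!file.exists(out[[key]])) {
      abort(paste0("input file for '", key, "' not found: ", out[[key]]))
    }
  }
  class(out) <- "run_config"
  out
}

#' Read a pipeline configuration from a YAML file
#'
#' Plain `key: value` YAML; keys are those of [default_run_config()].
#'
#' @param path Path to the config file.
#' @param ... Overrides applied on top of the file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path, ...) {
  run_config(..., config = yaml::read_yaml(path))
}

# Samples used for feature selection: paired patients, restricted to the
# selection partition when the metadata carries one.
selection_dataset <- function(dataset) {
  has_part <- "partition" %in% names(dataset$meta)
  d <- if (has_part) {
    filter_dataset(dataset, partition = "selection")
  } else dataset
  pairs <- paired_patients(d)
  filter_dataset(d, samples = d$meta$sample_id[d$meta$patient_id %in% pairs])
}

validation_dataset <- function(dataset) {
  if ("partition" %in% names(dataset$meta)) {
    filter_dataset(dataset, partition = "validation")
  } else dataset
}

#' Preprocess stage: differential screen and candidate set
#'
#' Reads the expression, metadata and network inputs, converts to TPM,
#' runs the paired differential screen on the feature-selection samples,
#' selects network hubs, and writes `differential.tsv` and
#' `candidates.tsv` into `out_dir`.
#'
#' @param config A `run_config`.
#' @return List with `differential` (tibble), `candidates` (tibble) and
#'   the file paths, invisibly reusable by [pipeline_rank()].
#' @export
pipeline_preprocess <- function(config) {
  dataset <- read_expression(config$expression, config$metadata)
  network <- read_fi_network(config$network)
  tpm <- fpkm_to_tpm(dataset)
  sel <- selection_dataset(tpm)
  differential <- paired_t_test(sel, pseudocount = config$pseudocount)
  n_genes <- select_differential_genes(
    differential, fdr_cutoff = config$fdr_cutoff,
    lfc_cutoff = config$lfc_cutoff,
    max_genes = config$max_differential_genes)
  m_genes <- select_hub_genes(network, min_degree = config$min_degree)
  cand <- candidate_set(n_genes, m_genes)
  measured <- cand$gene %in% rownames(dataset$values)
  if (any(!measured)) {
    inform(paste0(sum(!measured),
                  " candidate gene(s) not measured in the expression data; dropped"))
    cand <- cand[measured, , drop = FALSE]
  }
  if (nrow(cand) == 0) abort("preprocess: empty candidate set T")
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  diff_path <- file.path(config$out_dir, "differential.tsv")
  cand_path <- file.path(config$out_dir, "candidates.tsv")
  diff_out <- differential
  diff_out$t_statistic <- format_score(diff_out$t_statistic)
  diff_out$p_value <- format_score(diff_out$p_value)
  diff_out$q_value <- format_score(diff_out$q_value)
  diff_out$log2_fold_change <- format_score(diff_out$log2_fold_change)
  utils::write.table(diff_out, diff_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cand, cand_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(differential = differential, candidates = cand,
                 paths = c(differential = diff_path, candidates = cand_path)))
}

#' Ranking stage: tokenize, weight, mask, rank
#'
#' Consumes the outputs of [pipeline_preprocess()] (re-read from `out_dir`
#' when not passed), reconstructs the interaction network over the
#' candidate set, fits the two-topic PLSA on the feature-selection
#' samples, masks the relevance graph and writes `ranking.tsv`.
#'
#' @param config A `run_config`.
#' @param preprocess Optional result of [pipeline_preprocess()].
#' @return The `gene_ranking` tibble, invisibly.
#' @export
pipeline_rank <- function(config, preprocess = NULL) {
  dataset <- read_expression(config$expression, config$metadata)
  network <- read_fi_network(config$network)
  if (is.null(preprocess)) {
    diff_path <- file.path(config$out_dir, "differential.tsv")
    cand_path <- file.path(config$out_dir, "candidates.tsv")
    if (!file.exists(diff_path) || !file.exists(cand_path)) {
      abort("rank: run the preprocess stage first (differential.tsv / candidates.tsv missing)")
    }
    differential <- readr::read_tsv(diff_path, show_col_types = FALSE,
                                    progress = FALSE)
    cand <- readr::read_tsv(cand_path, show_col_types = FALSE,
                            progress = FALSE)
  } else {
    differential <- preprocess$differential
    cand <- preprocess$candidates
  }
  mask <- reconstruct_network(network, cand)
  tpm <- fpkm_to_tpm(dataset)
  sel <- selection_dataset(tpm)
  sel_cand <- filter_dataset(sel, genes = cand$gene)
  tokens <- tokenize_features(sel_cand,
                              quantization_levels = config$quantization_levels,
                              pseudocount = config$pseudocount)
  model <- fit_plsa(tokens, seed = derive_seed(config$master_seed, 101L),
                    max_iter = config$plsa_max_iter, tol = config$plsa_tol,
                    restarts = config$plsa_restarts)
  graph <- weight_graph(model)
  masked <- apply_network_mask(graph, mask,
                               symmetrize = config$symmetrize_mask)
  ranking <- rank_features(masked, alpha = config$alpha, candidates = cand,
                           differential = differential)
  write_ranking(ranking, file.path(config$out_dir, "ranking.tsv"))
  invisible(ranking)
}

#' Evaluation stage: rebalanced repeated CV on the top-ranked genes
#'
#' Classifies the validation-partition samples using the leading `top_k`
#' genes of `ranking.tsv` and writes `evaluation.tsv`.
#'
#' @param config A `run_config`.
#' @param ranking Optional `gene_ranking` (re-read from `out_dir` when
#'   absent).
#' @return The `evaluation_report`, invisibly.
#' @export
pipeline_evaluate <- function(config, ranking = NULL) {
  dataset <- read_expression(config$expression, config$metadata)
  if (is.null(ranking)) {
    rank_path <- file.path(config$out_dir, "ranking.tsv")
    if (!file.exists(rank_path)) abort("evaluate: ranking.tsv missing; run rank first")
    ranking <- read_ranking(rank_path)
  }
  val <- validation_dataset(fpkm_to_tpm(dataset))
  report <- run_cv_evaluation(
    val, ranking, top_k = min(config$top_k, nrow(ranking)),
    folds = config$folds, repeats = config$repeats,
    seed = derive_seed(config$master_seed, 202L), svm_c = config$svm_c,
    adasyn_k = config$adasyn_k, adasyn_beta = config$adasyn_beta)
  write_evaluation_report(report, file.path(config$out_dir, "evaluation.tsv"))
  invisible(report)
}

#' Enrichment stage: known-oncogene content of the top-ranked genes
#'
#' Tests the leading `top_k` genes against the oncogene list with the
#' measured gene universe and writes `enrichment.tsv`.
#'
#' @param config A `run_config` with a non-NULL `oncogenes` path.
#' @param ranking Optional `gene_ranking` (re-read from `out_dir` when
#'   absent).
#' @return The enrichment tibble, invisibly.
#' @export
pipeline_enrich <- function(config, ranking = NULL) {
  if (is.null(config$oncogenes)) abort("enrich: config key 'oncogenes' not set")
  dataset <- read_expression(config$expression, config$metadata)
  if (is.null(ranking)) {
    rank_path <- file.path(config$out_dir, "ranking.tsv")
    if (!file.exists(rank_path)) abort("enrich: ranking.tsv missing; run rank first")
    ranking <- read_ranking(rank_path)
  }
  oncogenes <- read_gene_list(config$oncogenes)
  universe <- rownames(dataset$values)
  selected <- head(ranking$gene, min(config$top_k, nrow(ranking)))
  enrichment <- hypergeometric_enrichment(selected, oncogenes, universe)
  out <- enrichment
  out$p_value <- format_score(out$p_value)
  utils::write.table(out, file.path(config$out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(enrichment)
}

#' Run the full pipeline
#'
#' TPM conversion, paired differential screen, hub selection, candidate
#' union, network reconstruction, tokenization, PLSA weighting, network
#' masking, path-energy ranking, then (optionally) the CV evaluation and
#' the oncogene-enrichment test. Stage outputs (`differential.tsv`,
#' `candidates.tsv`, `ranking.tsv`, `evaluation.tsv`, `enrichment.tsv`)
#' are written into `config$out_dir`; identical config and `master_seed`
#' reproduce them byte-for-byte. Chaining [pipeline_preprocess()],
#' [pipeline_rank()], [pipeline_evaluate()] and [pipeline_enrich()] by
#' hand produces the same files.
#'
#' @param config A `run_config` (or a named list accepted by
#'   [run_config()]).
#' @return List with `ranking`, `report` (NULL when `evaluate` is FALSE)
#'   and `enrichment` (NULL when no oncogene list is configured).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config = config)
  log_config(config)
  pre <- tryCatch(
    pipeline_preprocess(config),
    error = function(e) abort(paste0("stage preprocess: ",
                                     conditionMessage(e))))
  ranking <- tryCatch(
    pipeline_rank(config, preprocess = pre),
    error = function(e) abort(paste0("stage rank: ", conditionMessage(e))))
  report <- NULL
  if (isTRUE(config$evaluate)) {
    report <- tryCatch(
      pipeline_evaluate(config, ranking = ranking),
      error = function(e) abort(paste0("stage evaluate: ",
                                       conditionMessage(e))))
  }
  enrichment <- NULL
  if (!is.null(config$oncogenes)) {
    enrichment <- tryCatch(
      pipeline_enrich(config, ranking = ranking),
      error = function(e) abort(paste0("stage enrich: ",
                                       conditionMessage(e))))
  } else {
    inform("no oncogene list configured; enrichment stage skipped")
  }
  list(ranking = ranking, report = report, enrichment = enrichment)
}

# Every under-specified tunable's active value, logged once per run.
log_config <- function(config) {
  keys <- c("fdr_cutoff", "lfc_cutoff", "min_degree", "pseudocount",
            "quantization_levels", "plsa_restarts", "alpha",
            "symmetrize_mask", "top_k", "folds", "repeats", "svm_c",
            "adasyn_k", "adasyn_beta", "master_seed")
  vals <- vapply(keys, function(k) paste0(k, "=", config[[k]]), character(1))
  inform(paste0("run config: ", paste(vals, collapse = " ")))
}
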
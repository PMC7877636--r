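#' Specify a synthetic benchmark
#'
#' Defines an in-silico study: a gene universe, paired tumor/normal
#' patients plus unpaired tumors, a planted connected module of `n_signal`
#' truly differential genes, optional isolated "decoy" differential genes,
#' network hubs, and random background interactions. The defaults describe
#' the benchmark the package's end-to-end recovery checks run on: 200
#' genes, 40 paired patients, a 20-gene signal module with a true tumor
#' effect of 2 on the log2-TPM scale and unit log2-scale noise.
#'
#' @param n_genes Total genes (default 200).
#' @param n_pairs Paired patients, one tumor + one normal sample each
#'   (default 40).
#' @param n_unpaired_tumor Tumor-only samples (default 20).
#' @param n_signal Planted network-connected differential genes
#'   (default 20).
#' @param signal_lfc True tumor effect of signal (and decoy) genes, log2
#'   units (default 2).
#' @param noise_sd Per-observation Gaussian noise sd, log2 units
#'   (default 1).
#' @param n_decoys Differential genes deliberately left without any
#'   network edge (default 0); the scenario where the network mask should
#'   separate the methods.
#' @param n_hubs Number of hub genes (default 5).
#' @param hub_degree Minimum degree wired for each hub (default 120).
#' @param background_edge_prob Probability of an edge between any other
#'   gene pair (default 0.02).
#' @param patient_sd Sd of the per-patient, per-gene random effect shared
#'   by a patient's tumor and normal samples (default 0.5, log2 units).
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline
#'   log2 expression (defaults 5 and 2).
#' @param selection_fraction Fraction of pairs assigned to the
#'   feature-selection partition (default 0.7).
#' @param seed Integer seed (default 1).
#' @return A `benchmark_spec` list.
#' @export
benchmark_spec <- function(n_genes = 200, n_pairs = 40, n_unpaired_tumor = 20,
                           n_signal = 20, signal_lfc = 2, noise_sd = 1,
                           n_decoys = 0, n_hubs = 5, hub_degree = 120,
                           background_edge_prob = 0.02, patient_sd = 0.5,
                           baseline_mean = 5, baseline_sd = 2,
                           selection_fraction = 0.7, seed = 1) {
  spec <- list(n_genes = n_genes, n_pairs = n_pairs,
               n_unpaired_tumor = n_unpaired_tumor, n_signal = n_signal,
               signal_lfc = signal_lfc, noise_sd = noise_sd,
               n_decoys = n_decoys, n_hubs = n_hubs, hub_degree = hub_degree,
               background_edge_prob = background_edge_prob,
               patient_sd = patient_sd, baseline_mean = baseline_mean,
               baseline_sd = baseline_sd,
               selection_fraction = selection_fraction, seed = seed)
  stopifnot(spec$n_signal + spec$n_decoys + spec$n_hubs <= spec$n_genes,
            spec$n_genes > 0, spec$n_pairs > 0,
            spec$background_edge_prob >= 0, spec$background_edge_prob < 1,
            spec$hub_degree < spec$n_genes)
  class(spec) <- "benchmark_spec"
  spec
}

# Gene naming: signal SIG001.., decoys DEC01.., hubs HUB1.., rest G0001..
benchmark_genes <- function(spec) {
  n_rest <- spec$n_genes - spec$n_signal - spec$n_decoys - spec$n_hubs
  list(
    signal = sprintf("SIG%03d", seq_len(spec$n_signal)),
    decoy = if (spec$n_decoys > 0) sprintf("DEC%03d", seq_len(spec$n_decoys))
            else character(0),
    hub = if (spec$n_hubs > 0) sprintf("HUB%02d", seq_len(spec$n_hubs))
          else character(0),
    rest = sprintf("G%04d", seq_len(n_rest)))
}

#' Generate a synthetic interaction network
#'
#' Signal genes are wired as one connected module (a random spanning tree
#' plus extra within-module edges at probability 0.3); each hub is wired to
#' at least `hub_degree` random partners; every remaining eligible pair
#' gets an edge with probability `background_edge_prob`. Decoy genes
#' receive no edges at all. Edge directions are drawn uniformly from
#' forward / backward / bidirectional. Deterministic given `spec$seed`.
#'
#' @param spec A [benchmark_spec()].
#' @return A `fi_network` tibble.
#' @export
generate_network <- function(spec) {
  set.seed(derive_seed(spec$seed, 11L))
  g <- benchmark_genes(spec)
  genes <- c(g$signal, g$decoy, g$hub, g$rest)
  wired <- setdiff(genes, g$decoy)
  edges <- list()
  # spanning tree over the signal module: attach each gene to a random
  # earlier one
  if (length(g$signal) >= 2) {
    for (i in 2:length(g$signal)) {
      edges[[length(edges) + 1]] <- c(g$signal[sample.int(i - 1, 1)],
                                      g$signal[i])
    }
    extra <- utils::combn(g$signal, 2)
    keep <- runif(ncol(extra)) < 0.3
    for (k in which(keep)) {
      edges[[length(edges) + 1]] <- extra[, k]
    }
  }
  # hubs: wire to hub_degree random non-decoy partners
  for (h in g$hub) {
    partners <- sample(setdiff(wired, h), spec$hub_degree)
    for (p in partners) edges[[length(edges) + 1]] <- c(h, p)
  }
  # background
  others <- setdiff(wired, g$signal)
  if (length(wired) >= 2 && spec$background_edge_prob > 0) {
    all_pairs <- utils::combn(wired, 2)
    both_signal <- all_pairs[1, ] %in% g$signal & all_pairs[2, ] %in% g$signal
    keep <- runif(ncol(all_pairs)) < spec$background_edge_prob & !both_signal
    for (k in which(keep)) {
      edges[[length(edges) + 1]] <- all_pairs[, k]
    }
  }
  edge_df <- tibble::tibble(
    gene_a = vapply(edges, `[`, character(1), 1),
    gene_b = vapply(edges, `[`, character(1), 2),
    direction = sample(c("forward", "backward", "bidirectional"),
                       length(edges), replace = TRUE))
  fi_network(edge_df)
}

#' Generate paired tumor/normal expression with planted signal
#'
#' Per gene, a baseline log2 expression is drawn once; each observation
#' adds a patient-level random effect (shared by the tumor and normal
#' samples of a patient), the condition effect (`signal_lfc` for signal and
#' decoy genes in tumor samples) and Gaussian noise, and is exponentiated
#' to the FPKM scale. About `selection_fraction` of the pairs are tagged
#' `selection`; the remaining pairs and all unpaired tumors are tagged
#' `validation`. Deterministic given `spec$seed`.
#'
#' @param spec A [benchmark_spec()].
#' @param network A `fi_network`, normally from [generate_network()].
#' @return A `benchmark_truth`: list with `dataset` (an
#'   [expression_dataset()], FPKM units, metadata carrying the `partition`
#'   tag), `network`, `signal_genes`, `decoy_genes`, `hub_genes`, and
#'   `spec`.
#' @export
generate_expression <- function(spec, network) {
  set.seed(derive_seed(spec$seed, 23L))
  g <- benchmark_genes(spec)
  genes <- c(g$signal, g$decoy, g$hub, g$rest)
  affected <- genes %in% c(g$signal, g$decoy)
  pair_ids <- sprintf("P%03d", seq_len(spec$n_pairs))
  unpaired_ids <- if (spec$n_unpaired_tumor > 0) {
    sprintf("U%03d", seq_len(spec$n_unpaired_tumor))
  } else character(0)
  meta <- tibble::tibble(
    sample_id = c(paste0(pair_ids, "_T"), paste0(pair_ids, "_N"),
                  paste0(unpaired_ids, "_T")),
    patient_id = c(pair_ids, pair_ids, unpaired_ids),
    condition = c(rep("tumor", spec$n_pairs), rep("normal", spec$n_pairs),
                  rep("tumor", length(unpaired_ids))))
  n_sel <- round(spec$selection_fraction * spec$n_pairs)
  sel_pairs <- pair_ids[sample.int(spec$n_pairs, n_sel)]
  meta$partition <- ifelse(meta$patient_id %in% sel_pairs,
                           "selection", "validation")
  baseline <- rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
  n_samp <- nrow(meta)
  patients <- unique(meta$patient_id)
  # per patient x gene random effect, shared within a pair
  pat_eff <- matrix(rnorm(spec$n_genes * length(patients), 0, spec$patient_sd),
                    nrow = spec$n_genes,
                    dimnames = list(NULL, patients))
  log2x <- matrix(baseline, spec$n_genes, n_samp) +
    pat_eff[, meta$patient_id] +
    outer(ifelse(affected, spec$signal_lfc, 0),
          as.numeric(meta$condition == "tumor")) +
    matrix(rnorm(spec$n_genes * n_samp, 0, spec$noise_sd), spec$n_genes)
  values <- 2^log2x
  dimnames(values) <- list(genes, meta$sample_id)
  dataset <- expression_dataset(values, meta, units = "FPKM")
  structure(list(dataset = dataset, network = network,
                 signal_genes = g$signal, decoy_genes = g$decoy,
                 hub_genes = g$hub, spec = spec),
            class = "benchmark_truth")
}

#' Generate a full synthetic benchmark
#'
#' Convenience wrapper: [generate_network()] then [generate_expression()].
#'
#' @param spec A [benchmark_spec()].
#' @return A `benchmark_truth`.
#' @export
simulate_benchmark <- function(spec = benchmark_spec()) {
  network <- generate_network(spec)
  generate_expression(spec, network)
}

#' Write a benchmark as the tool's standard input files
#'
#' Emits `expression.tsv` (FPKM matrix), `metadata.tsv` (sample_id,
#' patient_id, condition, partition), `network.tsv` (Gene1/Gene2/Direction
#' with arrow tokens) and `signal_genes.txt` (the planted genes, usable as
#' a synthetic known-oncogene list), consumable unchanged by
#' [read_expression()], [read_fi_network()] and [read_gene_list()].
#'
#' @param truth A `benchmark_truth` from [simulate_benchmark()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_benchmark <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             network = file.path(dir, "network.tsv"),
             signal = file.path(dir, "signal_genes.txt"))
  values <- truth$dataset$values
  expr_df <- data.frame(gene = rownames(values),
                        format(values, digits = 10, trim = TRUE,
                               scientific = FALSE),
                        check.names = FALSE)
  utils::write.table(expr_df, paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$dataset$meta, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  arrows <- c(forward = "->", backward = "<-", bidirectional = "<->")
  net_df <- data.frame(Gene1 = truth$network$gene_a,
                       Gene2 = truth$network$gene_b,
                       Direction = arrows[truth$network$direction])
  utils::write.table(net_df, paths["network"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c("# planted signal genes (synthetic oncogene list)",
               truth$signal_genes), paths["signal"])
  invisible(paths)
}
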
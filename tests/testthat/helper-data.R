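# Fixtures and independent oracles, built in code at test time.

# Tiny paired dataset: `diffs` gives, per gene, the tumor-minus-normal
# difference of log2(TPM + 1) for every pair; normals sit at `base`.
paired_dataset_from_diffs <- function(diffs, base = 8) {
  n_pairs <- ncol(diffs)
  genes <- rownames(diffs) %||% paste0("G", seq_len(nrow(diffs)))
  pair_ids <- paste0("P", seq_len(n_pairs))
  normal <- matrix(base, nrow(diffs), n_pairs)
  tumor <- normal + diffs
  values <- cbind(2^tumor - 1, 2^normal - 1)
  dimnames(values) <- list(genes, c(paste0(pair_ids, "_T"),
                                    paste0(pair_ids, "_N")))
  meta <- tibble::tibble(
    sample_id = colnames(values),
    patient_id = rep(pair_ids, 2),
    condition = rep(c("tumor", "normal"), each = n_pairs))
  expression_dataset(values, meta, units = "TPM")
}

# 3-gene x 4-sample dataset with 2 paired patients, written as TSV files.
write_tiny_files <- function(dir) {
  values <- matrix(c(1, 2, 3, 4,
                     5, 6, 7, 8,
                     9, 10, 11, 12), nrow = 3, byrow = TRUE,
                   dimnames = list(c("TP53", "MDM2", "EGFR"),
                                   c("S1", "S2", "S3", "S4")))
  expr <- data.frame(gene = rownames(values), values, check.names = FALSE)
  meta <- data.frame(sample_id = c("S1", "S2", "S3", "S4"),
                     patient_id = c("P1", "P1", "P2", "P2"),
                     condition = c("tumor", "normal", "tumor", "normal"))
  mp <- file.path(dir, "expr.tsv")
  mm <- file.path(dir, "meta.tsv")
  utils::write.table(expr, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(meta, mm, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mp, metadata = mm)
}

write_network_file <- function(dir, lines) {
  path <- file.path(dir, "net.tsv")
  writeLines(c("Gene1\tGene2\tDirection", lines), path)
  path
}

# Random non-negative weight matrix with zero diagonal.
random_graph_matrix <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  diag(a) <- 0
  a
}

as_relevance_graph <- function(a, genes = paste0("g", seq_len(nrow(a)))) {
  dimnames(a) <- list(genes, genes)
  structure(list(genes = genes, weights = a, masked = TRUE),
            class = "relevance_graph")
}

all_ones_mask <- function(genes) {
  m <- matrix(1, length(genes), length(genes),
              dimnames = list(genes, genes))
  diag(m) <- 0
  structure(list(genes = genes, matrix = m), class = "network_mask")
}

# Independent BH step-up oracle: literal sorted-p sweep.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}

# Hypergeometric upper-tail oracle by explicit pmf summation with choose().
hyper_upper_oracle <- function(k, universe, n_onc, n_sel) {
  kk <- k:min(n_onc, n_sel)
  sum(choose(n_onc, kk) * choose(universe - n_onc, n_sel - kk)) /
    choose(universe, n_sel)
}

# Truncated geometric series sum_{l=1}^{L} r^l A^l.
series_oracle <- function(a, r, L = 200) {
  acc <- matrix(0, nrow(a), ncol(a))
  pw <- diag(nrow(a))
  for (l in seq_len(L)) {
    pw <- pw %*% a
    acc <- acc + r^l * pw
  }
  acc
}

# Connectivity of an undirected edge list restricted to `genes`.
is_connected <- function(network, genes) {
  edges <- network[network$gene_a %in% genes & network$gene_b %in% genes, ]
  reached <- genes[1]
  repeat {
    nxt <- unique(c(edges$gene_b[edges$gene_a %in% reached],
                    edges$gene_a[edges$gene_b %in% reached]))
    grown <- union(reached, nxt)
    if (length(grown) == length(reached)) break
    reached <- grown
  }
  all(genes %in% reached)
}
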
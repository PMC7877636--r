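make_tokens_dataset <- function(values, conditions) {
  n <- ncol(values)
  meta <- tibble::tibble(sample_id = colnames(values),
                         patient_id = paste0("P", seq_len(n)),
                         condition = conditions)
  expression_dataset(values, meta, units = "TPM")
}

test_that("tokenization produces the forced two-bin partition", {
  values <- matrix(c(1, 1, 3, 3), 1, 4,
                   dimnames = list("G1", paste0("S", 1:4)))
  ds <- make_tokens_dataset(values, c("normal", "normal", "tumor", "tumor"))
  tk <- tokenize_features(ds, quantization_levels = 2)
  expect_equal(unname(tk$counts[1, ]), c(2L, 0L, 0L, 2L))
  expect_equal(colnames(tk$counts),
               c("bin1_normal", "bin1_tumor", "bin2_normal", "bin2_tumor"))
})

test_that("token counts partition the samples and ignore sample order", {
  set.seed(47)
  values <- matrix(2^rnorm(30 * 12, 5), 30, 12,
                   dimnames = list(sprintf("G%02d", 1:30),
                                   sprintf("S%02d", 1:12)))
  cond <- rep(c("tumor", "normal"), 6)
  ds <- make_tokens_dataset(values, cond)
  tk <- tokenize_features(ds)
  expect_true(all(rowSums(tk$counts) == 12))
  perm <- sample(12)
  ds2 <- make_tokens_dataset(values[, perm], cond[perm])
  tk2 <- tokenize_features(ds2)
  expect_equal(tk2$counts, tk$counts)
})

test_that("constant features land in the middle bin with a message", {
  values <- matrix(c(rep(7, 6), 2^rnorm(6, 3)), 2, 6, byrow = TRUE,
                   dimnames = list(c("FLAT", "VAR"), sprintf("S%d", 1:6)))
  ds <- make_tokens_dataset(values, rep(c("tumor", "normal"), 3))
  expect_message(tk <- tokenize_features(ds, quantization_levels = 6),
                 "constant")
  nonzero_bins <- unique(ceiling(which(tk$counts["FLAT", ] > 0) / 2))
  expect_equal(nonzero_bins, 3)  # middle of 6 bins
})

test_that("PLSA gives identical posteriors to identical count rows", {
  counts <- matrix(rep(c(3L, 1L, 0L, 4L), each = 5), 5, 4)
  tokens <- structure(list(
    features = paste0("f", 1:5),
    vocabulary = tidyr::expand_grid(bin = 1:2, class = c("normal", "tumor")),
    counts = counts), class = "token_counts")
  model <- fit_plsa(tokens, seed = 2, restarts = 1, max_iter = 50)
  post <- model$topic_given_feature
  expect_true(all(abs(sweep(post, 2, post[1, ]) ) < 1e-9))
})

test_that("EM log-likelihood is nondecreasing and probabilities normalized", {
  set.seed(48)
  for (i in 1:15) {
    counts <- matrix(rpois(12 * 8, 3), 12, 8)
    tokens <- structure(list(
      features = paste0("f", 1:12),
      vocabulary = tidyr::expand_grid(bin = 1:4, class = c("normal", "tumor")),
      counts = counts), class = "token_counts")
    model <- suppressWarnings(
      fit_plsa(tokens, seed = i, restarts = 1, max_iter = 80))
    trace <- model$log_likelihood_trace
    expect_true(all(diff(trace) >= -1e-8))
    expect_true(all(abs(rowSums(model$topic_given_feature) - 1) < 1e-9))
    expect_true(all(abs(colSums(model$token_given_topic) - 1) < 1e-9))
  }
})

test_that("planted class-skewed features receive high relevance posteriors", {
  # skewed features co-occur with tumor tokens in high bins and normal
  # tokens in low bins; balanced features spread counts evenly
  q <- 3
  vocab <- tidyr::expand_grid(bin = seq_len(q), class = c("normal", "tumor"))
  skewed <- c(10L, 0L, 4L, 2L, 0L, 10L)   # (bin,class) counts, m = 26
  balanced <- c(5L, 5L, 3L, 3L, 5L, 5L)
  counts <- rbind(matrix(rep(skewed, 6), 6, byrow = TRUE),
                  matrix(rep(balanced, 6), 6, byrow = TRUE))
  tokens <- structure(list(
    features = c(paste0("skew", 1:6), paste0("flat", 1:6)),
    vocabulary = vocab, counts = counts), class = "token_counts")
  model <- suppressWarnings(fit_plsa(tokens, seed = 11))
  rel <- model$relevance
  expect_true(all(rel[1:6] > 0.9))
  expect_true(mean(rel[1:6]) > mean(rel[7:12]))
})

test_that("graph weights are pairwise relevance products", {
  model <- structure(list(relevance = c(a = 1.0, b = 0.5),
                          features = c("a", "b")), class = "plsa_model")
  g <- weight_graph(model)
  expect_equal(unname(g$weights), matrix(c(0, 0.5, 0.5, 0), 2, 2))
  model$relevance <- c(a = 0, b = 0)
  expect_true(all(weight_graph(model)$weights == 0))
  set.seed(50)
  model$relevance <- runif(6)
  model$features <- paste0("f", 1:6)
  w <- weight_graph(model)$weights
  expect_equal(w, t(w))
  expect_true(all(w >= 0 & w <= 1) && all(diag(w) == 0))
})

test_that("the Hadamard mask zeroes exactly the non-network entries", {
  g <- as_relevance_graph(matrix(c(0, .3, .6, .3, 0, .2, .6, .2, 0), 3, 3),
                          genes = c("a", "b", "c"))
  zero_mask <- structure(list(genes = g$genes,
                              matrix = matrix(0, 3, 3)),
                         class = "network_mask")
  expect_true(all(apply_network_mask(g, zero_mask)$weights == 0))
  expect_equal(apply_network_mask(g, all_ones_mask(g$genes))$weights,
               g$weights)
  single <- zero_mask
  single$matrix[1, 2] <- 1
  masked <- apply_network_mask(g, single)
  expect_equal(masked$weights[1, 2], 0.3)
  expect_equal(masked$weights[2, 1], 0)  # directed mask retained
  expect_equal(sum(masked$weights != 0), 1)
  bad <- zero_mask
  bad$genes <- c("a", "c", "b")
  expect_error(apply_network_mask(g, bad), "gene order")
})

test_that("path enumeration matches hand counts and matrix powers", {
  chain <- matrix(c(0, .5, 0, .5, 0, .5, 0, .5, 0), 3, 3)
  c2 <- enumerate_path_energy(chain, 2)
  expect_equal(c2[1, 3], 0.25)  # single path 1 -> 2 -> 3
  expect_equal(enumerate_path_energy(chain, 1), chain)
  expect_true(all(enumerate_path_energy(matrix(0, 3, 3), 3) == 0))
  for (i in 1:10) {
    n <- sample(2:6, 1)
    a <- random_graph_matrix(n, seed = 500 + i)
    for (l in 1:4) {
      pw <- Reduce(`%*%`, rep(list(a), l))
      expect_equal(enumerate_path_energy(a, l), pw, tolerance = 1e-12)
    }
  }
  expect_error(enumerate_path_energy(matrix(0, 9, 9), 2), "8 nodes")
})

test_that("the closed-form ranking matches the 2x2 geometric series by hand", {
  a <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  ranking <- rank_features(as_relevance_graph(a, genes = c("A", "B")), r = 1)
  expect_equal(ranking$score, c(1, 1), tolerance = 1e-12)
  expect_false(any(ranking$isolated))
})

test_that("an all-zero graph scores everything zero with |t| fallback", {
  diff <- tibble::tibble(gene = c("x", "y", "z"),
                         t_statistic = c(1, 3, 2), p_value = 0.5,
                         q_value = 0.5, log2_fold_change = 0)
  ranking <- rank_features(
    as_relevance_graph(matrix(0, 3, 3), genes = c("x", "y", "z")),
    differential = diff)
  expect_equal(ranking$gene, c("y", "z", "x"))
  expect_true(all(ranking$score == 0))
  expect_true(all(ranking$isolated))
})

test_that("closed form equals the truncated series on random graphs", {
  for (i in 1:5) {
    a <- random_graph_matrix(8, seed = 600 + i)
    g <- as_relevance_graph(a)
    rho <- max(abs(eigen(a, only.values = TRUE)$values))
    r <- 0.9 / rho
    ranking <- rank_features(g, r = r)
    oracle <- rowSums(series_oracle(a, r))
    got <- ranking$score[match(g$genes, ranking$gene)]
    expect_equal(got, unname(oracle), tolerance = 1e-8)
  }
})

test_that("masked-out genes score exactly zero", {
  a <- random_graph_matrix(6, seed = 700)
  mask <- all_ones_mask(paste0("g", 1:6))
  mask$matrix[5, ] <- 0; mask$matrix[, 5] <- 0
  mask$matrix[6, ] <- 0; mask$matrix[, 6] <- 0
  masked <- apply_network_mask(as_relevance_graph(a), mask)
  ranking <- rank_features(masked)
  expect_identical(ranking$score[ranking$gene %in% c("g5", "g6")], c(0, 0))
  expect_true(all(ranking$isolated[ranking$gene %in% c("g5", "g6")]))
  expect_true(all(ranking$score[!ranking$isolated] > 0))
})

test_that("permuting the gene order permutes the scores identically", {
  a <- random_graph_matrix(7, seed = 701)
  genes <- paste0("g", 1:7)
  base <- rank_features(as_relevance_graph(a, genes))
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  permuted <- rank_features(as_relevance_graph(a[perm, perm], genes[perm]))
  expect_equal(permuted$score[match(genes, permuted$gene)],
               base$score[match(genes, base$gene)], tolerance = 1e-12)
})

test_that("raising a gene's relevance cannot lower its score", {
  score_of <- function(p1) {
    model <- structure(list(relevance = c(a = p1, b = 0.6),
                            features = c("a", "b")), class = "plsa_model")
    masked <- apply_network_mask(weight_graph(model), all_ones_mask(c("a", "b")))
    ranking <- rank_features(masked, r = 0.5)
    ranking$score[ranking$gene == "a"]
  }
  scores <- vapply(seq(0.1, 0.9, by = 0.1), score_of, numeric(1))
  expect_true(all(diff(scores) >= 0))
})
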
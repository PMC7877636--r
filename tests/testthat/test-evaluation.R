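two_cloud_records <- function(n_min = 6, n_maj = 24, sep = 6, p = 4,
                              seed = 52) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_min * p), n_min, p),
             matrix(rnorm(n_maj * p, mean = sep), n_maj, p))
  df <- tibble::as_tibble(as.data.frame(x))
  df$label <- rep(c("normal", "tumor"), c(n_min, n_maj))
  df
}

test_that("ADASYN fills the class gap and leaves the majority untouched", {
  rec <- two_cloud_records(n_min = 2, n_maj = 8, sep = 3)
  out <- suppressMessages(adasyn_oversample(rec, seed = 9))
  expect_equal(sum(out$.synthetic), 6)  # G = (8 - 2) * 1
  expect_equal(as.data.frame(out[!out$.synthetic, names(rec)]),
               as.data.frame(rec))
  balanced <- two_cloud_records(n_min = 10, n_maj = 10)
  out2 <- adasyn_oversample(balanced, seed = 9)
  expect_equal(sum(out2$.synthetic), 0)
  expect_equal(as.data.frame(out2[, names(balanced)]),
               as.data.frame(balanced))
})

test_that("every synthetic point interpolates a minority neighbor pair", {
  rec <- two_cloud_records(n_min = 6, n_maj = 20, sep = 2, seed = 53)
  out <- suppressMessages(adasyn_oversample(rec, k_neighbors = 3, seed = 10))
  syn <- as.matrix(out[out$.synthetic, 1:4])
  minority <- as.matrix(rec[rec$label == "normal", 1:4])
  on_some_segment <- apply(syn, 1, function(s) {
    for (i in seq_len(nrow(minority))) {
      for (j in seq_len(nrow(minority))) {
        if (i == j) next
        d <- minority[j, ] - minority[i, ]
        lambda <- sum((s - minority[i, ]) * d) / sum(d * d)
        proj <- minority[i, ] + lambda * d
        if (lambda >= -1e-9 && lambda <= 1 + 1e-9 &&
            sqrt(sum((s - proj)^2)) < 1e-8) {
          return(TRUE)
        }
      }
    }
    FALSE
  })
  expect_true(all(on_some_segment))
  # balance restored within 10%
  counts <- table(out$label)
  expect_true(min(counts) / max(counts) >= 0.9)
})

test_that("ADASYN rejects degenerate inputs", {
  rec <- two_cloud_records()
  one_class <- rec[rec$label == "tumor", ]
  expect_error(adasyn_oversample(one_class), "two classes")
})

test_that("F1 is the harmonic mean with a guarded zero case", {
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0.5, 0.5), 0.5)
  expect_equal(f1_score(1, 0.5), 2 / 3)
  expect_message(out <- f1_score(0, 0), "undefined")
  expect_equal(out, 0)
})

test_that("AUC computations are invariant to monotone score transforms", {
  set.seed(54)
  labels <- factor(rep(c("normal", "tumor"), c(12, 18)),
                   levels = c("normal", "tumor"))
  scores <- rnorm(30)
  base <- ncilfs:::rank_auc(scores, labels == "tumor")
  proc <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                         levels = c("normal", "tumor"),
                                         direction = "<", quiet = TRUE)))
  expect_equal(base, proc, tolerance = 1e-12)
  for (f in list(function(x) 3 * x + 2, exp, function(x) atan(x) - 5)) {
    expect_equal(ncilfs:::rank_auc(f(scores), labels == "tumor"), base,
                 tolerance = 1e-12)
  }
})

test_that("hypergeometric enrichment matches the pmf-summation oracle", {
  res <- hypergeometric_enrichment(paste0("g", 1:5), paste0("g", 1:5),
                                   paste0("g", 1:10))
  expect_equal(res$p_value, 0.00396825396825397, tolerance = 1e-12)
  res0 <- hypergeometric_enrichment(paste0("g", 6:10), paste0("g", 1:5),
                                    paste0("g", 1:10))
  expect_equal(res0$p_value, 1)
  full <- hypergeometric_enrichment(paste0("g", 1:10), paste0("g", 1:5),
                                    paste0("g", 1:10))
  expect_equal(full$p_value, 1)
  expect_equal(full$oncogenes_selected, 5)
  for (universe in c(5, 9, 14)) {
    genes <- paste0("g", seq_len(universe))
    for (n_onc in c(1, 3, universe)) {
      for (n_sel in c(1, 4, universe)) {
        sel <- genes[seq_len(n_sel)]
        onc <- genes[universe - seq_len(n_onc) + 1]
        k <- length(intersect(sel, onc))
        got <- hypergeometric_enrichment(sel, onc, genes)$p_value
        expect_equal(got, hyper_upper_oracle(k, universe, n_onc, n_sel),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("enrichment validates its inputs", {
  expect_error(hypergeometric_enrichment("a", "a", character(0)), "universe")
  expect_error(hypergeometric_enrichment("zz", "a", c("a", "b")), "outside")
})

cloud_dataset <- function(n_per_class = 30, n_genes = 10, sep = 4,
                          seed = 55) {
  set.seed(seed)
  n <- 2 * n_per_class
  cond <- rep(c("tumor", "normal"), each = n_per_class)
  shift <- outer(rep(sep, n_genes), as.numeric(cond == "tumor"))
  values <- 2^(matrix(rnorm(n_genes * n, 6), n_genes, n) + shift)
  dimnames(values) <- list(sprintf("G%02d", seq_len(n_genes)),
                           sprintf("S%02d", seq_len(n)))
  meta <- tibble::tibble(sample_id = colnames(values),
                         patient_id = colnames(values), condition = cond)
  expression_dataset(values, meta, units = "TPM")
}

test_that("separable clouds are classified nearly perfectly", {
  ds <- cloud_dataset()
  report <- run_cv_evaluation(ds, sprintf("G%02d", 1:10), top_k = 10,
                              repeats = 10, seed = 77)
  expect_gte(report$mean_auc, 0.99)
  expect_gte(report$mean_f1, 0.9)
  expect_true(all(report$per_repeat$auc >= 0 & report$per_repeat$auc <= 1))
})

test_that("a single repeat aggregates to itself", {
  ds <- cloud_dataset(n_per_class = 15, seed = 56)
  report <- run_cv_evaluation(ds, sprintf("G%02d", 1:10), top_k = 5,
                              repeats = 1, seed = 78)
  expect_equal(report$mean_auc, report$per_repeat$auc)
  expect_equal(report$mean_f1, report$per_repeat$f1)
  expect_equal(glance(report)$repeats, 1)
  expect_equal(nrow(tidy(report)), 1)
})

test_that("evaluation reports are reproducible and round-trip to TSV", {
  ds <- cloud_dataset(n_per_class = 15, seed = 57)
  r1 <- run_cv_evaluation(ds, sprintf("G%02d", 1:10), top_k = 6,
                          repeats = 3, seed = 79)
  r2 <- run_cv_evaluation(ds, sprintf("G%02d", 1:10), top_k = 6,
                          repeats = 3, seed = 79)
  expect_equal(r1$per_repeat, r2$per_repeat)
  dir <- withr::local_tempdir()
  write_evaluation_report(r1, file.path(dir, "a.tsv"))
  write_evaluation_report(r2, file.path(dir, "b.tsv"))
  expect_identical(readLines(file.path(dir, "a.tsv")),
                   readLines(file.path(dir, "b.tsv")))
})
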
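#' Fit a two-topic PLSA model to feature-token counts
#'
#' Probabilistic latent semantic analysis with exactly two latent topics,
#' interpreted as "relevant" and "irrelevant". The model factorizes the
#' conditional token distribution of each feature as
#' p(w | f) = sum_z p(w | z) p(z | f) and is fitted by EM, maximizing
#' sum_f sum_w n(f, w) log p(w | f). The best of `restarts` seeded runs (by
#' final log-likelihood) is kept. The relevant topic is the one whose token
#' distribution is most asymmetric between tumor and normal tokens:
#' S(z) = sum_bins | p((bin, tumor) | z) - p((bin, normal) | z) |.
#'
#' @param tokens A `token_counts` from [tokenize_features()].
#' @param seed Integer seed for the random initializations.
#' @param max_iter Maximum EM iterations per restart (default 200).
#' @param tol Stop when the log-likelihood gain per iteration falls below
#'   this (default 1e-6, on the absolute log-likelihood scale).
#' @param restarts Number of random restarts (default 3).
#' @return A `plsa_model`: list with `topic_given_feature` (features x 2,
#'   rows sum to 1), `token_given_topic` (tokens x 2, columns sum to 1),
#'   `relevant_topic` (1 or 2), `relevance` (named vector
#'   p(relevant | f)), `log_likelihood_trace`, and `converged`.
#' @export
fit_plsa <- function(tokens, seed = 1, max_iter = 200, tol = 1e-6,
                     restarts = 3) {
  n_mat <- tokens$counts
  storage.mode(n_mat) <- "double"
  stopifnot(all(n_mat >= 0), sum(n_mat) > 0)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- plsa_em(n_mat, seed = derive_seed(seed, r), max_iter = max_iter,
                   tol = tol)
    if (is.null(best) ||
        fit$log_likelihood > best$log_likelihood + 1e-12) {
      best <- fit
    }
  }
  rel <- relevant_topic_index(best$token_given_topic, tokens$vocabulary)
  relevance <- best$topic_given_feature[, rel]
  names(relevance) <- tokens$features
  if (!best$converged) {
    warn(sprintf("PLSA EM did not reach tol within %d iterations", max_iter))
  }
  structure(list(
    topic_given_feature = best$topic_given_feature,
    token_given_topic = best$token_given_topic,
    relevant_topic = rel,
    relevance = relevance,
    log_likelihood_trace = best$trace,
    converged = best$converged,
    features = tokens$features,
    vocabulary = tokens$vocabulary), class = "plsa_model")
}

# One seeded EM run. p_zf: features x 2 (rows sum to 1); p_wz: tokens x 2
# (columns sum to 1). Topic mixtures start uniform so that features with
# identical count rows keep identical posteriors (feature symmetry is
# broken only by the data); the topic symmetry is broken by the random
# (uniform-Dirichlet) token distributions.
plsa_em <- function(n_mat, seed, max_iter, tol) {
  n_f <- nrow(n_mat)
  n_w <- ncol(n_mat)
  set.seed(seed)
  p_zf <- matrix(0.5, n_f, 2)
  p_wz <- matrix(-log(runif(n_w * 2)), n_w, 2)
  p_wz <- sweep(p_wz, 2, colSums(p_wz), "/")
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step folded into M-step sufficient statistics:
    # q_z(f, w) = p(w|z) p(z|f) / p(w|f)
    mix1 <- outer(p_zf[, 1], p_wz[, 1])     # features x tokens, topic 1
    mix2 <- outer(p_zf[, 2], p_wz[, 2])
    denom <- mix1 + mix2
    denom[denom == 0] <- .Machine$double.xmin
    ll <- sum(n_mat * log(denom))
    trace <- c(trace, ll)
    resp1 <- n_mat * mix1 / denom           # n(f,w) q_z(f,w), z = 1, 2
    resp2 <- n_mat * mix2 / denom
    p_zf <- cbind(rowSums(resp1), rowSums(resp2))
    p_zf <- p_zf / pmax(rowSums(p_zf), .Machine$double.xmin)
    p_wz <- cbind(colSums(resp1), colSums(resp2))
    p_wz <- sweep(p_wz, 2, pmax(colSums(p_wz), .Machine$double.xmin), "/")
    if (ll - ll_old < tol && iter > 1) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(topic_given_feature = p_zf, token_given_topic = p_wz,
       log_likelihood = trace[length(trace)], trace = trace,
       converged = converged)
}

# Topic whose token distribution differs most between the tumor and normal
# copies of each bin.
relevant_topic_index <- function(p_wz, vocabulary) {
  asym <- vapply(1:2, function(z) {
    by_bin <- split(p_wz[, z], vocabulary$bin)
    cls <- split(vocabulary$class, vocabulary$bin)
    sum(vapply(seq_along(by_bin), function(b) {
      abs(sum(by_bin[[b]][cls[[b]] == "tumor"]) -
            sum(by_bin[[b]][cls[[b]] == "normal"]))
    }, numeric(1)))
  }, numeric(1))
  which.max(asym)
}

#' @export
print.plsa_model <- function(x, ...) {
  cat(sprintf(
    "<plsa_model> %d features, relevant topic %d, logLik %.4f (%d iter%s)\n",
    length(x$features), x$relevant_topic,
    x$log_likelihood_trace[length(x$log_likelihood_trace)],
    length(x$log_likelihood_trace),
    if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Per-feature relevance posteriors of a PLSA model
#'
#' @param x A `plsa_model`.
#' @param ... Unused.
#' @return Tibble with columns `gene` and `relevance` = p(relevant | gene).
#' @export
tidy.plsa_model <- function(x, ...) {
  tibble::tibble(gene = x$features, relevance = unname(x$relevance))
}

#' One-row summary of a PLSA fit
#'
#' @param x A `plsa_model`.
#' @param ... Unused.
#' @return Tibble with `log_likelihood`, `n_iter`, `converged`,
#'   `relevant_topic`.
#' @export
glance.plsa_model <- function(x, ...) {
  tibble::tibble(
    log_likelihood = x$log_likelihood_trace[length(x$log_likelihood_trace)],
    n_iter = length(x$log_likelihood_trace),
    converged = x$converged,
    relevant_topic = x$relevant_topic)
}
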
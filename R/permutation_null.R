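#' Permuted Bayesian correlation for one pair of entities
#'
#' Evaluates the permuted correlation used to build the null distribution:
#' only the cross-group covariance term of the numerator uses entity `j`'s
#' permuted group means; the within-sample covariance term (which reflects
#' the sum-to-one constraint, unaffected by the null hypothesis) and both
#' denominator variances are computed unpermuted.
#'
#' @inheritParams total_covariance
#' @param rho an integer permutation of `1:n` (or a permutation of the group
#'   labels) applied to `j`'s group means.
#' @export
permuted_bayesian_correlation <- function(post, groups, i, j, rho,
                                          include_within_sample_cov = FALSE) {
  i <- .resolve_entity(post, i); j <- .resolve_entity(post, j)
  if (i == j) stop("i and j must differ")
  mom <- group_moments(post, groups)
  n <- length(mom$groups)
  if (is.character(rho)) rho <- match(rho, mom$groups)
  rho <- as.integer(rho)
  if (length(rho) != n || anyNA(rho) || !setequal(rho, seq_len(n)))
    stop("rho must be a bijection on the ", n, " groups")
  di <- mom$group_mean[i, ] - mom$grand_mean[i]
  dj <- mom$group_mean[j, rho] - mom$grand_mean[j]
  num <- mean(di * dj)
  if (include_within_sample_cov) {
    wg <- vapply(seq_len(n), function(g)
      group_pair_covariance(post, groups, i, j, g), numeric(1))
    num <- num + mean(wg)
  }
  num / sqrt(total_variance(mom, i) * total_variance(mom, j))
}

# deterministic RNG stream derived from a base seed and a stream name;
# result stays below 2^31
.stream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483562
  as.integer((as.numeric(seed) %% 2147483562 * 48271 + h) %% 2147483562) + 1L
}

#' Build a pooled permutation null distribution
#'
#' For each of `K` repetitions every entity's group-mean vector receives an
#' independent uniform random permutation, and all pairwise permuted
#' correlations are pooled into one empirical null. Comparing two
#' independently permuted vectors is distributionally equivalent to comparing
#' an unpermuted entity against a permuted partner, while needing only
#' `O(K m)` permutations. The within-sample covariance term and the
#' denominator variances are permutation-invariant and precomputed once.
#'
#' @param x a `dirichlet_posterior` (Bayesian null) or `expression_matrix`
#'   (Pearson null).
#' @param groups a [group_assignment()].
#' @param K number of repetitions (default 100).
#' @param seed integer seed; the pooled values are reproducible given
#'   `(seed, K)`.
#' @param include_within_sample_cov Bayesian numerators only; default `FALSE`.
#' @return Object of class `permutation_null`: `values` (sorted pooled
#'   permuted correlations), `K`, `method`, `seed`, `entity_ids`,
#'   `n_masked_pairs`.
#' @export
build_null <- function(x, groups, K = 100, seed = 1,
                       include_within_sample_cov = FALSE) {
  if (K < 1) stop("K must be at least 1")
  if (inherits(x, "dirichlet_posterior")) {
    method <- "bayesian"
    mom <- group_moments(x, groups)
    gm <- mom$group_mean
    tv <- rowMeans((gm - mom$grand_mean)^2) + rowMeans(mom$group_var)
    W <- if (include_within_sample_cov)
      .within_sample_cov_matrix(x, groups) else NULL
  } else if (inherits(x, "expression_matrix")) {
    method <- "pearson"
    idx <- .group_index(groups, x$sample_ids)
    gm <- vapply(idx, function(cols)
      rowMeans(x$values[, cols, drop = FALSE]), numeric(nrow(x$values)))
    tv <- rowMeans((gm - rowMeans(gm))^2)
    W <- NULL
  } else stop("x must be a dirichlet_posterior or an expression_matrix")
  m <- nrow(gm)
  n <- ncol(gm)
  defined <- tv > 0
  denom <- sqrt(outer(tv, tv))
  ut <- upper.tri(denom)
  keep <- ut & outer(defined, defined, "&")
  n_masked <- sum(ut) - sum(keep)
  set.seed(.stream_seed(seed, sprintf("null-%s-K%d", method, K)))
  values <- vector("list", K)
  for (k in seq_len(K)) {
    P <- t(apply(gm, 1L, function(v) v[sample.int(n)]))
    D <- P - rowMeans(gm)   # grand mean is permutation-invariant
    num <- tcrossprod(D) / n
    if (!is.null(W)) num <- num + W
    values[[k]] <- (num / denom)[keep]
  }
  structure(list(values = sort(unlist(values)), K = K, method = method,
                 seed = seed, entity_ids = rownames(gm),
                 include_within_sample_cov = include_within_sample_cov,
                 n_masked_pairs = n_masked),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "permutation_null (%s): %d pooled values (K = %d, %d masked pairs)\n",
    x$method, length(x$values), x$K, x$n_masked_pairs))
  invisible(x)
}

#' Tail probability of the pooled null
#'
#' \eqn{P(r \ge t)}: the fraction of pooled permuted correlations at least
#' `t` (inclusive). Nonincreasing and right-continuous in `t`.
#'
#' @param null a [build_null()] result.
#' @param t threshold(s).
#' @export
tail_probability <- function(null, t) {
  stopifnot(inherits(null, "permutation_null"))
  N <- length(null$values)
  # findInterval with left.open counts pooled values strictly below t
  vapply(t, function(tt)
    (N - findInterval(tt, null$values, left.open = TRUE)) / N,
    numeric(1))
}

# FP/TP/FDR arithmetic shared by the error-estimate entry points
.error_rates <- function(n_links, fp) {
  tp <- max(n_links - fp, 0)
  if (n_links > 0) list(fdr = min(fp / n_links, 1), tp = tp,
                        fdr_defined = TRUE)
  else list(fdr = NA_real_, tp = 0, fdr_defined = FALSE)
}

#' False-positive, true-positive and FDR estimates at a threshold
#'
#' Counts observed links `N_t` (defined pairs i < j with `r >= t`), estimates
#' the expected number of false positives as
#' \eqn{FP_t = P(r \ge t)\, m(m-1)/2}, true positives as
#' \eqn{max(N_t - FP_t, 0)}, and the false discovery rate as
#' \eqn{min(FP_t/N_t, 1)} (undefined when `N_t = 0`). Masked pairs are
#' excluded from both the observed count and the pair budget.
#'
#' @param null a [build_null()] result.
#' @param observed a `correlation_result` over the same entities and method.
#' @param t correlation threshold.
#' @return Object of class `network_error_estimate`: `threshold`, `n_links`,
#'   `fp`, `tp`, `fdr`, `fdr_defined`, `n_pairs`.
#' @export
network_error_estimates <- function(null, observed, t) {
  stopifnot(inherits(null, "permutation_null"),
            inherits(observed, "correlation_result"))
  if (!identical(null$entity_ids, observed$entity_ids))
    stop("null and observed correlations cover different entity sets")
  if (!identical(null$method, observed$method))
    stop("null method (", null$method, ") does not match observed (",
         observed$method, ")")
  vals <- observed$r[upper.tri(observed$r)]
  vals <- vals[!is.na(vals)]
  n_pairs <- length(vals)
  n_links <- sum(vals >= t)
  fp <- tail_probability(null, t) * n_pairs
  er <- .error_rates(n_links, fp)
  structure(list(threshold = t, n_links = n_links, fp = fp, tp = er$tp,
                 fdr = er$fdr, fdr_defined = er$fdr_defined,
                 n_pairs = n_pairs),
            class = "network_error_estimate")
}

#' @export
print.network_error_estimate <- function(x, ...) {
  cat(sprintf(
    "t = %g: N = %d links, FP = %.2f, TP = %.2f, FDR = %s\n",
    x$threshold, x$n_links, x$fp, x$tp,
    if (x$fdr_defined) sprintf("%.4f", x$fdr) else "undefined"))
  invisible(x)
}

#' Error-estimate table over a threshold grid
#'
#' @inheritParams network_error_estimates
#' @param thresholds numeric vector of thresholds.
#' @return data.frame with one row per threshold:
#'   `t`, `n_links`, `fp`, `tp`, `fdr`.
#' @export
error_estimate_table <- function(null, observed, thresholds) {
  rows <- lapply(thresholds, function(t)
    network_error_estimates(null, observed, t))
  data.frame(t = thresholds,
             n_links = vapply(rows, `[[`, numeric(1), "n_links"),
             fp = vapply(rows, `[[`, numeric(1), "fp"),
             tp = vapply(rows, `[[`, numeric(1), "tp"),
             fdr = vapply(rows, `[[`, numeric(1), "fdr"))
}

#' Write a permutation null (values file + JSON sidecar)
#'
#' @param null a [build_null()] result.
#' @param prefix output path prefix; writes `<prefix>.values.txt` and
#'   `<prefix>.json`.
#' @export
write_null <- function(null, prefix) {
  writeLines(format(null$values, digits = 17, trim = TRUE, scientific = TRUE),
             paste0(prefix, ".values.txt"))
  jsonlite::write_json(
    list(K = null$K, method = null$method, seed = null$seed,
         n_values = length(null$values),
         n_masked_pairs = null$n_masked_pairs,
         include_within_sample_cov = null$include_within_sample_cov),
    paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}
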
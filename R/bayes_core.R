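#' Dirichlet posterior over idealized expression fractions
#'
#' Under the multinomial read-sampling model, a Dirichlet prior with
#' concentration `prior_value` per entity (default \eqn{\alpha^0 = 1/m},
#' which has provably low bias for low-count entities) yields the conjugate
#' posterior \eqn{\alpha_{igs} = \alpha^0_{igs} + R_{igs}} for each sample
#' independently. All downstream moments are functions of `alpha` and the
#' per-sample totals \eqn{\alpha_{gs} = \sum_i \alpha_{igs}}.
#'
#' @param cm a [count_matrix()].
#' @param prior_value positive scalar prior concentration applied to every
#'   entity, or a length-`m` positive vector of per-entity priors. Default
#'   `1/m`.
#' @return Object of class `dirichlet_posterior`: `alpha` (m x samples),
#'   `alpha_totals`, `prior_value`, plus the entity/sample ids.
#' @export
posterior_from_counts <- function(cm, prior_value = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  m <- nrow(cm$counts)
  if (is.null(prior_value)) prior_value <- 1 / m
  if (!is.numeric(prior_value) || any(prior_value <= 0))
    stop("prior_value must be positive")
  if (!length(prior_value) %in% c(1L, m))
    stop("prior_value must be a scalar or one value per entity")
  alpha <- cm$counts + prior_value
  structure(list(alpha = alpha,
                 alpha_totals = colSums(alpha),
                 prior_value = prior_value,
                 entity_ids = cm$entity_ids,
                 sample_ids = cm$sample_ids),
            class = "dirichlet_posterior")
}

.resolve_entity <- function(post, i) {
  if (is.character(i)) i <- match(i, post$entity_ids)
  if (anyNA(i) || any(i < 1) || any(i > nrow(post$alpha)))
    stop("unknown entity")
  i
}

.resolve_sample <- function(post, s) {
  if (is.character(s)) s <- match(s, post$sample_ids)
  if (anyNA(s) || any(s < 1) || any(s > ncol(post$alpha)))
    stop("unknown sample")
  s
}

#' Posterior mean of one entity's fraction in one sample
#'
#' \eqn{E_u(p_{igs}) = \alpha_{igs}/\alpha_{gs}}.
#'
#' @param post a [posterior_from_counts()] result.
#' @param i entity index or id.
#' @param gs sample index or id.
#' @export
sample_mean <- function(post, i, gs) {
  i <- .resolve_entity(post, i); gs <- .resolve_sample(post, gs)
  unname(post$alpha[i, gs] / post$alpha_totals[gs])
}

#' Posterior variance of one entity's fraction in one sample
#'
#' \eqn{var_u(p_{igs}) =
#'   \alpha_{igs}(\alpha_{gs}-\alpha_{igs}) / (\alpha_{gs}^2(\alpha_{gs}+1))}.
#'
#' @inheritParams sample_mean
#' @export
sample_variance <- function(post, i, gs) {
  i <- .resolve_entity(post, i); gs <- .resolve_sample(post, gs)
  a <- post$alpha[i, gs]; a0 <- post$alpha_totals[gs]
  unname(a * (a0 - a) / (a0^2 * (a0 + 1)))
}

#' Posterior covariance between two entities' fractions in one sample
#'
#' \eqn{cov_u(p_{igs}, p_{jgs}) =
#'   -\alpha_{igs}\alpha_{jgs} / (\alpha_{gs}^2(\alpha_{gs}+1))}; always
#' nonpositive, reflecting the sum-to-one constraint on fractions within a
#' sample.
#'
#' @inheritParams sample_mean
#' @param j a second entity, distinct from `i`.
#' @export
sample_pair_covariance <- function(post, i, j, gs) {
  i <- .resolve_entity(post, i); j <- .resolve_entity(post, j)
  gs <- .resolve_sample(post, gs)
  if (any(i == j)) stop("i and j must differ; use sample_variance for i = j")
  a0 <- post$alpha_totals[gs]
  unname(-post$alpha[i, gs] * post$alpha[j, gs] / (a0^2 * (a0 + 1)))
}

#' Group-level posterior moments
#'
#' Averages per-sample posterior moments into group-level beliefs: the group
#' mean \eqn{E_u(p_{ig})} is the average of sample means over the group's
#' \eqn{n_g} samples; because beliefs about different samples are independent,
#' the group variance is the sum of sample variances divided by \eqn{n_g^2}.
#' The grand mean weights groups equally: \eqn{E_u(p_i) = (1/n)\sum_g
#' E_u(p_{ig})}.
#'
#' @param post a [posterior_from_counts()] result.
#' @param groups a [group_assignment()] covering `post`'s samples.
#' @return Object of class `group_moments`: `group_mean` and `group_var`
#'   (m x n matrices, columns in group level order), `grand_mean`, `groups`.
#' @export
group_moments <- function(post, groups) {
  stopifnot(inherits(post, "dirichlet_posterior"),
            inherits(groups, "group_assignment"))
  idx <- .group_index(groups, post$sample_ids)
  M <- sweep(post$alpha, 2L, post$alpha_totals, "/")
  a0 <- post$alpha_totals
  V <- post$alpha * sweep(-post$alpha, 2L, a0, "+") /
    rep(a0^2 * (a0 + 1), each = nrow(post$alpha))
  n <- length(idx)
  gm <- matrix(0, nrow(M), n, dimnames = list(post$entity_ids, names(idx)))
  gv <- gm
  for (g in seq_len(n)) {
    cols <- idx[[g]]
    ng <- length(cols)
    gm[, g] <- rowSums(M[, cols, drop = FALSE]) / ng
    gv[, g] <- rowSums(V[, cols, drop = FALSE]) / ng^2
  }
  structure(list(group_mean = gm, group_var = gv,
                 grand_mean = rowMeans(gm),
                 groups = names(idx),
                 entity_ids = post$entity_ids),
            class = "group_moments")
}

#' Within-group posterior covariance between two entities
#'
#' \eqn{cov_u(p_{ig}, p_{jg}) = (1/n_g^2)\sum_s cov_u(p_{igs}, p_{jgs})};
#' cross-sample terms vanish because beliefs about different samples are
#' independent. Always nonpositive.
#'
#' @inheritParams group_moments
#' @param i,j distinct entity indices or ids.
#' @param g group label or index.
#' @export
group_pair_covariance <- function(post, groups, i, j, g) {
  i <- .resolve_entity(post, i); j <- .resolve_entity(post, j)
  if (i == j) stop("i and j must differ")
  if (is.numeric(g)) g <- groups$groups[g]
  cols <- which(as.character(groups$group_of[post$sample_ids]) == g)
  if (!length(cols)) stop("unknown group: ", g)
  a0 <- post$alpha_totals[cols]
  sum(-post$alpha[i, cols] * post$alpha[j, cols] / (a0^2 * (a0 + 1))) /
    length(cols)^2
}

#' Total variance of an entity's group expression
#'
#' Law of Total Variance over group identity (equal 1/n weights) and
#' posterior uncertainty:
#' \eqn{var_{g,u}(p_{ig}) = \sum_g (1/n)(E_u(p_{ig})-E_u(p_i))^2 +
#'   \sum_g (1/n) var_u(p_{ig})}.
#'
#' @param moments a [group_moments()] result.
#' @param i entity index or id.
#' @export
total_variance <- function(moments, i) {
  if (is.character(i)) i <- match(i, moments$entity_ids)
  d <- moments$group_mean[i, ] - moments$grand_mean[i]
  mean(d^2) + mean(moments$group_var[i, ])
}

# m x m matrix of E_g(cov_u(p_ig, p_jg)) for all pairs (diagonal meaningless)
.within_sample_cov_matrix <- function(post, groups) {
  idx <- .group_index(groups, post$sample_ids)
  n <- length(idx)
  a0 <- post$alpha_totals
  # cov_u(p_igs, p_jgs) = -(alpha_i * alpha_j) * w_s with w_s = 1/(a0^2 (a0+1));
  # sample s in group g contributes with overall weight 1/(n * n_g(s)^2)
  w <- 1 / (a0^2 * (a0 + 1))
  for (g in seq_len(n)) {
    cols <- idx[[g]]
    w[cols] <- w[cols] / (n * length(cols)^2)
  }
  B <- sweep(post$alpha, 2L, sqrt(w), "*")
  -tcrossprod(B)
}

#' Total covariance between two entities' group expression
#'
#' Law of Total Covariance: the cross-group covariance of posterior group
#' means plus (optionally) the mean within-group posterior covariance
#' \eqn{E_g(cov_u(p_{ig}, p_{jg}))}. The second term is typically orders of
#' magnitude smaller and may be skipped (`include_within_sample_cov = FALSE`)
#' for a large speed gain with virtually identical results.
#'
#' @inheritParams group_pair_covariance
#' @param moments a [group_moments()] result.
#' @param include_within_sample_cov include the within-sample covariance term?
#' @export
total_covariance <- function(moments, post, groups, i, j,
                             include_within_sample_cov = TRUE) {
  i <- .resolve_entity(post, i); j <- .resolve_entity(post, j)
  if (i == j) stop("i and j must differ; use total_variance")
  di <- moments$group_mean[i, ] - moments$grand_mean[i]
  dj <- moments$group_mean[j, ] - moments$grand_mean[j]
  out <- mean(di * dj)
  if (include_within_sample_cov) {
    n <- length(moments$groups)
    wg <- vapply(seq_len(n), function(g)
      group_pair_covariance(post, groups, i, j, g), numeric(1))
    out <- out + mean(wg)
  }
  out
}

.correlation_result <- function(r, method, include_within_sample_cov,
                                defined) {
  r[!defined, ] <- NA_real_
  r[, !defined] <- NA_real_
  diag(r) <- 1
  structure(list(r = r, method = method,
                 include_within_sample_cov = include_within_sample_cov,
                 defined = defined,
                 entity_ids = rownames(r)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "correlation_result (%s): %d entities, %d masked (undefined)\n",
    x$method, length(x$defined), sum(!x$defined)))
  invisible(x)
}

#' Bayesian grouped correlation matrix
#'
#' The uncertainty-moderated correlation
#' \eqn{r^B_{ij} = cov_{g,u}(p_{ig}, p_{jg}) /
#'   \sqrt{var_{g,u}(p_{ig})\, var_{g,u}(p_{jg})}}: a Pearson-style
#' correlation of posterior group means whose variance and covariance terms
#' additionally integrate over posterior uncertainty. High uncertainty
#' inflates the denominator, moderating the correlation toward zero.
#'
#' Entities whose total variance is zero are masked (`NA`), never reported as
#' 0. The diagonal is set to 1 by convention; self-pairs are never edges.
#'
#' @inheritParams group_moments
#' @param include_within_sample_cov include the (small, nonpositive)
#'   within-sample covariance term \eqn{E_g(cov_u)} in the numerator? Default
#'   `FALSE`, the fast path.
#' @return A `correlation_result` with `method = "bayesian"`.
#' @export
bayesian_correlation_matrix <- function(post, groups,
                                        include_within_sample_cov = FALSE) {
  stopifnot(inherits(post, "dirichlet_posterior"))
  if (groups$n < 2L)
    stop("at least 2 groups are required for a cross-group correlation")
  mom <- group_moments(post, groups)
  n <- length(mom$groups)
  D <- mom$group_mean - mom$grand_mean
  num <- tcrossprod(D) / n
  tv <- rowMeans(D^2) + rowMeans(mom$group_var)
  if (include_within_sample_cov)
    num <- num + .within_sample_cov_matrix(post, groups)
  defined <- tv > 0
  denom <- sqrt(outer(tv, tv))
  r <- num / denom
  .correlation_result(r, "bayesian", include_within_sample_cov, defined)
}

#' Classical grouped Pearson correlation matrix
#'
#' The baseline of the classical Relevance Networks algorithm on grouped
#' data: within-group mean expression per entity, then the Pearson
#' correlation of those group means across the n groups with equal 1/n
#' weights. Scale-invariant, so fraction and RPM units give identical
#' results. Entities with zero cross-group variance are masked.
#'
#' @param expr an `expression_matrix` (see [normalize_counts()]).
#' @param groups a [group_assignment()].
#' @return A `correlation_result` with `method = "pearson"`.
#' @export
pearson_group_correlation_matrix <- function(expr, groups) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (groups$n < 2L)
    stop("at least 2 groups are required for a cross-group correlation")
  idx <- .group_index(groups, expr$sample_ids)
  n <- length(idx)
  gm <- vapply(idx, function(cols)
    rowMeans(expr$values[, cols, drop = FALSE]), numeric(nrow(expr$values)))
  D <- gm - rowMeans(gm)
  num <- tcrossprod(D) / n
  v <- rowMeans(D^2)
  defined <- v > 0
  r <- num / sqrt(outer(v, v))
  rownames(r) <- colnames(r) <- expr$entity_ids
  .correlation_result(r, "pearson", FALSE, defined)
}

#' Write a correlation matrix
#'
#' Dense TSV (entity ids as header and first column) or long-format pair list
#' (`entity_i`, `entity_j`, `r` for i < j; masked pairs omitted).
#'
#' @param corr a `correlation_result`.
#' @param path output path.
#' @param format `"matrix"` or `"pairs"`.
#' @export
write_correlation <- function(corr, path, format = c("matrix", "pairs")) {
  format <- match.arg(format)
  if (format == "matrix") {
    df <- data.frame(entity_id = corr$entity_ids, corr$r,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.table(correlation_pairs(corr), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Long-format pair list of a correlation matrix
#'
#' @param corr a `correlation_result`.
#' @return data.frame (`entity_i`, `entity_j`, `r`) over defined pairs i < j.
#' @export
correlation_pairs <- function(corr) {
  m <- length(corr$entity_ids)
  ut <- which(upper.tri(corr$r), arr.ind = TRUE)
  keep <- !is.na(corr$r[ut])
  ut <- ut[keep, , drop = FALSE]
  data.frame(entity_i = corr$entity_ids[ut[, 1L]],
             entity_j = corr$entity_ids[ut[, 2L]],
             r = corr$r[ut])
}

#' Read a dense correlation TSV written by [write_correlation()]
#'
#' @param path path to the matrix TSV.
#' @param method method label to attach.
#' @return A `correlation_result` (entities whose rows are all `NA` are
#'   marked undefined).
#' @export
read_correlation <- function(path, method = c("bayesian", "pearson")) {
  method <- match.arg(method)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  r <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(r) <- tab[[1L]]
  defined <- !apply(is.na(r) & row(r) != col(r), 1L, all)
  .correlation_result(r, method, FALSE, defined)
}
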
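test_that("posterior construction adds the 1/m prior to counts", {
  cm <- count_matrix(matrix(c(3, 1), 2, 1), c("a", "b"), "s1")
  post <- posterior_from_counts(cm)
  expect_equal(unname(post$alpha[, 1]), c(3.5, 1.5))
  expect_equal(unname(post$alpha_totals), 5)

  cm0 <- count_matrix(matrix(0, 4, 1))
  p0 <- posterior_from_counts(cm0)
  expect_equal(unname(p0$alpha[, 1]), rep(0.25, 4))
  expect_equal(unname(p0$alpha_totals), 1)
  expect_equal(unname(sapply(1:4, function(i) sample_mean(p0, i, 1))),
               rep(0.25, 4))

  expect_error(posterior_from_counts(cm, prior_value = 0), "positive")
  expect_error(posterior_from_counts(cm, prior_value = -1), "positive")
})

test_that("per-sample posterior moments match the closed forms and each other", {
  cm <- count_matrix(matrix(c(3, 1), 2, 1), c("a", "b"), "s1")
  post <- posterior_from_counts(cm)
  expect_equal(sample_mean(post, 1, 1), 0.7)
  expect_equal(sample_variance(post, 1, 1), 3.5 * 1.5 / (25 * 6))
  expect_equal(sample_pair_covariance(post, 1, 2, 1), -3.5 * 1.5 / (25 * 6))
  expect_error(sample_pair_covariance(post, 1, 1, 1), "differ")

  # m = 1: the lone fraction is exactly 1, so zero variance
  p1 <- posterior_from_counts(count_matrix(matrix(5, 1, 1)))
  expect_equal(sample_variance(p1, 1, 1), 0)
})

test_that("posterior moments agree with Monte-Carlo Dirichlet draws", {
  cm <- count_matrix(matrix(c(7, 0, 2, 31, 1), 5, 1))
  post <- posterior_from_counts(cm)
  set.seed(42)
  ndraw <- 200000
  draws <- rdirichlet_oracle(ndraw, post$alpha[, 1])
  for (i in c(1, 2, 4)) {
    mu <- mean(draws[i, ]); v <- var(draws[i, ])
    se_mu <- sd(draws[i, ]) / sqrt(ndraw)
    expect_lt(abs(sample_mean(post, i, 1) - mu), 3 * se_mu)
    se_v <- sd((draws[i, ] - mu)^2) / sqrt(ndraw)
    expect_lt(abs(sample_variance(post, i, 1) - v), 3 * se_v)
  }
  prod_dev <- (draws[1, ] - mean(draws[1, ])) * (draws[3, ] - mean(draws[3, ]))
  expect_lt(abs(sample_pair_covariance(post, 1, 3, 1) - mean(prod_dev)),
            3 * sd(prod_dev) / sqrt(ndraw))
})

test_that("conservation: sample means sum to 1, covariances to -variance", {
  for (seed in 1:3) {
    fx <- random_grouped_fixture(8, 3, 4, seed)
    post <- posterior_from_counts(fx$cm)
    for (s in seq_along(fx$cm$sample_ids)) {
      expect_lt(abs(sum(sapply(1:8, function(i) sample_mean(post, i, s))) - 1),
                1e-9)
      for (i in 1:3) {
        covs <- sum(sapply(setdiff(1:8, i), function(j)
          sample_pair_covariance(post, i, j, s)))
        expect_lt(abs(covs + sample_variance(post, i, s)), 1e-9)
      }
    }
  }
})

test_that("group moments match naive loops and scale with group size", {
  fx <- random_grouped_fixture(5, 2, 3, seed = 21)
  post <- posterior_from_counts(fx$cm)
  mom <- group_moments(post, fx$ga)
  cols <- group_cols_of(fx$cm, fx$ga)
  for (i in 1:5) for (g in 1:2) {
    expect_equal(mom$group_mean[i, g],
                 oracle_group_mean(post$alpha, i, cols[[g]]))
    expect_equal(mom$group_var[i, g],
                 oracle_group_var(post$alpha, i, cols[[g]]))
  }
  expect_equal(unname(mom$grand_mean),
               unname(rowMeans(mom$group_mean)))

  # single-sample group: group moments are the sample moments
  cm1 <- count_matrix(matrix(c(4, 6, 1, 2), 2, 2))
  ga1 <- group_assignment(setNames(c("g1", "g2"), cm1$sample_ids))
  post1 <- posterior_from_counts(cm1)
  mom1 <- group_moments(post1, ga1)
  expect_equal(mom1$group_mean[1, 1], sample_mean(post1, 1, 1))
  expect_equal(mom1$group_var[2, 2], sample_variance(post1, 2, 2))

  # duplicating a sample into a 2-sample group halves the group variance
  cm2 <- count_matrix(cbind(c(4, 6), c(4, 6)))
  ga2 <- group_assignment(setNames(c("g", "g"), cm2$sample_ids))
  post2 <- posterior_from_counts(cm2)
  expect_equal(group_moments(post2, ga2)$group_var[1, 1],
               sample_variance(post2, 1, 1) / 2)
})

test_that("group pair covariance is nonpositive and matches the double sum", {
  fx <- random_grouped_fixture(6, 3, 4, seed = 8)
  post <- posterior_from_counts(fx$cm)
  cols <- group_cols_of(fx$cm, fx$ga)
  for (g in 1:3) for (pair in list(c(1, 2), c(3, 6), c(4, 5))) {
    got <- group_pair_covariance(post, fx$ga, pair[1], pair[2], g)
    expect_lte(got, 0)
    expect_equal(got, oracle_group_cov(post$alpha, pair[1], pair[2],
                                       cols[[g]]))
  }
  # single-sample group reduces to the within-sample covariance
  cm1 <- count_matrix(cbind(c(4, 6, 2), c(1, 1, 1)))
  ga1 <- group_assignment(setNames(c("g1", "g2"), cm1$sample_ids))
  post1 <- posterior_from_counts(cm1)
  expect_equal(group_pair_covariance(post1, ga1, 1, 2, "g1"),
               sample_pair_covariance(post1, 1, 2, 1))
  expect_error(group_pair_covariance(post1, ga1, 2, 2, "g1"), "differ")
})

test_that("total variance and covariance match brute-force evaluation", {
  fx <- random_grouped_fixture(4, 3, 2, seed = 13)
  post <- posterior_from_counts(fx$cm)
  mom <- group_moments(post, fx$ga)
  cols <- group_cols_of(fx$cm, fx$ga)
  for (i in 1:4)
    expect_equal(total_variance(mom, i),
                 oracle_total_variance(post$alpha, i, cols))
  for (pair in list(c(1, 2), c(2, 4), c(3, 4))) {
    for (w in c(TRUE, FALSE))
      expect_equal(total_covariance(mom, post, fx$ga, pair[1], pair[2], w),
                   oracle_total_covariance(post$alpha, pair[1], pair[2],
                                           cols, w))
  }
  # total variance dominates its cross-group term
  for (i in 1:4) {
    cross <- mean((mom$group_mean[i, ] - mom$grand_mean[i])^2)
    expect_gte(total_variance(mom, i), cross)
  }
  # identical count rows: cross-group covariance term equals the variance term
  cmI <- count_matrix(rbind(c(5, 9, 2), c(5, 9, 2), c(10, 4, 8)))
  gaI <- group_assignment(setNames(paste0("g", 1:3), cmI$sample_ids))
  postI <- posterior_from_counts(cmI)
  momI <- group_moments(postI, gaI)
  expect_equal(total_covariance(momI, postI, gaI, 1, 2, FALSE),
               mean((momI$group_mean[1, ] - momI$grand_mean[1])^2))
})

test_that("prior-only data leaves only the uncertainty variance term", {
  cm <- count_matrix(matrix(0, 4, 6))
  ga <- group_assignment(setNames(rep(c("a", "b", "c"), each = 2),
                                  cm$sample_ids))
  post <- posterior_from_counts(cm)
  mom <- group_moments(post, ga)
  for (i in 1:4)  # all group means are 1/m: the cross-group term vanishes
    expect_equal(total_variance(mom, i), mean(mom$group_var[i, ]))
})

test_that("full correlation matrix matches the per-pair oracle", {
  fx <- random_grouped_fixture(6, 4, 3, seed = 31)
  post <- posterior_from_counts(fx$cm)
  cols <- group_cols_of(fx$cm, fx$ga)
  for (w in c(TRUE, FALSE)) {
    corr <- bayesian_correlation_matrix(post, fx$ga,
                                        include_within_sample_cov = w)
    expect_true(isSymmetric(corr$r))
    expect_true(all(abs(corr$r[!is.na(corr$r)]) <= 1 + 1e-9))
    expect_equal(unname(diag(corr$r)), rep(1, 6))
    for (i in 1:5) for (j in (i + 1):6)
      expect_equal(corr$r[i, j],
                   oracle_bayes_r(post$alpha, i, j, cols, w),
                   tolerance = 1e-10)
  }
  expect_error(bayesian_correlation_matrix(
    post, group_assignment(setNames(rep("g", 12), fx$cm$sample_ids))),
    "2 groups")
})

test_that("results are invariant to entity and sample order", {
  fx <- random_grouped_fixture(5, 3, 4, seed = 77)
  post <- posterior_from_counts(fx$cm)
  r1 <- bayesian_correlation_matrix(post, fx$ga, TRUE)$r
  set.seed(1)
  pe <- sample(5)
  # permute entities and, within the matrix, samples (groups unchanged)
  ps <- sample(ncol(fx$cm$counts))
  cm2 <- count_matrix(fx$cm$counts[pe, ps])
  ga2 <- group_assignment(fx$ga$group_of[fx$cm$sample_ids[ps]])
  r2 <- bayesian_correlation_matrix(posterior_from_counts(cm2), ga2, TRUE)$r
  expect_equal(r2[fx$cm$entity_ids, fx$cm$entity_ids], r1,
               tolerance = 1e-12)
})

test_that("grouped Pearson correlations behave as textbook Pearson on group means", {
  fx <- random_grouped_fixture(7, 4, 3, seed = 19)
  expr <- normalize_counts(fx$cm, "RPM")
  corr <- pearson_group_correlation_matrix(expr, fx$ga)
  # independent oracle: stats::cor of the within-group mean vectors
  cols <- group_cols_of(fx$cm, fx$ga)
  gm <- sapply(cols, function(cc) rowMeans(expr$values[, cc, drop = FALSE]))
  expect_equal(unname(corr$r), unname(cor(t(gm))), tolerance = 1e-12)

  # exact proportionality gives r = 1 regardless of scale
  vals <- matrix(c(10, 20, 5, 40), 1)
  cm2 <- count_matrix(rbind(vals, 2 * vals, c(9, 1, 7, 3)))
  ga2 <- group_assignment(setNames(c("a", "a", "b", "b"), cm2$sample_ids))
  r2 <- pearson_group_correlation_matrix(normalize_counts(cm2, "fraction"),
                                         ga2)
  expect_equal(r2$r[1, 2], 1)

  # both entities expressed in exactly one (shared) group: two effective
  # values, perfect correlation
  cm3 <- count_matrix(rbind(c(2, 0, 0), c(5, 0, 0), c(1, 8, 4)))
  ga3 <- group_assignment(setNames(c("a", "b", "c"), cm3$sample_ids))
  r3 <- pearson_group_correlation_matrix(normalize_counts(cm3, "RPM"), ga3)
  expect_equal(r3$r[1, 2], 1)

  # zero-variance entities are masked, not zeroed (equal depths keep the
  # first entity's RPM constant across groups)
  cm4 <- count_matrix(rbind(c(2, 2), c(3, 5), c(5, 3)))
  ga4 <- group_assignment(setNames(c("a", "b"), cm4$sample_ids))
  r4 <- pearson_group_correlation_matrix(normalize_counts(cm4, "fraction"),
                                         ga4)
  expect_false(r4$defined[1])
  expect_true(is.na(r4$r[1, 2]))
})

test_that("uncertainty moderates correlations toward zero", {
  fx <- structured_fixture(10, 5, 3, depth = 2000, seed = 9)
  post <- posterior_from_counts(fx$cm)
  mom <- group_moments(post, fx$ga)
  rB <- bayesian_correlation_matrix(post, fx$ga, FALSE)$r
  # plug-in Pearson on the posterior group means (no uncertainty term)
  plug <- cor(t(mom$group_mean))
  ut <- upper.tri(rB)
  expect_true(all(abs(rB[ut]) <= abs(plug[ut]) + 1e-12))
})

test_that("skipping the within-sample covariance term is a faithful fast path", {
  fx <- structured_fixture(12, 5, 4, depth = 5000, seed = 23)
  post <- posterior_from_counts(fx$cm)
  full <- bayesian_correlation_matrix(post, fx$ga, TRUE)$r
  fast <- bayesian_correlation_matrix(post, fx$ga, FALSE)$r
  expect_lt(max(abs(full - fast)), 1e-3)
})

test_that("correlation output round-trips through TSV formats", {
  fx <- random_grouped_fixture(5, 3, 2, seed = 55)
  corr <- bayesian_correlation_matrix(posterior_from_counts(fx$cm), fx$ga)
  d <- withr::local_tempdir()
  write_correlation(corr, file.path(d, "m.tsv"), "matrix")
  back <- read_correlation(file.path(d, "m.tsv"), "bayesian")
  expect_equal(back$r, corr$r, tolerance = 1e-12)
  write_correlation(corr, file.path(d, "p.tsv"), "pairs")
  pairs <- read.delim(file.path(d, "p.tsv"))
  expect_equal(nrow(pairs), choose(5, 2))
  expect_true(all(pairs$entity_i < pairs$entity_j))
})
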
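# Independent naive-loop oracles and fixture generators. These deliberately
# re-derive every quantity from scalar formulas with explicit loops, so they
# share no code path with the vectorized implementation they check.

rdirichlet_oracle <- function(ndraw, alpha) {
  x <- matrix(stats::rgamma(ndraw * length(alpha), shape = alpha),
              nrow = length(alpha))
  sweep(x, 2L, colSums(x), "/")
}

random_cm <- function(m, S, seed, max_count = 50) {
  set.seed(seed)
  count_matrix(matrix(rpois(m * S, lambda = runif(m, 1, max_count)), m, S))
}

random_grouped_fixture <- function(m, n_groups, per_group, seed,
                                   max_count = 50) {
  cm <- random_cm(m, n_groups * per_group, seed, max_count)
  ga <- group_assignment(setNames(rep(paste0("g", seq_len(n_groups)),
                                      each = per_group),
                                  cm$sample_ids))
  list(cm = cm, ga = ga)
}

# counts with real group structure: group-dependent multinomial fractions
structured_fixture <- function(m, n_groups, per_group, depth, seed,
                               group_sd = 1) {
  set.seed(seed)
  base <- rlnorm(m, 0, 1)
  counts <- matrix(0, m, n_groups * per_group)
  gl <- rep(paste0("g", seq_len(n_groups)), each = per_group)
  for (g in seq_len(n_groups)) {
    w <- base * exp(rnorm(m, 0, group_sd))
    for (s in which(gl == paste0("g", g))) {
      p <- w * exp(rnorm(m, 0, 0.1))
      counts[, s] <- rmultinom(1, depth, p / sum(p))
    }
  }
  cm <- count_matrix(counts)
  list(cm = cm,
       ga = group_assignment(setNames(gl, cm$sample_ids)))
}

oracle_sample_mean <- function(alpha, i, s) alpha[i, s] / sum(alpha[, s])

oracle_sample_var <- function(alpha, i, s) {
  a0 <- sum(alpha[, s])
  alpha[i, s] * (a0 - alpha[i, s]) / (a0^2 * (a0 + 1))
}

oracle_sample_cov <- function(alpha, i, j, s) {
  a0 <- sum(alpha[, s])
  -alpha[i, s] * alpha[j, s] / (a0^2 * (a0 + 1))
}

# group-level moments by explicit loops over the group's samples
oracle_group_mean <- function(alpha, i, cols) {
  tot <- 0
  for (s in cols) tot <- tot + oracle_sample_mean(alpha, i, s)
  tot / length(cols)
}

oracle_group_var <- function(alpha, i, cols) {
  tot <- 0
  for (s in cols) tot <- tot + oracle_sample_var(alpha, i, s)
  tot / length(cols)^2
}

oracle_group_cov <- function(alpha, i, j, cols) {
  # naive double sum with the cross-sample terms written out (they are zero)
  tot <- 0
  for (s in cols) for (s2 in cols)
    tot <- tot + if (s == s2) oracle_sample_cov(alpha, i, j, s) else 0
  tot / length(cols)^2
}

oracle_total_variance <- function(alpha, i, group_cols) {
  n <- length(group_cols)
  gm <- sapply(group_cols, function(cols) oracle_group_mean(alpha, i, cols))
  grand <- mean(gm)
  cross <- 0; within <- 0
  for (g in seq_len(n)) {
    cross <- cross + (gm[g] - grand)^2 / n
    within <- within + oracle_group_var(alpha, i, group_cols[[g]]) / n
  }
  cross + within
}

oracle_total_covariance <- function(alpha, i, j, group_cols,
                                    include_within = TRUE) {
  n <- length(group_cols)
  gmi <- sapply(group_cols, function(cols) oracle_group_mean(alpha, i, cols))
  gmj <- sapply(group_cols, function(cols) oracle_group_mean(alpha, j, cols))
  out <- sum((gmi - mean(gmi)) * (gmj - mean(gmj))) / n
  if (include_within)
    out <- out + mean(sapply(group_cols, function(cols)
      oracle_group_cov(alpha, i, j, cols)))
  out
}

oracle_bayes_r <- function(alpha, i, j, group_cols, include_within = TRUE) {
  oracle_total_covariance(alpha, i, j, group_cols, include_within) /
    sqrt(oracle_total_variance(alpha, i, group_cols) *
           oracle_total_variance(alpha, j, group_cols))
}

group_cols_of <- function(cm, ga)
  lapply(ga$groups, function(g)
    which(as.character(ga$group_of[cm$sample_ids]) == g))

# subset a dataset to a sample fold
fold_data <- function(cm, ga, fold) {
  list(cm = count_matrix(cm$counts[, fold, drop = FALSE]),
       ga = group_assignment(ga$group_of[fold]))
}
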
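#' Configuration for the grouped multinomial simulator
#'
#' The simulator realizes the package's sampling model exactly: latent
#' per-sample fractions are constructed from group-level profiles and read
#' counts are drawn multinomially at a heterogeneous per-sample depth.
#' Defaults emulate a scaled-down miRNA-seq compendium: entity baselines
#' spanning orders of magnitude (log-normal), a two-orders-of-magnitude depth
#' range echoing the ~150-fold spread seen in large sequencing cohorts,
#' planted co-expression modules whose members share a per-group
#' multiplicative factor, and planted "spurious" pairs expressed only as a
#' handful of reads in one shared sample — the situation where naive Pearson
#' correlation produces a near-perfect, meaningless link.
#'
#' @param m number of entities (default 200).
#' @param n_groups number of groups (default 10).
#' @param samples_per_group samples per group (scalar or length `n_groups`;
#'   default 6).
#' @param depth_range `[min, max]` reads per sample, drawn uniformly
#'   (default `c(5e3, 5e5)`, two orders of magnitude).
#' @param n_modules,module_size planted co-expression modules: disjoint
#'   blocks of `module_size` entities sharing a group profile (defaults 2
#'   and 8).
#' @param module_sd sd (natural-log scale) of the shared per-group module
#'   factor (default 2); larger values give stronger cross-group signal.
#' @param module_baseline_meanlog,module_baseline_sdlog log-normal baseline
#'   of module members (defaults `log(0.1)` and 0.5, against non-member
#'   baselines centred at `exp(0)`): planted modules sit at low-to-moderate
#'   abundance so the shared factor redistributes a negligible share of
#'   total reads, as real group-specific miRNA clusters do. Members of a
#'   high-abundance module would drag every other entity's fraction along
#'   through the common multinomial denominator, creating genuine
#'   correlations outside the planted set.
#' @param noise_sd sd of the per-sample within-group log-noise (default
#'   0.25). Non-module entities have no cross-group structure at all:
#'   baseline plus within-group noise only, so their true cross-entity
#'   correlations are zero.
#' @param baseline_sdlog sd of the log-normal non-member baselines (default
#'   2, spanning several orders of magnitude of expression).
#' @param n_spurious_pairs planted low-count outlier pairs (default 2); each
#'   pair has zero true expression but both members receive a couple of
#'   injected reads in one shared sample.
#' @param spurious_reads range of injected reads per member (default
#'   `c(1, 2)`; the canonical real-data case is 2 stray reads). The shared
#'   outlier sample is the deepest sample, where a stray read represents a
#'   vanishing fraction yet classical Pearson still sees a perfect profile.
#' @param seed base seed; all randomness flows from it through named
#'   substreams (one per entity, module and sample) so draws are stable.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(m = 200, n_groups = 10, samples_per_group = 6,
                              depth_range = c(5e3, 5e5),
                              n_modules = 2, module_size = 8,
                              module_sd = 2,
                              module_baseline_meanlog = log(0.1),
                              module_baseline_sdlog = 0.5,
                              noise_sd = 0.25, baseline_sdlog = 2,
                              n_spurious_pairs = 2,
                              spurious_reads = c(1, 2), seed = 1) {
  if (length(samples_per_group) == 1L)
    samples_per_group <- rep(samples_per_group, n_groups)
  if (length(samples_per_group) != n_groups)
    stop("samples_per_group must be a scalar or one value per group")
  cfg <- list(m = m, n_groups = n_groups,
              samples_per_group = as.integer(samples_per_group),
              depth_range = depth_range, n_modules = n_modules,
              module_size = module_size, module_sd = module_sd,
              module_baseline_meanlog = module_baseline_meanlog,
              module_baseline_sdlog = module_baseline_sdlog,
              noise_sd = noise_sd,
              baseline_sdlog = baseline_sdlog,
              n_spurious_pairs = n_spurious_pairs,
              spurious_reads = range(spurious_reads), seed = seed)
  if (n_modules * module_size + 2 * n_spurious_pairs > m)
    stop("modules and spurious pairs require more entities than m = ", m)
  if (any(depth_range <= 0) || depth_range[2] < depth_range[1])
    stop("depth_range must be positive and nondecreasing")
  structure(cfg, class = "simulation_config")
}

#' Read a simulation configuration from a JSON file
#'
#' @param path JSON file whose keys are [simulation_config()] arguments.
#' @export
read_simulation_config <- function(path) {
  do.call(simulation_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Simulate grouped multinomial count data with known ground truth
#'
#' Constructs latent fractions per sample — entity baseline, times the
#' shared per-group module factor for module members, times per-sample
#' log-normal noise, renormalized to sum to one — then draws read counts
#' `Multinom(depth, p)` independently per sample. Non-module entities carry
#' no cross-group structure, so all true cross-entity correlation lives in
#' the planted modules. Spurious pairs have zero latent expression; their
#' members instead receive a couple of injected reads in the deepest sample.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` ([count_matrix()]), `groups`
#'   ([group_assignment()]), and `truth`: `true_fractions` (m x samples,
#'   columns sum to 1), `module_membership` (named integer, `NA` = none),
#'   `planted_correlated_pairs` and `planted_spurious_pairs` (data.frames
#'   `entity_i`, `entity_j`).
#' @export
simulate_counts <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  m <- config$m; n <- config$n_groups
  entity_ids <- sprintf("ent%03d", seq_len(m))
  group_ids <- sprintf("G%02d", seq_len(n))
  sample_ids <- unlist(lapply(seq_len(n), function(g)
    sprintf("%s_s%d", group_ids[g], seq_len(config$samples_per_group[g]))))
  sample_group <- rep(group_ids, config$samples_per_group)
  S <- length(sample_ids)

  module_members <- lapply(seq_len(config$n_modules), function(k)
    entity_ids[((k - 1) * config$module_size + 1):(k * config$module_size)])
  module_of <- rep(NA_integer_, m)
  names(module_of) <- entity_ids
  for (k in seq_along(module_members)) module_of[module_members[[k]]] <- k
  n_mod_ent <- config$n_modules * config$module_size
  spurious <- if (config$n_spurious_pairs > 0)
    data.frame(
      entity_i = entity_ids[n_mod_ent + 2 * seq_len(config$n_spurious_pairs) - 1],
      entity_j = entity_ids[n_mod_ent + 2 * seq_len(config$n_spurious_pairs)])
  else data.frame(entity_i = character(0), entity_j = character(0))
  is_spurious <- entity_ids %in% unlist(spurious)

  # per-entity streams: baselines (module members drawn from the
  # low-abundance log-normal so the planted blocks hold a negligible share
  # of total mass); non-members have no cross-group factor
  baseline <- numeric(m)
  gf <- matrix(0, m, n, dimnames = list(entity_ids, group_ids))
  for (i in seq_len(m)) {
    set.seed(.stream_seed(config$seed, paste0("entity-", entity_ids[i])))
    baseline[i] <- if (is.na(module_of[i]))
      stats::rlnorm(1, meanlog = 0, sdlog = config$baseline_sdlog)
    else
      stats::rlnorm(1, meanlog = config$module_baseline_meanlog,
                    sdlog = config$module_baseline_sdlog)
  }
  # module streams: shared per-group factor for all members
  for (k in seq_len(config$n_modules)) {
    set.seed(.stream_seed(config$seed, paste0("module-", k)))
    prof <- stats::rnorm(n, 0, config$module_sd)
    for (i in module_members[[k]]) gf[i, ] <- prof
  }

  true_fractions <- matrix(0, m, S, dimnames = list(entity_ids, sample_ids))
  counts <- matrix(0, m, S, dimnames = list(entity_ids, sample_ids))
  for (s in seq_len(S)) {
    set.seed(.stream_seed(config$seed, paste0("sample-", sample_ids[s])))
    depth <- round(stats::runif(1, config$depth_range[1],
                                config$depth_range[2]))
    eps <- stats::rnorm(m, 0, config$noise_sd)
    g <- match(sample_group[s], group_ids)
    w <- baseline * exp(gf[, g] + eps)
    w[is_spurious] <- 0
    p <- w / sum(w)
    true_fractions[, s] <- p
    counts[, s] <- stats::rmultinom(1, size = depth, prob = p)
  }
  # inject the stray outlier reads for each spurious pair into the deepest
  # sample: a couple of reads there are a vanishing fraction of the sample,
  # yet both members' only nonzero expression coincides perfectly
  if (nrow(spurious)) {
    set.seed(.stream_seed(config$seed, "spurious"))
    deep <- order(colSums(counts), decreasing = TRUE)
    lo <- config$spurious_reads[1]; hi <- config$spurious_reads[2]
    for (q in seq_len(nrow(spurious))) {
      s <- deep[q]   # pair q's stray reads land in the q-th deepest sample
      counts[spurious$entity_i[q], s] <- sample(lo:hi, 1)
      counts[spurious$entity_j[q], s] <- sample(lo:hi, 1)
    }
  }

  planted <- do.call(rbind, lapply(module_members, function(mem) {
    cmb <- utils::combn(mem, 2)
    data.frame(entity_i = cmb[1, ], entity_j = cmb[2, ])
  }))
  if (is.null(planted))
    planted <- data.frame(entity_i = character(0), entity_j = character(0))
  list(counts = count_matrix(counts, entity_ids, sample_ids),
       groups = group_assignment(stats::setNames(sample_group, sample_ids)),
       truth = list(true_fractions = true_fractions,
                    module_membership = module_of,
                    planted_correlated_pairs = planted,
                    planted_spurious_pairs = spurious))
}

#' Split samples into two folds, balanced by group
#'
#' Each group's samples are divided as evenly as possible (sizes differ by at
#' most 1, the extra sample's fold chosen at random); groups with a single
#' sample go wholly to one fold and are flagged with a warning.
#'
#' @param groups a [group_assignment()].
#' @param seed integer seed.
#' @return list with `fold1` and `fold2` (character sample-id vectors
#'   partitioning all samples).
#' @export
split_half <- function(groups, seed = 1) {
  stopifnot(inherits(groups, "group_assignment"))
  singles <- groups$groups[groups$group_sizes == 1L]
  if (length(singles))
    warning("group(s) with a single sample assigned wholly to one fold: ",
            paste(singles, collapse = ", "))
  fold1 <- character(0); fold2 <- character(0)
  for (g in groups$groups) {
    ids <- names(groups$group_of)[as.character(groups$group_of) == g]
    set.seed(.stream_seed(seed, paste0("fold-", g)))
    ids <- sample(ids)
    k <- length(ids) %/% 2
    if (length(ids) %% 2 == 1 && stats::runif(1) < 0.5) k <- k + 1
    fold1 <- c(fold1, ids[seq_len(k)])
    fold2 <- c(fold2, if (k < length(ids)) ids[(k + 1):length(ids)])
  }
  list(fold1 = fold1, fold2 = fold2)
}

#' Mean absolute deviation between two correlation sets
#'
#' `MAD(X, Y) = sum_{x in X, y in Y} |r1_xy - r2_xy| / (|X||Y| pairs)`,
#' comparing the same entity pairs in two correlation results (e.g. computed
#' on two data folds). With `binsX = binsY = NULL` all distinct pairs are
#' used, giving the global MAD. Pairs masked in either result are excluded
#' and counted.
#'
#' @param corrA,corrB `correlation_result`s covering the listed entities.
#' @param binsX,binsY entity-id sets defining the pair block; `NULL` = all
#'   entities.
#' @return list with `mad`, `n_pairs` (compared) and `n_masked` (excluded).
#' @export
mad_between <- function(corrA, corrB, binsX = NULL, binsY = NULL) {
  stopifnot(inherits(corrA, "correlation_result"),
            inherits(corrB, "correlation_result"))
  if (is.null(binsX)) binsX <- corrA$entity_ids
  if (is.null(binsY)) binsY <- corrA$entity_ids
  ia <- match(binsX, corrA$entity_ids); ja <- match(binsY, corrA$entity_ids)
  ib <- match(binsX, corrB$entity_ids); jb <- match(binsY, corrB$entity_ids)
  if (anyNA(c(ia, ja, ib, jb))) stop("entities missing from a result")
  A <- corrA$r[ia, ja, drop = FALSE]
  B <- corrB$r[ib, jb, drop = FALSE]
  distinct <- outer(binsX, binsY, "!=")
  ok <- distinct & !is.na(A) & !is.na(B)
  list(mad = mean(abs(A - B)[ok]),
       n_pairs = sum(ok),
       n_masked = sum(distinct) - sum(ok))
}

#' Rank entities into bins of increasing average expression
#'
#' Entities are ranked by mean expression across samples (ties broken by
#' entity id) and split into `n_bins` contiguous rank groups of near-equal
#' size (sizes differ by at most 1), lowest-expression bin first.
#'
#' @param expr an `expression_matrix`.
#' @param n_bins number of bins (default 21).
#' @return named integer vector: bin index (1 = lowest expression) per
#'   entity.
#' @export
expression_bins <- function(expr, n_bins = 21) {
  stopifnot(inherits(expr, "expression_matrix"), n_bins >= 1)
  avg <- rowMeans(expr$values)
  ord <- order(avg, expr$entity_ids)
  m <- length(avg)
  sizes <- rep(m %/% n_bins, n_bins) +
    c(rep(1L, m %% n_bins), rep(0L, n_bins - m %% n_bins))
  bins <- integer(m)
  bins[ord] <- rep(seq_len(n_bins), times = sizes)
  stats::setNames(bins, expr$entity_ids)
}

#' Percentage of variance explained by group
#'
#' Per entity, the between-group variance of expression divided by the total
#' variance across all samples, x100 (population-style variances; group
#' means weighted by group size in the decomposition so the parts sum to the
#' total). 0 when total variance is 0.
#'
#' @param expr an `expression_matrix`.
#' @param groups a [group_assignment()].
#' @return named numeric vector in `[0, 100]`.
#' @export
pove <- function(expr, groups) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (groups$n < 2L) stop("at least 2 groups required")
  idx <- .group_index(groups, expr$sample_ids)
  vals <- expr$values
  S <- ncol(vals)
  grand <- rowMeans(vals)
  total <- rowMeans((vals - grand)^2)
  between <- numeric(nrow(vals))
  for (cols in idx) {
    gm <- rowMeans(vals[, cols, drop = FALSE])
    between <- between + length(cols) / S * (gm - grand)^2
  }
  out <- ifelse(total > 0, 100 * between / total, 0)
  stats::setNames(out, expr$entity_ids)
}
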
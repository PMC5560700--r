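---
title: "Uncertainty-moderated co-expression networks from grouped count data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-moderated co-expression networks from grouped count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brnet)
```

# The problem

Sequencing-based expression measurements are counts, and counts carry their
own precision: an entity observed at 2 reads is measured five orders of
magnitude less precisely (relative to its level) than one observed at
200,000 reads, and the same entity is measured with different precision in a
36-million-read sample than in a 250,000-read sample. Classical relevance
networks threshold Pearson correlations that ignore this, so sparse entities
generate abundant near-perfect correlations that evaporate when the data are
split in half. `brnet` replaces the point estimates with posterior beliefs
and the Pearson correlation with a correlation taken jointly over group
identity and posterior uncertainty.

# Model and assumptions

Within each sample, read counts over the $m$ entities are multinomial with
latent fractions $p_{igs}$ (sample $s$, group $g$). The assumptions that
matter:

* **Multinomial sampling.** All overdispersion beyond multinomial noise is
  attributed to real variation between samples; the model does not add a
  technical overdispersion term.
* **Dirichlet conjugacy with $\alpha^0 = 1/m$.** The prior adds one
  pseudo-read spread over all entities. This choice has provably low bias
  for low-count entities; for well-measured entities the data dominate and
  the prior is irrelevant. `posterior_from_counts()` accepts a scalar or a
  per-entity vector for users with informative priors.
* **Independence across samples.** Posterior beliefs about different
  samples are independent, so group variances are sums of sample variances
  divided by $n_g^2$, and cross-sample covariance terms vanish.
* **Groups as a uniform random variable.** Cross-group moments weight each
  of the $n$ groups equally ($1/n$, not $n_g/n_{tot}$), and population-style
  denominators are used throughout, matching the definitional formulas
  rather than $n-1$ sample-variance conventions. Correlations are invariant
  to this, but reported variance components are not, so the convention is
  fixed and documented.

The within-sample covariance term $E_g(\mathrm{cov}_u)$ in the numerator
reflects the sum-to-one constraint (believing one entity up means believing
everything else down). It is always nonpositive, usually orders of magnitude
smaller than the cross-group term, and costs a dense $m \times m$ product to
evaluate; `include_within_sample_cov = FALSE` (the default) skips it, the
documented fast path. The test suite verifies that on structured count data
the two variants agree to $10^{-3}$.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `prior_value` | $1/m$ | Dirichlet concentration per entity |
| `include_within_sample_cov` | `FALSE` | include $E_g(\mathrm{cov}_u)$ numerator term |
| `K` | 100 | permutation repetitions pooled into the null |
| `h_thresh_percent` | 10 | entropy filter percentile (0 disables; the original recipe used 5) |
| `near_bp` | 10000 | genomic distance defining the "near" locality category |

# The permutation scheme

Permuting raw counts would change sample totals and hence the estimated
expression levels themselves; permuting per-sample estimates would change
group means. The correct null permutes each entity's *group-mean vector*,
and only in the cross-group covariance term of the numerator — the
within-sample covariance term and both denominator variances are
permutation-invariant and reused across repetitions.

The pairwise definition permutes entity $j$ against a fixed entity $i$. At
the matrix level a single shared permutation applied to every entity would
preserve all pairwise alignments and break nothing, so each repetition draws
an **independent uniform permutation per entity**; a pair of independently
permuted vectors is distributionally identical to "fixed $i$ versus permuted
$j$" (compose one permutation with the other's inverse), at a cost of
$O(Km)$ permutations instead of $O(Km^2)$. The suite checks that on a
2-entity, 3-group instance the pooled null support coincides exactly with
the 6-permutation exhaustive enumeration of the pairwise formula, and that
the identity permutation reproduces every observed matrix entry.

Thresholding is inclusive ($r \ge t$) in both the observed link count and
the null tail, the pooled null is stored as a sorted array, and pairs masked
in the observed matrix are excluded from both the numerator and the pair
budget of the tail probability.

# What the simulator emulates

`simulate_counts()` realizes the sampling model exactly: latent fractions
constructed per sample, then a multinomial draw at a depth sampled uniformly
from `depth_range`. Its default world:

* **Abundances spanning orders of magnitude** — log-normal baselines with
  `sdlog = 2`, echoing real compendia where expression runs from
  $10^5$ RPM to below 1 RPM.
* **Two orders of magnitude of depth heterogeneity** (`c(5e3, 5e5)`),
  emulating the roughly 150-fold spread seen in large cancer compendia.
* **Planted co-expression modules**: blocks of entities sharing one
  per-group multiplicative factor ($e^{N(0, 2)}$), i.e. group-specific
  expression programs. Module members are drawn from a *lower* baseline
  distribution (`meanlog = log(0.1)`, `sdlog = 0.5`) so a module holds
  roughly 0.1% of total reads. This is deliberate and load-bearing: planted
  blocks at high abundance would swing the shared multinomial denominator
  and thereby induce genuine correlations between members and every other
  entity, which the ground-truth labels would then miscount as false
  positives. Biologically this matches the group-specific miRNA clusters
  such networks recover in practice, which are a small fraction of total
  reads rather than the dominant species.
* **Non-module entities carry no cross-group structure** — baseline times
  per-sample log-normal noise (`noise_sd = 0.25`) only — so every true
  cross-entity correlation is in the planted set.
* **Spurious pairs**: zero latent expression, with 1–2 stray reads per
  member injected into one shared *deep* sample (pair $q$ uses the $q$-th
  deepest). This reconstructs the canonical failure mode of the classical
  estimator — two entities whose only expression coincides in a single
  sample have grouped Pearson correlation exactly 1 — in the regime where
  the Bayesian estimate can recognize the evidence as negligible. The
  placement matters, and for an instructive reason: the Bayesian
  suppression is governed by the ratio of the posterior-uncertainty floor
  (which sums $\alpha^0/\alpha_{gs}^2$ over *all* samples and is dominated
  by the shallowest ones) to the cross-group signal of the stray reads
  (which scales as $(c/\text{depth})^2$ in the outlier sample). A couple
  of reads in a deep sample is overwhelming moderated; the same reads in a
  shallow sample represent a non-trivial maximum-likelihood fraction and
  are — correctly — only partially moderated. At this desk scale (6 samples
  per group) the suppression also requires the stray count to be small:
  with 4–5 injected reads the cross-group signal already outgrows the
  uncertainty floor and the moderated correlation lands near 0.3–0.4
  rather than below 0.2, which is why the default injects 1–2 reads, the
  magnitude of the phenomenon's real archetype.

What the generator does **not** emulate: overdispersion beyond multinomial
sampling, batch or library-preparation effects, entity-specific biological
variance profiles, and — importantly — the full compositional coupling of
real data. On the simplex, fluctuation of a dominant entity genuinely
anti-correlates with everyone and correlates everyone else with each other.
With heavy-tailed baselines the top entity holds tens of percent of the
reads and this closure effect produces a real, if weak, positive correlation
among all pairs. A green recovery test therefore establishes that the
machinery finds planted signal and controls the error rate against the
planted truth; it does not establish that every correlation in strongly
dominated compositional data is biological. For the null-calibration check
specifically, the no-signal world uses homogeneous baselines
(`baseline_sdlog = 0.5`, no entity above a few percent of mass), because
calibration is only a meaningful question in a world where the
no-correlation hypothesis actually holds; in the dominated world the
permutation test correctly reports the closure excess.

# Numerical and edge-case choices

* **Masking, not zeroing.** Pairs where either total variance is zero are
  `NA`; they are excluded (and counted) in null tails, MAD comparisons and
  networks. With the $1/m$ prior this essentially only occurs for
  expression profiles that are exactly constant across groups.
* **Diagonal convention.** The defining formula applied to $i = i$ does not
  give 1 at finite depth (the uncertainty terms differ); the diagonal is
  reported as 1 by convention and self-pairs are never edges or null
  contributions.
* **Entropy bins.** Ten half-open equal-width bins on $[A, B]$ with the
  last bin closed at $B$; $H = 0$ when $A = B$; $0\log 0 = 0$. The filter
  discards exactly $\lfloor m \cdot H_{thresh}/100 \rfloor$ entities,
  lowest entropy first, ties broken by entity id — deterministic across
  platforms.
* **Link-count matching.** `match_link_count()` returns the largest
  threshold achieving at least the target count; under ties the achieved
  count is reported since an exact match may not exist.
* **"Near" distance.** Closest-endpoint gap between 1-based inclusive
  intervals on the same chromosome (0 when overlapping), strand-agnostic;
  multi-locus mature miRNAs qualify for a category if *any* occurrence pair
  does; near-clusters are connected components of the near graph over all
  occurrences.
* **Zero-depth samples** are retained (they still carry the prior and the
  group-size bookkeeping) but flagged.
* **Reproducibility.** All randomness derives from one seed through named
  substreams (per entity, module, sample, fold), so enlarging one part of a
  configuration does not reshuffle another's draws; every stream seed stays
  below $2^{31}$.

# Known limitations

* The pooled null borrows strength across pairs, as the classical algorithm
  does; a per-pair null would be more exact and is out of scope.
* FDR estimates are expectations under the pooled null, not simultaneous
  error control.
* The entropy filter operates on maximum-likelihood fractions by design
  (parity with the classical algorithm), so it can discard entities whose
  low entropy is purely a depth artifact.
* Locality annotation trusts the supplied GFF3/GTF coordinates and uses
  any-occurrence logic; entities without genomic records fall back to
  non-local with a warning.
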
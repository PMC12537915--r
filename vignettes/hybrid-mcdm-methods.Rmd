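---
title: "Methods: composite indices with DCRITIC, WASPAS and graph-seeded k-means"
author: "graphMCDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite indices with DCRITIC, WASPAS and graph-seeded k-means}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphMCDM)
```

## Scope and assumptions

`graphMCDM` builds composite performance indices from a decision matrix of
`m` alternatives by `n` criteria and groups the alternatives by their
composite score. The pipeline assumes: all entries are observed and finite
(no imputation — validation rejects missing data); every criterion is
orientable as *benefit* (more is better) or *cost* (less is better); and
the composite index is a convex blend of the weighted arithmetic and
geometric means of the normalized criteria. Grouping operates on the
composite score itself, which in the intended application is a scalar, so
the clustering is typically one-dimensional; all clustering code is
written for general dimension `d`.

## Normalization

Four maps to a common benefit-oriented scale are provided.

* **Logistic** (default): `1/(1 + exp(-x))` for benefit columns and
  `1/(1 + exp(x))` for cost columns, applied after column z-scoring.
  Two choices here were genuinely open and are exposed as switches rather
  than hidden:
  * Applied verbatim to raw data, the sigmoid saturates whenever criteria
    live on very different scales (a GDP column in the tens of thousands
    maps everything to 1), destroying discrimination. We therefore z-score
    each column first by default (`standardize_first = TRUE`); a
    zero-variance column is a degeneracy error rather than silently mapped
    to 0.5.
  * The decreasing form `1/(1 + exp(x))` is monotone *decreasing*, so used
    on a benefit criterion it would invert merit order. We read it as the
    cost-orientation map and use the increasing twin for benefit columns;
    `strict_verbatim = TRUE` applies the decreasing form everywhere for
    anyone wanting the literal behaviour.
* **Fuzzy quantization**: linear min–max membership,
  `(x - min)/(max - min)` (benefit) or `(max - x)/(max - min)` (cost).
  This is the simplest standard fuzzy quantizer; both endpoints are
  attained in every column, and a constant column is an error.
* **Decimal scaling**: divide by the smallest power of ten making
  `max|x| <= 1`; cost columns then flip as `1 - value`. Multiplying a
  column by 10 leaves the output unchanged.
* **Vector**: divide by the column Euclidean norm (unit-norm columns),
  cost columns flipped as `1 - value` afterwards.

The cost-flip convention for decimal scaling and vector normalization
(`1 - value` after scaling) keeps all methods benefit-oriented so the
aggregators downstream never need to know criterion directions.

## DCRITIC weighting

The weight of criterion `j` is its *information content* normalized to sum
to one:

`I_j = t_j * sum over j' of (1 - dCor(o_j, o_j'))`,

with `t_j` the sample standard deviation (denominator `m - 1`) of the
normalized column and `dCor` the sample distance correlation. Dispersion
rewards criteria that discriminate between alternatives; the
`(1 - dCor)` sum rewards criteria that are not redundant with the others.
Distance correlation — computed from double-centered pairwise-distance
matrices, as the biased V-statistic — is zero (in the population) only
under independence, so nonlinear redundancy is penalized too, which is the
point of the D in DCRITIC. Conventions we fixed:

* V-statistic (biased) estimator, the classical definition; there is no
  bias-corrected switch because weights are ratios of like quantities.
* The self-term `j' = j` is included in the sum; it contributes 0 for any
  non-constant column.
* `dCor` with a constant column is defined as 0 (the 0/0 case); such a
  column has `t_j = 0` and hence no weight regardless.
* Weighting operates on the *normalized* matrix so dispersion is measured
  on a common scale.
* If all columns are mutually affine every `I_j` is zero up to rounding
  (~1e-15 residues); totals below `sqrt(machine eps) * max(t_j)` raise a
  degeneracy error instead of returning noise-driven weights.

Entropy weights (Shannon divergence of column shares) and MEREC weights
(mean absolute change of a log-score when each criterion is removed) are
implemented for the sensitivity harness; MEREC requires values in (0, 1]
and offers an explicit uniform fallback for the all-ones degenerate case.

## WASPAS, TOPSIS, VIKOR

`WQ_i = lambda * WS_i + (1 - lambda) * WP_i` with `WS` the weighted sum
and `WP` the weighted product (computed in the log domain; non-positive
normalized values are an error). `lambda` is not dictated by theory; we
default to 0.5, the symmetric convention, and expose it. By AM–GM,
`WP_i <= WQ_i <= WS_i`, so `WQ` is non-decreasing in `lambda` — a useful
invariant that the test suite asserts.

Ranks use competition ranking (ties share the best rank, the next rank is
skipped); ties in stored order are broken by alternative id so output
files are deterministic. The published case-study tables contain no ties,
so the tie policy is an artifact decision.

TOPSIS (closeness to the ideal point) and VIKOR (compromise index with
strategy weight `v = 0.5`) consume the *same* normalized matrix and weight
vector as WASPAS rather than applying their own normalizations: the
comparison is then a clean one-factor experiment in which only the
aggregation rule varies. VIKOR's acceptable-advantage conditions do not
change `Q`-ranks and are not reported.

## Graph-seeded k-means

The grouping stage removes the initialization randomness of classical
k-means:

1. Gaussian similarity graph `S_ij = exp(-||x_i - x_j||^2 / (2 sigma^2))`.
2. Unnormalized Laplacian `L = D - S` (the self-similarity cancels in the
   difference, so the diagonal convention of `S` is irrelevant). No
   symmetric or random-walk normalization of `L`, and no row-normalization
   of the eigenvector matrix: the plain `D - S` spectrum is used.
3. Spectral embedding: eigenvectors of the `k` smallest eigenvalues,
   ascending, with a deterministic sign convention (largest-magnitude
   entry positive, ties to the lowest index).
4. A fully deterministic k-means on the rows of the embedding:
   farthest-first seeding (first seed = the row nearest the embedded
   centroid, each next seed maximizes the minimum distance to the chosen
   seeds, ties to the lowest index), then Lloyd iterations. Seeding the
   inner k-means randomly would reintroduce exactly the randomness the
   method exists to remove.
5. The embedded-space *assignment* is transferred back: the j-th initial
   centroid is the mean of the original-space points in embedded cluster
   j, and the final Lloyd loop runs in the original space. Centering in
   the original space is what makes the final assignment step (distances
   between data points and centroids) well-typed; running the final loop
   in the embedded space instead is a coherent alternative reading, and
   the transfer point is isolated in `initial_centers()` should anyone
   want to change it.

Lloyd's loop uses squared-Euclidean assignment with ties to the lowest
center index, convergence when the assignment is unchanged or the largest
center shift falls below `tol = 1e-10`, `max_iter = 300`, and a
deterministic empty-cluster repair (reseed with the point farthest from
its assigned center, ties to the lowest index). The per-iteration inertia
trace is retained and asserted non-increasing in the tests.

### The bandwidth

`sigma` is the one tunable with real leverage. The default (`"auto"`) is
the median distance to the 3rd-nearest neighbour (2nd/1st for very small
m) — a single-bandwidth variant of the local-scaling rule from
self-tuning spectral clustering. We also implement the global
median-of-all-pairwise-distances rule (`sigma = "median"`), but it is not
the default for a measured reason: on clustered data the median pairwise
distance is dominated by *between*-cluster distances, the graph
over-smooths, and the embedding stops separating groups. On the package's
own recovery benchmark (six 1-D Gaussian blobs, unit spacing, noise sd
1/6, m = 35) the local scale attains median ARI 1.0 against generator
truth while the global median scale stays near 0.7. Any positive numeric
`sigma` can be supplied directly; group agreement on real data should be
read jointly with a `sigma` sweep, as in `scripts/acceptance.R`.

## Synthetic data

The generators are pure functions of a `synthetic_spec` (sizes, latent
centers, noise sd, outlier rate, skew, equicorrelation, seed):
decision matrices come from an equicorrelated Gaussian copula with an
exponential-tilt skew and scale-inflated (5x) outlier rows; clustered
scores are Gaussian blobs around distinct centers; panels add per-cell
drift with the drift matrix returned as ground truth. Defaults mirror the
case-study shape — m = 35 alternatives, n = 15 criteria, k = 6 groups,
two periods — with unit-spaced blob centers and noise sd 0.05 where a
scale must be chosen. Each generator draws from its own seed-derived
stream and restores the caller's RNG state.

What they deliberately do not emulate: the marginal distributions of real
safety-performance indicators (unavailable), criterion-specific
correlation structure beyond a common level, or missingness. Passing
tests on these generators therefore demonstrates correctness of the
algorithms under controlled structure, not fidelity to any particular
real dataset.

### What the tests can and cannot show about recovery

With 35 points in 6 blobs (~6 points per blob) at separation six times
the noise sd, the *optimal* sum-of-squares partition occasionally
disagrees with the generating labels: a boundary point drawn into the
neighbouring blob is correctly (in the SSE sense) clustered with it. We
verified that on such datasets an exhaustively restarted k-means returns
the same partition as the graph-seeded method. Recovery is therefore
asserted in expectation — mean ARI and mean V-measure over 20 seeded
datasets at least 0.95 — rather than per dataset, where no SSE-based
method could pass uniformly.

## Numerical conventions

* Validation failures raise classed conditions (`mcdm_*_error`), one class
  per failure kind; the CLI maps them to exit codes (2 validation,
  3 degeneracy, 4 I/O).
* CSV output writes reals with 17 significant digits, so read-back is
  exact for doubles; configuration provenance is embedded as `#` comment
  lines in every output file, and re-running from the same configuration
  reproduces files byte-identically.
* V-measure uses natural-log entropies and the harmonic mean (beta = 1),
  with the 0/0 homogeneity/completeness conventions set to 1 and
  `V = 0` when both vanish.
* Spearman correlation is tie-corrected (Pearson on rank values), via
  `stats::cor(method = "spearman")`.
* Change decomposition takes a *single* weight vector, supplied
  explicitly: with per-period weights the decomposition is no longer
  additive, so the choice of which weights to hold fixed belongs to the
  caller, visibly. Contributions use the additive weighted-sum (`WS`)
  convention; the geometric `WP` component is not additively separable,
  so attributions of the blended `WQ` would not sum exactly.

## Known limitations

* The number of groups `k` is an input; no elbow/silhouette selection is
  provided.
* The similarity graph is dense (m x m) and the Laplacian is fully
  eigendecomposed: fine for benchmarking-sized problems (tens to hundreds
  of alternatives), not engineered for thousands.
* Grouping quality inherits the resolution of the composite score: with a
  scalar score, clusters are intervals, and near-boundary alternatives are
  intrinsically unstable under any method variation — which is exactly
  what the V-measure comparisons quantify.
* The packaged case-study fixtures carry printed scores, ranks and group
  labels only; the underlying indicator data are not distributed, so
  score-level replication of that study is out of scope. One printed rank
  column (decimal scaling, first year) contains a duplicated rank in the
  source; the transcription preserves it as printed.
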
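---
title: "Yield-stability methods for multi-environment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Yield-stability methods for multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstab)
```

## The problem

Plant-breeding programs evaluate candidate genotypes in multi-environment
trials (METs): the same entries grown at several locations or seasons.
Mean yield alone is a poor selection criterion because genotype ranking
changes across environments — the genotype-by-environment interaction
(GEI). A breeder wants entries that combine high mean yield with
*stability*: a predictable response to environmental variation.

`metstab` implements the standard quantitative toolkit for this question
on trials laid out as **augmented designs**: a large set of unreplicated
test lines grown alongside a few replicated check cultivars, the usual
layout for early-generation material where seed is scarce. The checks,
replicated in blocks within each environment, supply the error estimate
that the unreplicated lines cannot.

## Data model

The central container is the complete genotype × environment matrix of
cell-mean yields $X_{ij}$ (t/ha), with margins $\bar X_{i\cdot}$ (genotype
means), $\bar X_{\cdot j}$ (environment means, also called the
*environmental index* $E_j$) and the grand mean $\bar X$. Plot-level
records (environment, genotype, block, role, yield) are validated and
collapsed to this matrix by `as_met_matrix()`; replicated checks are
averaged over blocks, unreplicated lines contribute their single plot.

Two data-preparation policies are deliberate defaults:

* **Missing cells are an error.** Every index below assumes a complete
  matrix; environment-mean imputation is available by explicit opt-in
  (`missing_policy = "impute_env_mean"`) and imputed cells are flagged in
  the result, never silently filled.
* **No check adjustment by default.** Augmented-design practice sometimes
  adjusts line plots by their block's check deviation
  ($x - (\text{block check mean} - \text{environment check mean})$);
  `check_adjustment = TRUE` enables exactly that correction, but raw cell
  values are the default so that the analysis of an already-summarised
  matrix and of the underlying plot table agree.
* **Units are metadata.** Yields are stored as supplied (t/ha by
  convention) and never rescaled silently.

## Univariate stability indices

For each genotype `stability()` computes, across the $n$ environments:

* environmental variance $S^2_i = \frac{1}{n-1}\sum_j (X_{ij}-\bar
  X_{i\cdot})^2$ and its square root (SD);
* coefficient of variation $CV_i = 100\, S_i / \bar X_{i\cdot}$;
* Wricke's ecovalence
  $W^2_i = \sum_j (X_{ij}-\bar X_{i\cdot}-\bar X_{\cdot j}+\bar X)^2$,
  the genotype's share of the interaction sum of squares (the
  double-centred residual; summed over genotypes it *is* $SS_{GE}$ — a
  tested invariant);
* Shukla's stability variance in **two modes**: `scaled_ecovalence`, the
  simple scaling $W^2_i/(n-1)$, and `classical`, Shukla's (1972) unbiased
  variance-component estimator
  $\hat\sigma^2_i = \frac{g(g-1)W^2_i - \sum_m W^2_m}{(g-1)(g-2)(n-1)}$,
  which needs $g \ge 3$ and may be negative for very stable genotypes.
  The two differ in scale and can differ in ranking; both columns are
  always reported and `shukla_mode` selects which feeds the aggregate
  ranking (default `scaled_ecovalence`);
* the Finlay–Wilkinson joint-regression slope $b_i$ of the genotype on
  the environmental index, the Eberhart–Russell deviation mean square
  $S^2d_i = SS_{res}/(n-2)$ and the coefficient of determination $R^2_i$.
  Because the regressor is the column-mean profile, the slopes average to
  exactly 1 — another tested invariant, as is the identity
  $R^2 = 1 - \frac{(n-2)S^2d}{(n-1)S^2}$.

Degenerate inputs are handled explicitly: $S^2d$ is undefined at $n = 2$
(hard error, no silent fallback); a zero-variance genotype has undefined
$R^2$ (0/0) and is reported `NA` with a warning, never 0 or 1; a
non-positive genotype mean makes the CV undefined.

## SID/RSID: harmonic-mean rank aggregation

The indices rarely agree, so they are aggregated into a single score:

1. **Orientation.** Each index is correlated (Pearson) with mean yield.
   An index with *negative* correlation has its values replaced by
   reciprocals before ranking.
2. **Ranking.** The greater the oriented value, the better (numerically
   lower) the rank. Combined with step 1 this means: an index positively
   associated with yield ranks its largest value first, while an inverted
   stability index (e.g. ecovalence negatively correlated with yield)
   ranks its *smallest* raw value first — the most stable genotype gets
   rank 1. Ties receive average (fractional) ranks, so rank sums are
   conserved; missing values keep `NA` ranks and simply drop out of the
   aggregate.
3. **Aggregation.** SID is the harmonic mean of the genotype's per-index
   ranks, $\mathrm{SID}_i = k / \sum_m 1/r_{im}$; RSID is the rank of SID
   (ascending, rank 1 best). The harmonic mean is always $\le$ the
   arithmetic mean rank (equality only when all ranks agree) and rewards
   genotypes that are top-ranked by at least some indices. Both SID and
   the arithmetic `mean_rank` are reported, since either is a defensible
   x-axis for the selection plot.

Design choices made here, where the method description left room:

* The aggregate uses the **seven stability indices** ($S^2$, CV, $W^2$,
  $\sigma^2$, $b$, $S^2d$, $R^2$) and *not* mean yield itself — yield is
  plotted against the aggregate rank rather than folded into it.
  `sid_include_yield = TRUE` adds a yield rank (rank 1 = highest yield)
  for users who want a single selection score.
* The slope $b$ is oriented by its empirical yield correlation like every
  other index. Breeding practice often prefers ranking $|b-1|$
  ("average adaptability"); that is available as
  `b_rank = "closeness_to_one"` but is not the default.
* Reciprocal inversion and rank reversal coincide on positive values; for
  an index column spanning zero (possible for the classical Shukla
  estimator) reciprocals are not monotone, and ascending ranks are used
  directly.

**A limitation worth knowing.** Orientation is *data-driven*: the sign of
an index's yield correlation decides whether it is inverted. In a finite
trial that sign is an estimate, and for indices nearly uncorrelated with
yield it can flip between datasets, reversing that index's contribution.
Simulations with planted perfectly-stable, high-yielding genotypes show
them in selection quadrant A with better-than-median RSID in the large
majority of zero-noise runs (the acceptance script reports the measured
rate), but not in all: when a stability index happens to correlate
positively with yield, the rule ranks the stable genotype last on that
index. This is a property of the correlation-driven orientation itself,
faithfully implemented.

The yield-vs-rank plane is split into quadrants by the mean yield and the
mean aggregate rank: **A** (above-mean yield, better-than-mean rank — the
selection target), then counter-clockwise B (high yield, poor rank), C
(poor/poor) and D (low yield, good rank). Boundary genotypes are assigned
to the favourable side and flagged.

## AMMI

`ammi()` fits $Y_{ij} = \mu + G_i + E_j + \sum_k \lambda_k \gamma_{ik}
\delta_{jk} + \rho_{ij}$: additive main effects, then a singular value
decomposition of the double-centred interaction residual
$Z_{ij} = X_{ij} - \bar X_{i\cdot} - \bar X_{\cdot j} + \bar X$.

* **Scaling.** Scores are stored in the symmetric convention
  $\gamma_{ik} = u_{ik}\sqrt{\lambda_k}$, $\delta_{jk} =
  v_{jk}\sqrt{\lambda_k}$, the common biplot compromise that treats
  genotypes and environments alike; the full-rank reconstruction
  $\gamma\delta^{\top} = Z$ is exact (tested to 1e-10).
* **Sign convention.** An SVD is sign-indeterminate per component; each
  component is flipped so its largest-magnitude environment loading is
  positive, making output deterministic across linear-algebra backends.
* **Stability reading.** The Euclidean norm of a genotype's first two
  scaled scores (`ipca_distance()`) is its distance from the biplot
  origin; zero interaction means zero distance.

With plot-level records the **combined analysis of variance** of the
augmented design is assembled: environment, genotype and interaction sums
of squares from the unreplicated line cells; the replication-within-
environment stratum and the residual error from the replicated checks
(model: environment + blocks within environment + check genotype + check
× environment, all degrees of freedom derived from the supplied block
labels, never assumed). F ratios use the replication MS as denominator
for the environment test and the check residual MS for genotype,
interaction and each multiplicative component; component degrees of
freedom follow Gollob, $g + n - 1 - 2k$. The trial CV% is
$100\sqrt{MS_{res}}/\bar X$. Without checks, an external error MS can be
supplied; without either, the decomposition is still available and only
the tests are omitted.

## GGE

`gge()` decomposes the environment-centred matrix $X_{ij} - \bar
X_{\cdot j}$, retaining genotype main effect plus interaction — the two
terms relevant to choosing a cultivar for an environment. Centring only
(no per-environment SD scaling) is the default, the usual
"centering = 2, scaling = 0" convention; SD scaling is available by flag.
Scaling and sign conventions match the AMMI module so the two biplots are
visually comparable. The sum of squared singular values equals
$SS_{G} + SS_{GE}$ of the two-way decomposition (tested invariant).

**Which-won-where** (`which_won_where()`): the convex hull of the
genotype PC1–PC2 cloud is drawn and rays from the origin perpendicular to
each hull edge partition the plane into as many angular sectors as hull
vertices. Each sector is exactly the set of directions in which its hull
vertex has the largest projection (the normal-cone property of convex
polygons), so the vertex "wins" every environment whose marker falls in
the sector. Deterministic tie-breaks: an environment exactly on a ray
belongs to the counter-clockwise sector; sectors without environments are
still reported, flagged empty. Collinear score clouds (a degenerate hull)
fall back to a two-sector split along the common direction, with a
warning. Sector widths always sum to 360° and the assignment is tested
against a brute-force angular scan at 0.1° resolution.

## Correlation and clustering

`pearson_matrix()` computes Pearson correlations among yield and the
indices by the explicit cross-product formula, with two-sided p-values
from $t = r\sqrt{(m-2)/(1-r^2)}$ on $m$ complete pairs — unadjusted, as
is common practice for these descriptive screens — plus a Holm-adjusted
column for users who want family-wise control.

`met_cluster()` clusters either axis of the yield matrix
agglomeratively; Euclidean distance with Ward (`ward.D2`) linkage is the
default (both configurable and recorded in the result). Raw t/ha values
are clustered by default — environments with very different means should
be allowed to separate on mean level — with an opt-in z-score
standardisation. Leaf order is canonicalised by reordering the dendrogram
with item-mean weights, which makes the heatmap layout invariant to input
row order.

## The synthetic MET generator

`simulate_met()` is the sampling counterpart of the AMMI model and the
package's test harness: additive genotype and environment effects
(exactly centred Gaussian draws), an exact low-rank interaction built
from orthonormalised, centred random score vectors with planted
$\lambda^2$ shares, optional genotypes forced to zero interaction
("planted stable", optionally with a yield bonus), checks replicated in
blocks within environments, lines once per cell, and i.i.d. Gaussian plot
error. The score vectors carry the same sign convention as the AMMI
module, so planted and estimated scores are directly comparable; checks
get zero interaction by default (they are stability references).

Defaults emulate the augmented wheat-trial setting the package targets:
4 environments, 4 checks in quadruplicate, grand mean 7 t/ha, genotype
effect SD 1.2, environment effect SD 1.5, rank-2 interaction with RMS
0.6 t/ha per interacting cell, and plot error SD 0.8 t/ha — about an 11%
trial CV. The packaged fixture `inst/extdata/mock_met.csv` is one such
draw (30 lines, rank-3 interaction with 50/33/17 shares, two planted
stable lines with a +1 t/ha bonus, seed 4217) and is synthetic; it stands
in for no field data.

Zero-noise simulations are exact fixed points: every estimator recovers
its planted parameter to machine precision (effects, slopes, shares,
$W^2 = 0$ for planted-stable rows) — tested. What the generator does
*not* emulate: spatial field trend and autocorrelation, heteroscedastic
or non-Gaussian plot error, and incomplete-block confounding beyond the
block-nested checks. Passing tests therefore validate the estimators'
algebra and sampling behaviour, not robustness to field artefacts.

`simulate_fw()` plants per-genotype joint-regression slopes directly
(rescaled to mean 1, the only realisable slope sets, since slopes on the
environmental index average to 1 by construction).

Simulated plot yields are truncated at zero (yields are physical
quantities) with a warning; with the default means this is vanishingly
rare and the validation suites use settings where it is immaterial.

## Validation problem sizes

The test and acceptance suites run, by the package's own choice of
scale: algebraic identities and oracle comparisons on random 5×4 to 12×6
matrices against independently coded double-loop, normal-equation and
eigen-decomposition oracles (1e-8 relative); slope recovery over 200
seeded trials of 8 genotypes × 8 environments at noise SD 0.3; share
recovery over 200 seeded trials of 30 × 6 at noise SD 0.2 (planted
60/30/10); and planted-stable selection over 50 zero-noise trials of
30 × 4. The estimated-share means carry a small upward-levelling bias
under noise (noise inflates all singular values, pulling shares toward
equality); the Monte-Carlo bands in the tests account for it.

## Pipeline and command line

`run_pipeline()` executes the requested steps in dependency order on a
long or wide CSV (or in-memory objects), writes each module's tables and
JSON artefacts plus a `manifest.json` (tool version, full configuration,
input checksum, per-step status and warnings, output list — written even
on partial failure), and is deterministic given the same input and
configuration. `inst/scripts/met-stab` is a thin Rscript front end with
`all`/per-step/`simulate` subcommands.
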
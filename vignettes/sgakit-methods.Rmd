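---
title: "Models and methods behind sgakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sgakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgakit)
```

sgakit implements the quantitative chain of a yeast colony-array genetic
interaction screen together with two companion assays — fluctuation-test
mutation-rate estimation and growth-curve doubling times. This vignette
describes the underlying models, the tunable parameters and their
defaults, the numerical choices, what the synthetic-data generators do and
do not emulate, and the known limitations.

## The screen model

A synthetic genetic array (SGA) screen crosses query strains against an
arrayed deletion library in 1536-colony format (32 rows × 48 columns).
Queries are combined on each plate, every cross is pinned as four adjacent
technical replicates, and the four outermost rows and columns carry dummy
strains that absorb the edge growth advantage. The observable is colony
size, taken as a proxy for double-mutant fitness.

The analysis assumes effects combine multiplicatively: the expected colony
size at plate position $(i, j)$ carrying cross $(q, g)$ is

$$
S_{ij} = S_0 \cdot f_q \cdot f_g \cdot w_{qg} \cdot r_i c_j \cdot
\varepsilon_{ij},
\qquad \varepsilon_{ij} \sim \mathrm{Lognormal}(0, \sigma),
$$

where $f_q$ and $f_g$ are single-mutant fitness factors, $w_{qg}$ is the
genetic interaction ($w = 1$: none; $w < 1$: synthetic sick), $r_i c_j$ is
a smooth multiplicative spatial field, and $\varepsilon$ is measurement
and pinning noise. Every stage of the pipeline removes one factor of this
model:

1. **Masking** (`mask_non_experimental`) sets border-dummy and empty
   positions to `NA`. Missingness is a distinct state throughout; a zero
   colony size is a legal measurement and is never conflated with `NA`.
2. **Spatial correction** (`correct_spatial`) estimates $r_i$ and $c_j$
   by median polish of $\log S$ — iterated row- and column-median sweeps,
   robust to the occasional giant or failed colony — and divides them
   out. The effects are gauge-fixed to geometric mean 1 so the overall
   plate level is untouched. Sweeps stop when updates fall below
   $10^{-10}$ on the log scale or after 50 iterations; reaching the cap
   leaves residual updates orders of magnitude below measurement noise.
   An optional second pass (off by default) removes a 7×7 moving-median
   residual surface for non-separable gradients.
3. **Plate normalization** (`normalize_to_plate_median`) divides by the
   plate median of present values, putting plates on a common scale
   (median exactly 1; even counts use the midpoint of the two central
   order statistics).
4. **Fitness** (`compute_fitness`) divides each replicate's normalized
   size by the median normalized size of its query across *all* genes and
   plates. Since most deletions do not interact, this median is the
   query's no-interaction baseline, and fitness deviations below 1 track
   $w_{qg}$. The per-query median is computed globally rather than per
   plate: queries span plates, and a global gauge avoids re-introducing
   plate effects the normalization just removed.

Plates carry a processing `stage` (`raw → corrected → normalized`) and the
transitions are enforced, so a plate cannot be normalized twice or scored
before correction.

### Replicate exclusion

Pinning artifacts occasionally produce one wildly deviant replicate.
A replicate is excluded when it contributes more than 90% of the
replicate variance, formalized as the leave-one-out share

$$
s_i = 1 - \frac{SS_{-i}}{SS},
$$

with $SS$ the sum of squared deviations from the mean. The naive share
$(x_i - \bar x)^2 / SS$ cannot exceed 75% for four replicates with three
ties, so a 90% threshold on it would never fire; the leave-one-out form
makes the threshold operative. The rule is a single pass: at most one
replicate (the largest share) is removed per call, and a zero-variance
vector is left alone. It is deliberately *not* iterated — about 61% of
random iid triples contain a >90% leave-one-out contributor, so iterating
the rule would eat genuine replicates. For two-replicate groups the share
is identically 1 whenever the values differ, so exclusion is only applied
to groups of three or more (two-replicate crosses are untestable anyway
under the default replicate floor).

### Testing and hit calling

Each gene's query replicates are compared to its wild-type-control
replicates with a two-sided Welch (unequal-variance) t-test after
exclusion; Welch is the safe default for 4-versus-4 comparisons where an
interaction may inflate one group's variance. Degenerate inputs are
defined explicitly: both groups constant with equal means gives
$t = 0, p = 1$; constant with unequal means gives $p = 0$. Groups below
`min_replicates_for_test` (default 3) make the cross untestable, with
`NA` statistics propagated to the output.

P-values are adjusted with Benjamini–Hochberg per query across all array
genes (the natural family: one query's genome-wide comparison). A cross
is a hit iff

* fitness ratio (query mean / wild-type mean, exclusion applied to each
  side) strictly below `fitness_ratio_threshold` = 0.8, and
* adjusted p strictly below `alpha` = 0.05.

Both inequalities are strict; a ratio of exactly 0.8 is not a hit.
`use_adjusted_p = FALSE` thresholds the raw p instead, as a sensitivity
mode — it raises recall substantially but costs precision (see
*Limitations*).

### Power profile

With four replicates per side, the Welch noncentrality for a true ratio
of 0.5 at lognormal noise $\sigma = 0.15$ is about 6 with roughly 5
degrees of freedom, while the BH cutoff in a 200-gene family with ~10%
true interactions demands $|t| \gtrsim 4.8$. The resulting per-gene
recall is ~0.6–0.75 at essentially perfect precision. This is a property
of the design (4-vs-4 with FDR control), not of the implementation:
screens of this geometry are tuned to call few false positives and
confirm candidates downstream (tetrad dissection), not to be exhaustive.
The package's recovery tests document this honestly rather than assert
power the design does not have; strong interactions (ratio ≤ 0.3) are
recovered nearly completely.

### Post-scoring tools

`intersect_hits` counts all $2^k - 1$ exclusive Venn regions of the
per-query hit sets. `linkage_filter` removes hits on the query-locus
chromosome whose nearest gene boundary lies strictly within a window of
the locus — genes linked to the query marker co-segregate through the
screen's meiosis and score as spurious sick interactions. The window
defaults to 75 kb (roughly 25 cM in *S. cerevisiae*, where
double-mutant recovery by random spore selection becomes unreliable);
it is configurable because the appropriate width depends on the
selection scheme. `hypergeometric_enrichment` tests a hit list against
gene-set collections with the upper tail $P(X \ge k)$, ranks terms by raw
p (an optional BH column is available), and keeps the top 10 by default.
Gene sets are intersected with the screened universe before testing.

## Fluctuation assay

Mutation rates are estimated from parallel cultures plated on selective
medium. Counted colonies are scaled to mutant cells per culture,

$$
r = \text{culture vol} \times \Big( \text{conc. factor} \times
\frac{\#\text{colonies}}{\text{plated vol}} \times \text{dilution} \Big),
$$

then the Lea–Coulson median relation $r = M(1.24 + \ln M)$ is inverted
for the number of independent mutation events $M$, and the rate is
$M / \text{total cells in the culture}$. The inversion brackets the unique
root above $e^{-1.24}$ (the relation is strictly increasing there), runs
`uniroot`, and polishes with Newton steps until the forward residual is
below $10^{-10}$ (scaled by $r$ for large counts).

Two modes are provided because the equation sequence can be read either
way: the default applies the correction per culture and takes the median
of per-culture rates; `mode = "median-r"` applies it once to the cohort
median $r$ (the classical method of the median). Zero-count cultures map
to $M = 0$ and rate 0 with a warning — the zero-fraction (P0) estimator
is deliberately out of scope, so cohorts dominated by zeros should be
re-plated rather than pushed through this estimator.

The cohort median is reported with an exact, distribution-free confidence
interval from binomial order statistics: the tightest pair
$(x_{(l)}, x_{(u)})$ whose coverage $P(l \le B < u)$, $B \sim
\mathrm{Bin}(n, 1/2)$, reaches 95%, ties broken by the most central pair.
For the assay's typical $n = 14$ this selects ranks 3 and 11.

## Growth curves

OD600 time series are fitted as $y = Y e^{Bx}$ by ordinary least squares
of $\log \mathrm{OD}$ on time, and the population doubling time is
$\mathrm{PD} = 0.6931 / B \times 60$ minutes. The 4-digit constant 0.6931
is the convention in spreadsheet-style growth analysis and is used
verbatim so results match such calculations digit for digit;
`exact = TRUE` switches to machine-precision $\ln 2$ (a relative
difference of $7 \times 10^{-6}$).

The exponential ("linear range" on a log axis) window is chosen
automatically: among all runs of ≥ 4 consecutive readings with OD inside
`od_band` (default 0.05–0.5), take the longest window with $r^2 \ge$
`r2_min` (default 0.99); ties go to the higher $r^2$. If no window
qualifies the best-$r^2$ window is used and flagged (`window_ok =
FALSE`) instead of erroring, so batch fits always report something
inspectable. The hard error is reserved for curves with fewer than four
usable points.

One bias is inherent to any OD-band policy: on a logistic culture the
log-slope is $B(1 - y/K)$, so if the band extends toward the carrying
capacity the fit averages a slowed rate. With $K = 1$ and the default
band the fitted $B$ underestimates the intrinsic rate by ~20–25%. When
the intrinsic rate matters (rather than a comparable summary statistic
across strains), the culture should stay well below capacity across the
band — in that regime the fit recovers the true rate within a few
percent. Doubling times compared *between* strains under the same policy
are unaffected as a ranking.

## Synthetic data

The generators produce exactly the TSV dialects the readers consume, and
every dataset carries its ground truth.

* `generate_screen` draws colony sizes from the multiplicative model
  above: base size 300 units, smooth sinusoidal log-scale spatial
  gradients (amplitude 0.1, random phase per plate, geometric mean 1),
  lognormal noise ($\sigma = 0.1$ by default), 2×2 replicate blocks,
  4-deep dummy borders, queries adjacent per gene, leftover inner blocks
  marked empty. It does **not** emulate neighbor competition, pinning
  geometry artifacts, non-separable gradients, or colony segmentation
  error — so passing recovery tests demonstrate correctness of the
  scoring chain under its own model assumptions, not robustness to every
  real-plate pathology.
* `generate_fluctuation` simulates mutation events per generation as
  Poisson on the newly created cells, expands each mutant clone by
  deterministic doubling to the end of growth (no death, no differential
  mutant fitness — the Lea–Coulson assumptions), and samples mutants
  binomially into the plated aliquot with the fraction that exactly
  inverts the plating bookkeeping. It reproduces the Luria–Delbrück
  heavy tail: at $\mu = 10^{-7}$ grown to $10^8$ cells, roughly a third
  of 14-culture cohorts contain a jackpot exceeding 10× the cohort
  median, where an equal-mean Poisson model essentially never does.
* `generate_growth` samples a logistic trajectory (default: inoculum
  0.05, rate 0.7 h⁻¹, capacity 1.0, hourly readings for 20 h) with
  additive Gaussian noise floored at zero.

All generators take a single integer seed; identical seeds give
byte-identical outputs.

## Validation scales

The test suite validates the estimators at the scales the assays use:
fluctuation recovery over 50 cohorts of 14 cultures ($\mu = 10^{-7}$,
$10^3 \to 10^8$ cells; the cohort median lands within a factor of 2 of
the truth in well over 90% of cohorts), screen null calibration and
recovery over 20 simulated screens of 200 genes with 4+4 replicates, and
spatial correction on full 32×48 plates (noiseless injected gradients are
flattened to below $10^{-6}$ relative error). These sizes keep the whole
suite under a minute while leaving each stochastic check with enough
replication to be stable across seeds.

## Limitations

* Only synthetic-sick (negative) interactions are called; alleviating
  interactions and additive-scale epistasis measures are out of scope.
* The spatial model is separable (row × column); real plates can show
  non-separable gradients, for which the optional moving-median residual
  pass is a blunt instrument.
* The fluctuation estimator ignores phenotypic lag and differential
  mutant fitness, and has no maximum-likelihood (Ma–Sandri–Sarkar)
  variant.
* The 4-versus-4 replicate design with FDR control has limited recall
  for moderate interactions (see *Power profile*); hit lists should be
  read as high-precision candidate sets.
* The growth-window policy reports an effective exponential-phase rate;
  near carrying capacity it is a biased estimator of the intrinsic rate.
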
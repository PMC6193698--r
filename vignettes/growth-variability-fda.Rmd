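---
title: "Methods: functional data analysis of individual growth variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional data analysis of individual growth variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growfda)
```

## The problem

Even-aged bivalves reared under identical conditions grow at conspicuously
different rates. A classical way to look for physiological drivers of this
variability is to compare feeding and metabolic rates of fast and slow
growers *after* the sizes have diverged — but by then any difference may be a
consequence of size, not a cause of the divergence. The alternative
implemented here monitors every individual repeatedly *while* the divergence
is happening: monthly measurements of shell length (L, mm), total fresh
weight (TFW, g), clearance rate (CR, l/h), absorption efficiency (AE),
respiration (VO2, ml O2/h) and ammonia excretion (VNH4, µg NH4-N/h) on a
cohort of individually labelled mussels held in flow-through tanks on a
common diet. Each individual then becomes a set of *curves*, and questions
about growth variability become questions about samples of functions.

`growfda` implements the full chain: the energy-budget arithmetic that
converts raw rates into a scope for growth, the nonparametric smoothing that
turns sparse longitudinal measurements into curves, depth-based outlier
screening, cross-sectional dispersion tests, and functional comparison of
fast versus slow growers. A synthetic cohort generator with a known latent
structure makes every stage testable end to end.

## The energy budget

For each individual and sampling, with the tank diet's particulate organic
matter POM (mg/l):

* organic ingestion rate `OIR = CR × POM` (mg/h);
* absorption efficiency by the Conover ash-ratio method,
  `AE = (F − E) / ((1 − E) F)`, from the organic fractions of food (F) and
  feces (E);
* absorption rate `AR = AE × OIR` (mg/h);
* metabolic cost `M = q_O2 VO2 + q_NH4 VNH4` (J/h);
* scope for growth `SFG = q_POM AR − M` (J/h).

The three conversion coefficients default to the standard values of the
mussel energy-budget literature — `q_O2 = 20.33` J/ml O2 (oxycaloric
coefficient), `q_NH4 = 0.02483` J/µg NH4-N, `q_POM = 17.9` J/mg absorbed
organic matter — and are set in `energy_coefficients()`. Because the
coefficients are conventions rather than measurements, absolute SFG values
scale with them; all comparisons in the package (between individuals, groups
or samplings) are unaffected by that scale. `derive_all()` applies the chain
per record, joining each measurement to its tank's diet at the nearest
sampling time within ±3 days, propagating missing inputs to missing outputs
(never imputing), and reporting unmatched records in a join report instead of
dropping them. Negative AE values (feces more organic than the food, usually
a data problem) are retained and flagged rather than truncated, since
truncation would bias group means.

The identity `SFG + M = q_POM · AE · CR · POM` holds to machine precision for
every complete record; the test suite asserts it on 10^4 random records.

## From measurements to curves

Each individual's trajectory of a variable is a short, possibly gappy series
(6 monthly values at full design). The functional representation is the
Nadaraya–Watson estimator with a Gaussian kernel,

$$\hat X(t) = \frac{\sum_j y_j\,K_h(t - t_j)}{\sum_j K_h(t - t_j)},$$

a convex combination of the observations: weights sum to one at every `t`
and the curve never leaves the observed range. Missing values simply drop
out of the sums, which is what makes irregular sampling unproblematic. At
least 3 non-missing points are required; shorter trajectories are excluded
with a logged skip report.

The bandwidth `h` (days) is selected per trajectory by generalized
cross-validation,
$$\mathrm{GCV}(h) = \frac1n \sum_i \left(\frac{y_i - \hat X_h(t_i)}{1 - \mathrm{tr}(S_h)/n}\right)^2,$$
with `S_h` the smoother matrix on the observation times. The candidate grid
is 25 log-spaced values from half the smallest time gap (near interpolation)
to the full span (near flat); ties — including the all-zero GCV of noiseless
constant data — break toward the larger bandwidth, i.e. the smoother fit.
`build_functional_sample()` assembles all curves on a common equispaced grid
of 101 points over the pooled time span (the default trades resolution
against the cost of the downstream distance computations; it is a plain
argument).

## Depth and outlier screening

The h-modal depth of a curve is its total kernel similarity to the sample,
$\mathrm{depth}(x_i) = \sum_j K(\lVert x_i - x_j\rVert_2 / h_d)$, with the L2
norm computed by trapezoid quadrature on the grid and `h_d` the 15th
percentile of the pairwise distances. Curves near the functional mode are
deep; isolated curves are shallow. The ordering is invariant to adding a
common curve to every row and to joint positive rescaling.

`trimmed_mode_outliers()` flags curves whose depth falls below a bootstrap
cutoff, removes them, and repeats (at most 5 rounds). The cutoff is
estimated from B = 200 smoothed bootstrap resamples, where the smoothing
noise is Gaussian with covariance `gamma = 0.05` times the sample covariance
of the curves. Two resampling schemes are provided:

* **weighted** (default): curves are resampled with probability proportional
  to their depth, and the cutoff is the `alpha_cut = 1%` quantile of all
  B × n bootstrap depths pooled. Resampling weights taper the influence of
  shallow curves smoothly, so the bootstrap still sees the left tail of the
  depth distribution; in our null simulations (homogeneous Gaussian-process
  samples, both smooth and rough covariances, n = 20 and 48) this holds the
  per-curve false-flag rate near the nominal 1% while +10 pooled-sd curves
  are flagged essentially always.
* **trimmed**: resample uniformly from the (1 − trim) deepest curves
  (trim = 0.1, the 10% trimmed mode) and take the median of the
  per-replicate 1% depth quantiles. The hard trim deletes the left tail of
  the depth distribution outright, and the modest smoothing noise cannot
  rebuild it, so the cutoff sits too high: the same null simulations flag
  3–10% of perfectly ordinary curves. The scheme is kept because it is the
  textbook description, but it is not the default.

The choice matters: outliers are excluded before the group analysis, so a
liberal screen silently discards real individuals.

## Cross-sectional tests

Per sampling date, size and rate distributions are summarised by a Gaussian
KDE with the Sheather–Jones direct plug-in bandwidth (`kde_plugin()`, via
`stats::bw.SJ`). Differences in location across samplings use the
Kruskal–Wallis rank ANOVA (`kruskal_wallis()`, mid-rank tie correction,
χ²(k−1) reference) with Tukey-HSD post-hoc comparisons on the
rank-transformed pooled data (`tukey_hsd_on_ranks()`; whether to rank first
is genuinely open — ranks are the default to stay consistent with the rank
ANOVA, `on = "raw"` is available). Differences in *spread* use
`dispersion_test()`: each observation is reduced to its distance from its
own group centroid (|x − group mean| univariately), a one-way F is computed
on those distances, and inference is by label permutation (999 permutations,
p with the +1 correction, so p ≥ 1/(n_perm+1)). Because distances are
centroid-relative the test ignores location shifts entirely. Repeated
measures across samplings are treated as independent groups per sampling —
the same simplification the cross-sectional tests always make; it is a
documented limitation, not a modelling claim.

## Group comparison

`classify_growers()` splits individuals at the median of their final-sampling
size, strictly above = fast, strictly below = slow; individuals exactly at
the median belong to neither group and are listed as excluded (with an even
subsample the case is rare; the rule matters for general data — a split that
leaves an empty group is an error, a singleton group only a warning).
`select_even_start()` first restricts the analysis to individuals with a
common starting shell length (default 21 ± 0.5 mm), so group differences in
the subsequent curves cannot be inherited from initial size.

Equality of group mean curves is tested by the one-way functional ANOVA
statistic
$$V = \sum_{i<j} n_i \lVert \bar X_i - \bar X_j \rVert_2^2,$$
with a parametric bootstrap null: each group's mean curve is simulated as a
zero-mean Gaussian process with the group's estimated pointwise covariance
divided by its size, V is recomputed B times, and
p = (1 + #{V_b ≥ V}) / (1 + B). A label-permutation null
(`null = "permutation"`) is available as a robustness check. Dependence
between two families of curves (e.g. growth versus feeding) is measured by
the distance covariance of their L2 distance matrices with a permutation
null over the pairing of individuals (`functional_correlation_test()`); the
underlying study only names "functional correlation tests", and distance
covariance was chosen as a generic dependence measure that needs no
linearity assumption — this is an interpretation, recorded as such.

`compare_groups_report()` runs the full workflow — even-start subsample,
median split by final L and by final TFW, functional ANOVA per variable
(9 variables × 2 criteria), group mean curves with uniform bootstrap bands —
and returns one tidy table.

## The synthetic cohort generator

`generate_cohort()` emulates the monitoring design: 48 individuals, 16 per
3 tanks, 6 monthly samplings (days 0–150), initial shell length drawn from
N(20.5, 0.5²) mm rounded to the 0.1 mm caliper precision, initial TFW from
N(0.66, 0.089²) g, and per-tank diet POM uniform in [0.673, 0.734] mg/l with
organic content in [0.72, 0.75]. A latent quality factor
q_i ~ N(0, 1) gives each individual correlated advantages:
CR and AE load positively on q (+0.15, +0.08), VO2 and VNH4 negatively
(−0.05 each) — efficient individuals eat more and spend less. The
between-individual component of every rate inflates by a factor 1.15 per
sampling, producing the increasing dispersion the analysis is meant to
detect. Baselines (CR 2 l/h, AE 0.6, VO2 0.35 ml/h, VNH4 8 µg/h) are
order-of-magnitude placeholders: the study itself prints no rate
magnitudes, so the generator targets statistical structure, not calibrated
physiology.

Growth is mechanistic rather than a named growth curve: the generator
computes each individual's SFG from its *recorded* (noisy) rates with the
package's own budget arithmetic and increments TFW by
`growth_gain × max(SFG, 0) × hours` between samplings (growth_gain
7 × 10⁻⁵ g/J, process noise sd 0.03 g); shell length follows allometrically
as L ∝ TFW^(1/3). Two consequences: the energy identities hold in the
generated data by construction (`derive_all()` recovers the generator's
internal SFG exactly), and persistent quality differences compound into the
fast/slow divergence the group analysis is supposed to recover. With the
default loadings the even-start selection (21 ± 0.5 mm) captures roughly
half the cohort, matching the design's n = 24.

What the generator does *not* emulate: tank effects (available but off by
default, as the study reports constant per-tank diet), allometric scaling of
rates with current size, seasonal forcing, spawning events, and measurement
error structure beyond independent Gaussian noise. Passing tests therefore
demonstrate that the pipeline recovers the planted statistical structure,
not that it would be similarly powerful against every real-data pathology.

`plant_outliers()` shifts chosen individuals' trajectories by a stated
number of pooled standard deviations for detection studies; `degrade()`
removes rate cells at random (and interior size cells), never touching the
first or last size measurement, so selection and classification stay
defined. Missingness above 30% is refused because smoothing needs 3 points
per curve.

## Numerical and design choices

* **Quadrature**: all L2 norms use trapezoid weights on the (possibly
  non-equispaced) grid.
* **Degenerate inputs**: identical curves give equal depths and no outlier
  flags; all-tied samples give H = 0, p = 1 in the rank ANOVA; groups of
  identical constants give p = 1 in the dispersion test; underflowing kernel
  weights in the smoother fall back to the nearest observation.
* **Covariance sampling** in the functional ANOVA uses an eigendecomposition
  with negative eigenvalues clipped at zero, which is exact for rank-deficient
  covariance estimates (n curves < grid points).
* **Seeds**: every resampling function takes an explicit seed;
  `run_pipeline()` derives per-stage seeds from one master seed by hashing
  the stage name, so adding a stage never perturbs another stage's stream.
  Two runs with the same inputs, config and master seed write byte-identical
  tables.
* **Permutation p-values** use the +1 correction throughout, so p = 0 is
  impossible and p ≥ 1/(n_perm + 1).
* **Simulation sizes in the test suite** were chosen to estimate each
  operating characteristic to roughly a percentage point while keeping the
  default run modest: 500 replicates for the type-I calibrations of the
  dispersion, functional-ANOVA and correlation tests, 150 for functional
  ANOVA power, 100 for outlier detection/false-alarm rates, and
  100 random instances per brute-force oracle comparison.

## Known limitations

* The cross-sectional tests ignore the repeated-measures dependence between
  samplings; their p-values describe per-sampling groups, not a longitudinal
  model.
* The functional ANOVA's Gaussian-process bootstrap relies on pointwise
  covariance estimates; with very few curves per group (< ~8) it becomes
  mildly liberal, and the permutation null is the safer choice.
* The distance-based dispersion test inherits the known slight liberality of
  distance-to-centroid permutation tests in small groups.
* Absolute SFG values depend on the configurable energy coefficients and are
  not comparable across studies that use different conventions.
* Smoothing six monthly points cannot resolve within-month dynamics; curves
  are summaries of trends, not reconstructions.
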
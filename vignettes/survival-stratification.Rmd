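---
title: "Data-driven survival stratification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven survival stratification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survstrat)
```

## The problem

Prognostic transcriptomic signatures are usually built by dichotomizing the
expression of each candidate feature — a patient is "high" or "low" for a
miRNA — and asking whether the two groups differ in censored survival. The
package implements a family of *data-driven grouping* procedures that treat
the cut-off itself as a free parameter: for each feature the whole range of
observed expression values is scanned, and the cut-off minimizing the
Cox–Wald P-value of the induced two-group comparison is retained, together
with the direction of the effect. Around this core the package provides the
double cut-off (three-group) variant, a paired two-feature scan over the
seven quadrant grouping designs, statistically weighted voting (SWVg)
aggregation of many dichotomized features into a per-patient risk score,
cross-validated cut-off stability screening, robust consensus K-means
subtyping, a noise/signal mixture model for expression filtering, and the
set-intersection workflow that assembles the final signature.

## Statistical model

Survival follows the Cox proportional-hazards model
$h_i(t) = h_0(t)\,\exp(\beta z_i)$ with a single binary covariate
$z_i = \mathbf{1}[x_i > c]$. For each candidate cut-off $c$ the partial
likelihood is maximized in $\beta$ (Efron tie correction) and the two-sided
Wald test $z = \hat\beta/\widehat{se}$ is recorded; the scan reports
$\hat c = \arg\min_c p(c)$ over the admissible candidates. A candidate is
admissible when both sides retain at least `min_group_frac` (default 0.10)
of the cohort *and* at least one event — without the event condition the
partial likelihood is monotone and the fit diverges.

Two outcomes are possible and are reported as the feature's *phenotype*:
$\hat\beta > 0$ (higher expression, higher hazard) is the parallel,
*pro-oncogenic* pattern; $\hat\beta < 0$ the anti-parallel,
*tumor-suppressor-like* pattern. A coefficient of exactly zero is flagged
indeterminate rather than silently classified.

### The minimized P-value is optimistic

Minimizing over cut-offs is a multiple comparison: under the null the
minimized P-value is stochastically much smaller than uniform. The package
keeps the raw minimized value as the ranking statistic (it is what the
method sorts and weights by) and offers `permutation_B > 0` in `scan_1d()`
to additionally report
$p_{perm} = (1 + \#\{b: p^{min}_b \le p^{min}_{obs}\})/(B+1)$
over label permutations, which the test suite shows is near-uniform under
the null. The raw values should never be read as nominal test levels.

### Double cut-off (three groups)

`scan_1d_double()` builds the $-\log_{10} p$ profile over the admissible
candidates, smooths it with a running median (window 5 candidates, to
suppress single-candidate spikes — the selection rule needs *regions* of
strength, not isolated points), and retains the strongest local maxima
under non-maximum suppression (each retained maximum at least
`min_cutoff_gap_frac`, default 0.15, of the candidate range away from every
stronger one — without this, the runner-up maximum is typically a noisy
shoulder of the dominant boundary rather than a second boundary). Among
qualifying pairs of retained maxima (middle group at least
`min_group_frac`), the pair maximizing the three-group log-rank statistic
is selected, which operationalizes "two similar strongest minima" in terms
of the quantity the method maximizes: group separation. The
three expression strata are then ranked by their each-vs-rest log hazard
and labelled low/intermediate/high *risk* (so a suppressor-like feature
correctly maps its low-expression stratum to high risk). The model is
*accepted* when the overall three-group log-rank P-value is below 0.005 and
all three pairwise Cox–Wald P-values are below 0.05; otherwise — or when no
qualifying pair of maxima exists — it reports the single cut-off fallback
with `accepted = FALSE` and the reason.

### Paired scan and the seven designs

For a feature pair, two cut-offs split the plane into four quadrants. A
*grouping design* maps quadrants to lower/higher risk; up to exchanging the
two labels there are exactly $(2^4 - 2)/2 = 7$ distinct bipartitions, which
`enumerate_designs()` numbers canonically by the bitmask of higher-risk
quadrants (order low/low, low/high, high/low, high/high) reduced by
`min(mask, 15 - mask)`. `scan_2d()` searches a 49-level quantile grid per
axis crossed with the seven designs (the exhaustive observed-value grid is
used in 1D, but a full $O(n^2 \cdot 7)$ grid of Cox fits per pair is
needlessly fine for the paired search; the grid density is configurable).
The global minimizer is returned with a deterministic tie-break (smallest
first axis cut-off, then second, then design id). A pair is *synergistic*
when its best P-value beats both single-feature scans evaluated on the same
candidate grids — the comparison must use the same grids, otherwise the 1D
side is advantaged by its finer candidate set.

### Weighted voting

Each fitted 1D model votes $+1$ (its risk grouping calls the patient
high-risk) or $-1$; votes are combined as
$s_i = \sum_j w_j v_{ij} / \sum_j w_j \in [-1, 1]$ with
$w_j = -\log_{10} p_j$ (floored at $10^{-300}$ before the logarithm so
underflowing P-values cannot create infinite weights). This weight-
normalized vote mean is the package's concrete formalization of
statistically weighted voting (dichotomize, rank by Wald weight, maximize
separation, optimize the variable count); it is isolated in
`score_patients()` so an alternative combination rule is a one-function
substitution. The score is stratified by
re-using the 1D (k = 2) or double (k = 3) scan on the score as a derived
variable, labelling groups by score side (higher score = higher risk, which
is the score's construction). Forward selection includes features in weight
order and picks the smallest subset whose stratification P-value is within
one order of magnitude of the trace minimum; when three groups are
requested, only subset sizes that actually achieved a three-way split
compete, because a handful of features spans too few score levels to admit
two cut-offs.

### Cross-validated stability

`cv_stability()` repeats a 10-fold partition (stratified by event status so
every training split keeps events), refits the scan on each 9/10 split, and
summarizes (a) *confidence*: the fraction of fold fits with P < 0.05, with
the screening flag at > 0.997, and (b) the coefficient of variation of the
fold cut-offs, flag at < 1%. Because folds share 8/9 of their samples,
confidence measures stability on *this* cohort, not independent
replication; a feature whose whole-cohort scan is strongly significant will
pass the confidence screen even if it is a selection-bias artifact — the
cut-off CV criterion is what penalizes features whose optimum wanders
between rival minima. On synthetic cohorts with planted hazard ratios in
the 2–3 range the cut-off CVs of genuinely informative features spread over
roughly 0.1–16%, so the 1% default (kept as the method's original
stringency) under-recalls there; the package's end-to-end validation uses
a 5% ceiling and the threshold is a plain argument.

### Consensus K-means

`robust_kmeans()` repeats K-means (default 1000 runs) with Manhattan
distance and component-wise *median* centroid updates — the median is the
L1-consistent centroid; using the mean with an L1 assignment rule mixes
objectives. Runs are seeded from data points; label switching is avoided
entirely by accumulating co-assignment frequencies instead of aligning
labels. Robust sample cores are maximal groups co-clustered in 100% of
completed runs (connected components of the frequency-1 graph, verified to
be cliques and split greedily if not); feature clusters use a softer 0.90
threshold. Runs not stabilized within 300 assignment iterations are
discarded and the denominator adjusted.

### Expression noise filtering

Pooled log2 intensities are modelled as
$(1-w)\,\mathrm{Exp}(\lambda)\ (\text{shifted to the data minimum})
+ w\,\mathrm{GPD}(\mu, \sigma, \xi)$: a light-tailed noise component and a
long-right-tail signal component. Fitting is EM over responsibilities with
$\lambda$ closed-form and $(\sigma, \xi)$ numerical; the location $\mu$ is
not EM-identifiable (the supports differ), so it is profiled: a coarse
quantile grid, then a staged walk over observed values around the running
optimum, because the profile likelihood jumps at data points and quantile
spacing is wide exactly where the density is low. This profile is
deterministic, replacing the random-restart scheme a stochastic EM would
need. The signal cut-off is the smallest value $t$ with estimated precision
$P(\text{signal}\mid x \ge t) \ge$ `precision_target` (default 0.85, the
"~85% specificity" operating point; we operationalize specificity as
precision of the retained mass and label it as such). A fit is degenerate
when the weight collapses below 0.02 / above 0.98 *or* when the mixture
fails to beat a single exponential by BIC — the second trigger is needed
because EM on genuinely one-component data stalls at interior weights.
The default downstream filter `min_expr = 4.1` (median across samples; the
summary statistic is switchable to the mean) is the boundary this mixture
yields on the cohort the method was developed on.

## The synthetic cohort generator

`synthetic_truth()` / `generate_cohort()` emulate the structure of a large
public high-grade serous ovarian carcinoma miRNA study: 486 samples by
167 features by default; noise features drawn from the fitted-style mixture
(rate 0.45, GPD at 4.1 with scale 2 and shape 0.12, signal weight 0.35, so
most noise features fall below the 4.1 filter); signal features drawn from
the GPD component; 15 informative features with planted cut-offs at the
0.4/0.5/0.6 quantiles and hazard ratios 1.8/2.2/2.6 under alternating
phenotypes (the range printed for real prognostic miRNAs); two planted
pairwise interactions (hazard ×2.5 only when both features exceed their
0.6-quantile cut-offs). Survival is exponential with median 2.43 years at
baseline, multiplied by each planted stratum's hazard ratio; censoring is
uniform on $(0, c_{max})$ with $c_{max}$ solved numerically so the expected
censoring fraction is 0.46 (54% observed deaths). The same seed reproduces
the cohort byte for byte.

What the generator does *not* emulate: batch effects (batch correction is
out of scope upstream), correlation between features beyond the planted
interactions, non-proportional hazards, and informative censoring. Passing
tests on this generator therefore demonstrate correctness of the
algorithms under the stated model, not robustness to those real-data
violations.

## Numerical choices

* Cox fits: 1-parameter Newton on the Efron score with a sign bracket and
  bisection safeguard (the partial likelihood is strictly concave);
  convergence at |step| or |score| below 1e-10/1e-11; |beta| > 15 is
  reported as separation. Warm starts across adjacent scan candidates cut
  iteration counts roughly threefold and cannot change the root.
* Tie-breaks: all scans iterate candidates in ascending order and accept
  only strict improvements, so equal minima resolve to the smallest
  cut-off, independent of input order.
* P-value floor 1e-300 before $-\log_{10}$.
* Fold change on log2 data: $2^{\bar x_A - \bar x_B}$, thresholded
  symmetrically via $\max(FC, 1/FC)$.
* Degenerate inputs raise classed conditions (`NoValidCutoffError`,
  `NoContrastError`, `SeparationError`, `DegenerateGroupError`, ...) rather
  than NA results.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run entirely on generated
cohorts sized to exercise each property: oracle equivalence on 50 random
instances of n ≤ 200; planted 1D recovery over 50 seeds at n = 400 (HR 3);
the paired-interaction and triple-cutoff scenarios summarized over 20-seed
ensembles (design identification and acceptance/ordering rates, and the
ensemble median cut-off error, which is the stable functional of those
scenarios — single-seed cut-off error includes ~0.1–0.2 log2 units of pure
quantile sampling noise); null calibration with 500 replicates (B = 99
permutations) and 500 null features for the stability screen; consensus
clustering over 1000 runs; and the full default 486 × 167 pipeline with
the paired scan over the top 100 features on the 49-level grid. The
pipeline's repeated-CV count defaults to 10 partitions (100 fold fits per
feature), which stabilizes the confidence estimate to ±0.01.

## Known limitations

* The minimized P-values are selection-biased by construction; the
  permutation adjustment is provided but off by default to mirror the
  method's reported raw values.
* The repeated-CV stability screen is not immune to that bias either: on
  fully null cohorts (n ≈ 474) about 2% of features still pass the dual
  confidence/cut-off-CV criterion, because folds of one cohort are not
  independent replicates and a spuriously sharp minimum satisfies both
  criteria at once. The screen should be read as a stability filter, not a
  false-discovery guarantee.
* The SWVg combination rule is a documented reconstruction (see above).
* The double cut-off peak rule ("two similar strongest minima") is
  operationalized via median smoothing and an explicit gap/size constraint;
  other reasonable operationalizations exist.
* Design ids are canonical bitmasks; published figures numbering "design 2"
  etc. cannot be mapped with certainty, so reports always print the
  explicit quadrant risk map next to the id.
* `associate_clinical()` computes the weighted kappa only when the clinical
  category has exactly as many levels as the risk grouping, treating the
  category's sorted levels as ordinal; anything else is reported as NA
  rather than guessed.
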
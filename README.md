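# survstrat

Data-driven survival stratification for prognostic expression signatures.

## What problem this solves

Prognostic signatures from tumor expression profiles (the motivating case is
miRNA profiling of high-grade serous ovarian carcinoma) are built by
dichotomizing each candidate feature — calling a patient "high" or "low" for
a transcript — and testing the two groups against censored overall survival.
`survstrat` treats the cut-off as a parameter to be estimated: for a feature
with expression $x$ and survival data $(t, e)$ it scans every admissible
cut-off $c$, fits the Cox model $h_i(t) = h_0(t)\exp\{\beta\,\mathbf{1}[x_i > c]\}$
(Efron ties), and returns

$$\hat c \;=\; \arg\min_c \; p_{\text{Wald}}(c),$$

with the sign of $\hat\beta$ classifying the feature as *pro-oncogenic*
(high expression, high risk) or *tumor-suppressor-like*. On top of this core
the package provides:

* **Double cut-off scans** into three risk groups (two strongest profile
  maxima, accepted when the overall log-rank P < 0.005 and all pairwise
  Wald P < 0.05);
* **Paired 2D scans** over the seven quadrant grouping designs, with
  synergy accounting (pair beats both of its single-feature scans);
* **Statistically weighted voting (SWVg)**: per-feature risk votes
  ($\pm 1$) combined with weights $w_j = -\log_{10} p_j$ into a patient
  score in $[-1, 1]$, stratified into 2–3 risk groups with forward feature
  selection;
* **Cross-validated cut-off stability** (repeated 10-fold; confidence
  > 99.7% and cut-off CV < 1% screening);
* **Robust consensus K-means** (Manhattan distance, median centroids,
  1000 runs, 100%/90% co-clustering cores);
* **Noise filtering** via an exponential + Generalized Pareto intensity
  mixture (the "expression ≥ 4.1" filter at ~85% precision);
* **Signature workflows**: top-N ranking, three-way intersection,
  literature consensus, clinical association (chi-square + weighted kappa);
* A **seeded synthetic cohort generator** (default 486 samples × 167
  features, 54% observed deaths, median survival 2.43 years) with planted
  cut-off effects and interactions, so everything is testable without any
  data download.

All survival primitives (Kaplan–Meier, k-sample log-rank, binary-covariate
Cox–Wald) are implemented in the package with a compiled scan core, and are
cross-checked against the `survival` package in the test suite.

## Worked example

```r
library(survstrat)

# a synthetic cohort with known planted truth
gen <- generate_cohort(synthetic_truth(), seed = 1)
al  <- align_cohort(gen$expr, gen$surv)

# filter sub-threshold features and scan one feature
ex <- filter_features(al$expr, min_expr = 4.1)
m  <- scan_1d(ex["syn-miR-015", ], al$surv$time_years, al$surv$event,
              feature_id = "syn-miR-015")
m
#> 1D cut-off model 'syn-miR-015': cutoff 6.401, HR 1.93, Wald p 8.16e-08, pro-oncogenic
#>   groups: 316 low-risk / 170 high-risk
```

The planted truth for this feature is a cut-off at the 0.6 quantile of the
signal component (6.04 on the log2 scale), pro-oncogenic with hazard ratio
2.6: the scan recovers the direction exactly and the cut-off to 0.36 log2
units; the marginal hazard ratio (1.93) is attenuated relative to the
planted conditional one because fourteen other informative features also
shape each patient's hazard.

```r
# weighted voting over all fitted features, three risk groups
models <- lapply(rownames(ex), function(f)
  scan_1d(ex[f, ], al$surv$time_years, al$surv$event, feature_id = f))
vm <- swvg_select(models, al$surv$time_years, al$surv$event, k = 3)
vm
#> SWVg voting model: 76 features, k = 3, log-rank p 5.25e-98
#>   features: syn-miR-015, syn-miR-009, syn-miR-007, syn-miR-011, syn-miR-013, ...
```

The three groups are ordered by voting score (higher score = higher risk)
and the overall log-rank P-value refers to their Kaplan–Meier separation.
The complete workflow — filter, 1D scans, CV stability, 2D scans over the
top features, voting, consensus K-means, signature intersection — runs as

```r
summary <- run_pipeline(default_run_config(seed = 1, out_dir = "results"))
```

writing per-stage TSV reports, the voting model JSON, and a
machine-readable `summary.json`; re-running with the same seed reproduces
every artifact byte for byte. A thin command-line wrapper is installed at
`inst/cli/survstrat` (`survstrat run --config run.yaml`,
`survstrat simulate --seed 17 --out cohort/`).

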
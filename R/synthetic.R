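#' Configure a synthetic cohort with known ground truth
#'
#' Describes a cohort generator emulating a high-grade serous ovarian
#' carcinoma style miRNA study: log2 expression drawn from an exponential
#' (noise) + Generalized Pareto (signal) mixture, a subset of signal
#' features with planted expression cut-offs that multiply the hazard,
#' optional planted three-stratum features and pairwise interactions, and
#' uniform censoring calibrated to a target censoring fraction. Defaults
#' echo the reference cohort: 486 samples by 167 features, exponential
#' baseline hazard with 2.43-year median survival, and a 0.46 censoring
#' target (54% observed deaths).
#'
#' @param n_samples cohort size; default 486 (must be >= 50).
#' @param n_features total feature count; default 167.
#' @param n_noise features drawn from the full noise/signal mixture (mostly
#'   sub-threshold); default 18% of `n_features` (30 at the default 167).
#' @param informative data frame with columns `quantile` (planted cut-off
#'   as a population quantile), `hr` (hazard ratio of the risky stratum),
#'   `phenotype` (`"pro-oncogenic"` or `"tumor-suppressor-like"`); default
#'   15 features with hazard ratios 1.8-2.6.
#' @param three_group data frame with columns `quantile_lo`, `quantile_hi`,
#'   `hr_mid`, `hr_high` for planted three-stratum features; default none.
#' @param interaction_pairs data frame with columns `quantile1`,
#'   `quantile2`, `hr`: the hazard is multiplied by `hr` only when both
#'   features exceed their cut-offs; default 2 pairs at the 0.60 quantile
#'   with hazard ratio 2.5.
#' @param censoring_target expected fraction censored; default 0.46.
#' @param median_survival baseline median survival in years; default 2.43.
#' @param mixture list of mixture parameters `noise_rate`, `gpd_location`,
#'   `gpd_scale`, `gpd_shape`, `signal_weight`.
#' @return a `synthetic_truth` configuration object.
#' @export
synthetic_truth <- function(n_samples = 486L, n_features = 167L,
                            n_noise = round(0.18 * n_features),
                            informative = NULL, three_group = NULL,
                            interaction_pairs = NULL,
                            censoring_target = 0.46,
                            median_survival = 2.43,
                            mixture = list(noise_rate = 0.45,
                                           gpd_location = 4.1,
                                           gpd_scale = 2.0,
                                           gpd_shape = 0.12,
                                           signal_weight = 0.35)) {
  if (n_samples < 50L) ss_stop("ValidationError", "need at least 50 samples")
  if (is.null(informative))
    informative <- data.frame(
      quantile = rep(c(0.40, 0.50, 0.60), 5L),
      hr = rep(c(1.8, 2.2, 2.6), each = 5L),
      phenotype = rep(c("pro-oncogenic", "tumor-suppressor-like"),
                      length.out = 15L),
      stringsAsFactors = FALSE)
  if (is.null(three_group))
    three_group <- data.frame(quantile_lo = numeric(0), quantile_hi = numeric(0),
                              hr_mid = numeric(0), hr_high = numeric(0),
                              phenotype = character(0))
  if (is.null(interaction_pairs))
    interaction_pairs <- data.frame(quantile1 = c(0.60, 0.60),
                                    quantile2 = c(0.60, 0.60),
                                    hr = c(2.5, 2.5))
  if (any(informative$quantile <= 0 | informative$quantile >= 1))
    ss_stop("ValidationError", "planted quantiles must lie in (0, 1)")
  if (any(informative$hr <= 0)) ss_stop("ValidationError", "hazard ratios must be positive")
  if (censoring_target <= 0 || censoring_target >= 1)
    ss_stop("ValidationError", "censoring target must lie in (0, 1)")
  n_special <- nrow(informative) + 2L * nrow(interaction_pairs) +
    nrow(three_group)
  if (n_special + n_noise > n_features)
    ss_stop("ValidationError", "informative + pair + noise features exceed n_features")
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_noise = as.integer(n_noise), informative = informative,
                 three_group = three_group,
                 interaction_pairs = interaction_pairs,
                 censoring_target = censoring_target,
                 median_survival = median_survival, mixture = mixture),
            class = "synthetic_truth")
}

# expected censoring fraction with C ~ U(0, cmax), T_i ~ Exp(h_i)
expected_censoring <- function(cmax, h) {
  mean((1 - exp(-h * cmax)) / (h * cmax))
}

#' Generate a synthetic cohort with planted survival effects
#'
#' Draws an expression matrix and a clinical survival table from a
#' [synthetic_truth()] configuration. Per-sample hazards are the
#' exponential baseline times the planted hazard ratio of every risky
#' stratum the sample falls in; censoring times are uniform on
#' (0, c_max) with c_max solved numerically to match the target censoring
#' fraction. Identical seeds give byte-identical outputs.
#'
#' @param truth a `synthetic_truth` configuration.
#' @param seed integer master seed.
#' @return list with `expr` (expression matrix), `surv` (survival table
#'   including clinical categories), and `truth` (the planted ground truth:
#'   feature classes, cut-off values, per-sample hazards, stratum
#'   memberships, realized event fraction, `c_max`, the seed).
#' @export
generate_cohort <- function(truth, seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  n <- truth$n_samples
  mx <- truth$mixture
  n_inf <- nrow(truth$informative)
  n_tg <- nrow(truth$three_group)
  n_pairf <- 2L * nrow(truth$interaction_pairs)
  n_signal_null <- truth$n_features - truth$n_noise - n_inf - n_tg - n_pairf
  classes <- c(rep("informative", n_inf), rep("three_group", n_tg),
               rep("interaction", n_pairf),
               rep("signal_null", n_signal_null), rep("noise", truth$n_noise))
  fid <- sprintf("syn-miR-%03d", seq_len(truth$n_features))
  sid <- sprintf("S%04d", seq_len(n))
  rsignal <- function(m) rgpd(m, mx$gpd_location, mx$gpd_scale, mx$gpd_shape)
  expr <- matrix(NA_real_, truth$n_features, n, dimnames = list(fid, sid))
  log_h <- rep(0, n)
  cut_values <- rep(NA_real_, truth$n_features)
  stratum <- matrix(NA_integer_, truth$n_features, n)
  row <- 0L
  for (i in seq_len(n_inf)) {
    row <- row + 1L
    v <- rsignal(n)
    cut <- qgpd(truth$informative$quantile[i], mx$gpd_location, mx$gpd_scale,
                mx$gpd_shape)
    high <- v > cut
    risky <- if (truth$informative$phenotype[i] == "pro-oncogenic") high else !high
    log_h <- log_h + log(truth$informative$hr[i]) * risky
    expr[row, ] <- v
    cut_values[row] <- cut
    stratum[row, ] <- as.integer(high) + 1L
  }
  for (i in seq_len(n_tg)) {
    row <- row + 1L
    v <- rsignal(n)
    lo <- qgpd(truth$three_group$quantile_lo[i], mx$gpd_location,
               mx$gpd_scale, mx$gpd_shape)
    hi <- qgpd(truth$three_group$quantile_hi[i], mx$gpd_location,
               mx$gpd_scale, mx$gpd_shape)
    s <- ifelse(v <= lo, 1L, ifelse(v <= hi, 2L, 3L))
    mult <- c(1, truth$three_group$hr_mid[i], truth$three_group$hr_high[i])
    ph <- truth$three_group$phenotype[i] %||% "pro-oncogenic"
    if (identical(ph, "tumor-suppressor-like")) mult <- rev(mult)
    log_h <- log_h + log(mult)[s]
    expr[row, ] <- v
    cut_values[row] <- lo
    stratum[row, ] <- s
  }
  for (i in seq_len(nrow(truth$interaction_pairs))) {
    v1 <- rsignal(n); v2 <- rsignal(n)
    c1 <- qgpd(truth$interaction_pairs$quantile1[i], mx$gpd_location,
               mx$gpd_scale, mx$gpd_shape)
    c2 <- qgpd(truth$interaction_pairs$quantile2[i], mx$gpd_location,
               mx$gpd_scale, mx$gpd_shape)
    both <- v1 > c1 & v2 > c2
    log_h <- log_h + log(truth$interaction_pairs$hr[i]) * both
    expr[row + 1L, ] <- v1
    expr[row + 2L, ] <- v2
    cut_values[row + 1L] <- c1
    cut_values[row + 2L] <- c2
    stratum[row + 1L, ] <- as.integer(both) + 1L
    stratum[row + 2L, ] <- as.integer(both) + 1L
    row <- row + 2L
  }
  if (n_signal_null > 0L)
    expr[row + seq_len(n_signal_null), ] <- rsignal(n_signal_null * n)
  row <- row + n_signal_null
  if (truth$n_noise > 0L) {
    m <- truth$n_noise * n
    is_sig <- stats::runif(m) < mx$signal_weight
    vals <- numeric(m)
    vals[!is_sig] <- stats::rexp(sum(!is_sig), rate = mx$noise_rate)
    vals[is_sig] <- rsignal(sum(is_sig))
    expr[row + seq_len(truth$n_noise), ] <- vals
  }
  h0 <- log(2) / truth$median_survival
  h <- h0 * exp(log_h)
  t_event <- stats::rexp(n, rate = h)
  cmax <- tryCatch(
    stats::uniroot(function(cc) expected_censoring(cc, h) - truth$censoring_target,
                   lower = 1e-4, upper = 1e4, tol = 1e-10)$root,
    error = function(e) ss_stop("CalibrationError",
                                "could not calibrate the censoring fraction"))
  c_time <- stats::runif(n, 0, cmax)
  event <- as.integer(t_event <= c_time)
  time <- pmin(t_event, c_time)
  # clinical categories; therapy outcome is linked to the true hazard so
  # that association tests have signal to find
  stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                  prob = c(0.03, 0.05, 0.77, 0.15))
  grade <- sample(c("G2", "G3"), n, replace = TRUE, prob = c(0.14, 0.86))
  residual <- sample(c("none", "1-10mm", ">10mm"), n, replace = TRUE,
                     prob = c(0.25, 0.50, 0.25))
  pr_cr <- 1 / (1 + exp(1.2 * (log_h - stats::median(log_h))))
  outcome <- ifelse(stats::runif(n) < pr_cr, "complete_response",
                    sample(c("partial_response", "progressive_disease",
                             "stable_disease"), n, replace = TRUE,
                           prob = c(0.5, 0.3, 0.2)))
  age <- pmin(pmax(round(stats::rnorm(n, 59, 11)), 27), 89)
  surv <- as_survival_table(data.frame(
    sample_id = sid, time_years = time, event = event, stage = stage,
    grade = grade, residual = residual, therapy_outcome = outcome, age = age,
    stringsAsFactors = FALSE))
  truth_rec <- list(
    feature_class = stats::setNames(classes, fid),
    cutoff_value = stats::setNames(cut_values, fid),
    informative = cbind(truth$informative,
                        feature_id = fid[seq_len(n_inf)],
                        cutoff_value = cut_values[seq_len(n_inf)]),
    three_group = truth$three_group,
    interaction_pairs = truth$interaction_pairs,
    pair_feature_ids = if (n_pairf > 0L)
      matrix(fid[n_inf + n_tg + seq_len(n_pairf)], ncol = 2L, byrow = TRUE)
    else NULL,
    stratum = stratum, hazard = stats::setNames(h, sid), c_max = cmax,
    realized_event_fraction = mean(event), seed = seed)
  list(expr = as_expression_matrix(expr), surv = surv, truth = truth_rec)
}
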
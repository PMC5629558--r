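#' Exhaustive single cut-off survival scan (1D data-driven grouping)
#'
#' Scans every admissible candidate cut-off c of a feature's expression and
#' tests the binary split `x > c` against censored survival with the
#' Cox-Wald test, returning the cut-off minimizing the two-sided P-value.
#' Candidates default to all observed values; a candidate is admissible when
#' both sides keep at least `min_group_frac` of the cohort and at least one
#' event. Ties at the minimum resolve to the smallest cut-off, so the result
#' does not depend on input order.
#'
#' The minimized P-value is an optimistic selection minimum, not a nominal
#' test level; `permutation_B > 0` additionally reports a permutation-
#' adjusted P-value that is calibrated under the null.
#'
#' @param x expression values, named by sample id (names optional when
#'   `times`/`events` are aligned positionally).
#' @param times,events follow-up times (years) and 0/1 event indicators.
#' @param min_group_frac minimum fraction of samples on each side; default
#'   0.10.
#' @param candidates optional candidate cut-off grid; default all observed
#'   values.
#' @param feature_id label stored in the fitted model.
#' @param keep_profile keep the full candidate/P-value profile.
#' @param permutation_B number of label permutations for the adjusted
#'   P-value (0 = off).
#' @return a `cutoff_model_1d`: `feature_id`, `cutoff`, `wald`
#'   (`beta`/`se`/`z`/`p`/`hr`), `phenotype`, `grouping` (k = 2 risk
#'   grouping), `n_low`, `n_high`, optionally `profile` and `perm_p`.
#' @export
scan_1d <- function(x, times, events, min_group_frac = 0.10,
                    candidates = NULL, feature_id = "feature",
                    keep_profile = FALSE, permutation_B = 0L) {
  n <- length(x)
  if (length(times) != n || length(events) != n)
    ss_stop("AlignmentError", "x, times and events must have equal length")
  if (n < 30L) ss_stop("ValidationError", "scan needs at least 30 samples")
  if (sum(events) < 10L) ss_stop("ValidationError", "scan needs at least 10 events")
  if (length(unique(x)) < 2L)
    ss_stop("NoValidCutoffError", "feature is constant")
  if (is.null(candidates)) candidates <- sort(unique(x))
  min_group <- ceiling(min_group_frac * n)
  prof <- scan1d_cpp(as.numeric(times), as.integer(events), as.numeric(x),
                     as.numeric(candidates), as.integer(min_group))
  if (!any(prof$admissible))
    ss_stop("NoValidCutoffError",
            sprintf("no admissible cut-off for '%s' at min_group_frac = %g",
                    feature_id, min_group_frac))
  ok <- prof$admissible & prof$status == 0L & is.finite(prof$p)
  if (!any(ok))
    ss_stop("ScanFailedError",
            sprintf("Cox fit failed at every admissible cut-off of '%s'", feature_id))
  i <- which(ok)[which.min(prof$p[ok])]   # candidates ascending: smallest cut wins ties
  cutoff <- prof$cutoff[i]
  wald <- structure(list(beta = prof$beta[i], se = prof$se[i],
                         z = prof$beta[i] / prof$se[i], p = prof$p[i],
                         hr = exp(prof$beta[i])), class = "wald_result")
  phenotype <- if (wald$beta > 0) "pro-oncogenic" else "tumor-suppressor-like"
  high_expr <- x > cutoff
  risk_high <- if (wald$beta > 0) high_expr else !high_expr
  sid <- names(x)
  if (is.null(sid)) sid <- sprintf("s%04d", seq_len(n))
  lab <- ifelse(risk_high, "high", "low")
  names(lab) <- sid
  grouping <- risk_grouping(lab, provenance = sprintf("scan_1d(%s)", feature_id))
  out <- list(feature_id = feature_id, cutoff = cutoff, wald = wald,
              phenotype = phenotype, grouping = grouping,
              n_low = sum(!risk_high), n_high = sum(risk_high), n = n,
              min_group_frac = min_group_frac)
  if (keep_profile) out$profile <- prof
  if (permutation_B > 0L) {
    perms <- t(vapply(seq_len(permutation_B), function(b) sample.int(n),
                      integer(n)))
    null_min <- scan1d_perm_minp_cpp(as.numeric(times), as.integer(events),
                                     as.numeric(x), as.numeric(candidates),
                                     as.integer(min_group), perms)
    out$perm_p <- (1 + sum(null_min <= wald$p)) / (permutation_B + 1)
    out$permutation_B <- permutation_B
  }
  structure(out, class = "cutoff_model_1d")
}

#' @export
print.cutoff_model_1d <- function(x, ...) {
  cat(sprintf("1D cut-off model '%s': cutoff %.4g, HR %.3g, Wald p %.3g, %s\n",
              x$feature_id, x$cutoff, x$wald$hr, x$wald$p, x$phenotype))
  cat(sprintf("  groups: %d low-risk / %d high-risk\n", x$n_low, x$n_high))
  if (!is.null(x$perm_p))
    cat(sprintf("  permutation-adjusted p: %.3g (B = %d)\n", x$perm_p, x$permutation_B))
  invisible(x)
}

#' Classify the expression/risk pattern of a fitted cut-off model
#'
#' A positive log hazard ratio for the `x > cutoff` indicator means higher
#' expression carries higher risk (the parallel, pro-oncogenic pattern); a
#' negative one means higher expression is protective (the anti-parallel,
#' tumor-suppressor-like pattern). A coefficient of exactly zero is flagged
#' indeterminate.
#'
#' @param model a `cutoff_model_1d`, or anything with a `wald$beta`.
#' @return `"pro-oncogenic"` or `"tumor-suppressor-like"`, with attribute
#'   `indeterminate = TRUE` when beta is exactly zero.
#' @export
classify_phenotype <- function(model) {
  beta <- if (is.list(model)) model$wald$beta else as.numeric(model)
  if (beta == 0) {
    out <- "indeterminate"
    attr(out, "indeterminate") <- TRUE
    return(out)
  }
  if (beta > 0) "pro-oncogenic" else "tumor-suppressor-like"
}

local_peaks <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(vapply(seq_len(n), function(i) {
    left <- if (i == 1L) -Inf else y[i - 1L]
    right <- if (i == n) -Inf else y[i + 1L]
    y[i] > left && y[i] >= right    # first index of a plateau wins
  }, logical(1)))
}

#' Double cut-off scan into three risk subgroups
#'
#' Builds the -log10 P-value profile of the single cut-off scan, smooths it
#' with a running median (window 5) to suppress single-candidate spikes, and
#' picks the two strongest local maxima that are separated by at least
#' `min_cutoff_gap_frac` of the candidate range and leave a middle group of
#' at least `min_group_frac` of the cohort. The resulting three
#' expression strata are relabelled by hazard into low / intermediate / high
#' risk, and the model is accepted when the overall log-rank P-value is
#' below `logrank_threshold` and all pairwise Cox-Wald P-values are below
#' `pairwise_threshold`. When fewer than two qualifying maxima exist the
#' function falls back to the single cut-off model with `accepted = FALSE`.
#'
#' @inheritParams scan_1d
#' @param min_cutoff_gap_frac minimum separation of the two cut-offs as a
#'   fraction of the candidate range; default 0.15.
#' @param pairwise_threshold pairwise Cox-Wald acceptance level (0.05).
#' @param logrank_threshold overall log-rank acceptance level (0.005).
#' @return a `triple_cutoff_model` with `cutoff_lo < cutoff_hi`, a k = 3
#'   `grouping`, `overall_logrank_p`, `pairwise_wald_p` (three values),
#'   `accepted`; or, on fallback, the embedded 1D model plus
#'   `accepted = FALSE` and a `reason`.
#' @export
scan_1d_double <- function(x, times, events, min_group_frac = 0.10,
                           min_cutoff_gap_frac = 0.15, candidates = NULL,
                           feature_id = "feature",
                           pairwise_threshold = 0.05,
                           logrank_threshold = 0.005) {
  m1 <- scan_1d(x, times, events, min_group_frac = min_group_frac,
                candidates = candidates, feature_id = feature_id,
                keep_profile = TRUE)
  prof <- m1$profile
  ok <- prof$admissible & prof$status == 0L & is.finite(prof$p)
  cand <- prof$cutoff[ok]
  nl10 <- neg_log10_p(prof$p[ok])
  fallback <- function(reason) {
    out <- list(feature_id = feature_id, cutoff_lo = m1$cutoff,
                cutoff_hi = NA_real_, grouping = m1$grouping,
                overall_logrank_p = NA_real_,
                pairwise_wald_p = rep(NA_real_, 3L), accepted = FALSE,
                fallback = TRUE, reason = reason, model_1d = m1)
    structure(out, class = "triple_cutoff_model")
  }
  if (length(cand) < 5L) return(fallback("profile too short for peak detection"))
  sm <- stats::runmed(nl10, k = 5L)
  peaks <- local_peaks(sm)
  if (length(peaks) < 2L) return(fallback("fewer than two local maxima"))
  peaks <- peaks[order(-sm[peaks], cand[peaks])]
  n <- length(x)
  min_group <- ceiling(min_group_frac * n)
  gap <- min_cutoff_gap_frac * diff(range(cand))
  # non-maximum suppression: each retained maximum represents a distinct
  # profile region, at least one gap away from every stronger one
  keep <- integer(0)
  for (pk in peaks) {
    if (all(abs(cand[pk] - cand[keep]) >= gap)) keep <- c(keep, pk)
    if (length(keep) >= 8L) break
  }
  peaks <- keep
  # among qualifying pairs of strong maxima, take the pair maximizing the
  # three-group separation (overall log-rank)
  pick <- NULL
  best_lr <- -Inf
  for (a in seq_along(peaks)) {
    for (b in seq_along(peaks)) {
      if (b <= a) next
      lo <- min(cand[peaks[a]], cand[peaks[b]])
      hi <- max(cand[peaks[a]], cand[peaks[b]])
      mid <- sum(x > lo & x <= hi)
      if (hi - lo < gap || mid < min_group) next
      s3 <- ifelse(x <= lo, 1L, ifelse(x <= hi, 2L, 3L))
      lr <- tryCatch(logrank_test(factor(s3), times, events)$chisq,
                     survstrat_error = function(e) NA_real_)
      if (!is.na(lr) && lr > best_lr) { best_lr <- lr; pick <- c(lo, hi) }
    }
  }
  if (is.null(pick)) return(fallback("no qualifying pair of maxima"))
  lo <- pick[1L]; hi <- pick[2L]
  stratum <- ifelse(x <= lo, 1L, ifelse(x <= hi, 2L, 3L))
  sid <- names(x)
  if (is.null(sid)) sid <- sprintf("s%04d", seq_len(n))
  # hazard rank of the three expression strata via each-vs-rest Cox
  beta_s <- vapply(1:3, function(s) {
    tryCatch(cox_binary_wald(stratum == s, times, events)$beta,
             survstrat_error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(beta_s)) {
    # fall back to crude event-rate ordering if a stratum fit degenerates
    beta_s <- vapply(1:3, function(s) mean(events[stratum == s]) /
                       mean(times[stratum == s]), numeric(1))
  }
  risk_rank <- rank(beta_s, ties.method = "first")
  lev <- c("low", "intermediate", "high")
  lab <- lev[risk_rank][stratum]
  names(lab) <- sid
  grouping <- risk_grouping(lab, provenance = sprintf("scan_1d_double(%s)", feature_id))
  overall <- tryCatch(logrank_test(factor(stratum), times, events)$p,
                      survstrat_error = function(e) NA_real_)
  pw <- utils::combn(3L, 2L)
  pairwise <- vapply(seq_len(ncol(pw)), function(j) {
    keep <- stratum %in% pw[, j]
    tryCatch(cox_binary_wald(stratum[keep] == pw[2L, j], times[keep],
                             events[keep])$p,
             survstrat_error = function(e) NA_real_)
  }, numeric(1))
  accepted <- isTRUE(overall < logrank_threshold) &&
    all(!is.na(pairwise)) && all(pairwise < pairwise_threshold)
  structure(list(feature_id = feature_id, cutoff_lo = lo, cutoff_hi = hi,
                 grouping = grouping, overall_logrank_p = overall,
                 pairwise_wald_p = pairwise, accepted = accepted,
                 fallback = FALSE, reason = NA_character_,
                 stratum_log_hazard = beta_s, model_1d = m1),
            class = "triple_cutoff_model")
}

#' @export
print.triple_cutoff_model <- function(x, ...) {
  if (x$fallback) {
    cat(sprintf("Triple cut-off model '%s': fallback to single cut-off (%s)\n",
                x$feature_id, x$reason))
  } else {
    cat(sprintf("Triple cut-off model '%s': cut-offs (%.4g, %.4g), log-rank p %.3g, accepted: %s\n",
                x$feature_id, x$cutoff_lo, x$cutoff_hi,
                x$overall_logrank_p, x$accepted))
  }
  invisible(x)
}

QUADRANTS <- c("low/low", "low/high", "high/low", "high/high")

#' Enumerate the seven paired grouping designs
#'
#' A grouping design maps the four quadrants of a paired cut-off split
#' (feature 1 low/high x feature 2 low/high) to lower-/higher-risk labels.
#' Up to exchanging the two labels there are exactly (2^4 - 2) / 2 = 7
#' distinct non-trivial bipartitions. Designs are numbered canonically by
#' the bitmask of higher-risk quadrants in the order low/low, low/high,
#' high/low, high/high (bits 1, 2, 4, 8), reduced by `min(mask, 15 - mask)`.
#'
#' @return list of 7 `design_2d` objects, each with `id` and a `risk_map`
#'   naming each quadrant `"higher-risk"` or `"lower-risk"`.
#' @export
enumerate_designs <- function() {
  lapply(1:7, function(mask) {
    high <- as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)))
    rm <- ifelse(high, "higher-risk", "lower-risk")
    names(rm) <- QUADRANTS
    structure(list(id = mask, risk_map = rm), class = "design_2d")
  })
}

design_matrix <- function() {
  t(vapply(enumerate_designs(), function(d)
    as.integer(d$risk_map == "higher-risk"), integer(4)))
}

#' @export
print.design_2d <- function(x, ...) {
  cat(sprintf("2D grouping design %d: higher-risk quadrants {%s}\n", x$id,
              paste(names(x$risk_map)[x$risk_map == "higher-risk"], collapse = ", ")))
  invisible(x)
}

#' Paired cut-off scan over the seven grouping designs (2D data-driven
#' grouping)
#'
#' Jointly searches a quantile grid of cut-off pairs (c1, c2) and the seven
#' quadrant grouping designs, fitting the Cox-Wald test of the induced
#' binary risk split for every admissible configuration and returning the
#' global minimizer (ties resolve to the smallest c1, then c2, then design
#' id). The pair is flagged synergistic when its best P-value beats both
#' single-feature scans evaluated on the same candidate grids.
#'
#' @param x1,x2 expression values of the two features (named by sample id).
#' @inheritParams scan_1d
#' @param grid_quantiles number of evenly spaced quantile levels per axis;
#'   default 49.
#' @param feature_pair character vector of length 2 with the feature ids.
#' @return a `pair_model_2d`: `feature_pair`, `cutoffs`, `design`
#'   (a `design_2d`), `wald`, `synergistic`, `p_1d` (the two single-feature
#'   scan P-values on the same grids), `grouping`.
#' @export
scan_2d <- function(x1, x2, times, events, min_group_frac = 0.10,
                    grid_quantiles = 49L,
                    feature_pair = c("feature1", "feature2")) {
  n <- length(x1)
  if (length(x2) != n || length(times) != n || length(events) != n)
    ss_stop("AlignmentError", "inputs must have equal length")
  probs <- seq_len(grid_quantiles) / (grid_quantiles + 1)
  c1s <- sort(unique(stats::quantile(x1, probs, names = FALSE, type = 7)))
  c2s <- sort(unique(stats::quantile(x2, probs, names = FALSE, type = 7)))
  min_group <- ceiling(min_group_frac * n)
  res <- scan2d_cpp(as.numeric(times), as.integer(events), as.numeric(x1),
                    as.numeric(x2), c1s, c2s, design_matrix(),
                    as.integer(min_group))
  if (res$n_admissible == 0L || is.na(res$p))
    ss_stop("NoValidCutoffError", "no admissible paired configuration")
  p1 <- tryCatch(scan_1d(x1, times, events, min_group_frac, candidates = c1s,
                         feature_id = feature_pair[1L])$wald$p,
                 survstrat_error = function(e) Inf)
  p2 <- tryCatch(scan_1d(x2, times, events, min_group_frac, candidates = c2s,
                         feature_id = feature_pair[2L])$wald$p,
                 survstrat_error = function(e) Inf)
  design <- enumerate_designs()[[res$design]]
  high_quadrant <- design$risk_map == "higher-risk"
  quad <- 2L * (x1 > res$c1) + (x2 > res$c2) + 1L
  risk_high <- high_quadrant[quad]
  # orient by the fitted coefficient: beta < 0 means the flagged quadrants
  # actually carry lower hazard
  if (res$beta < 0) risk_high <- !risk_high
  sid <- names(x1)
  if (is.null(sid)) sid <- sprintf("s%04d", seq_len(n))
  lab <- ifelse(risk_high, "high", "low")
  names(lab) <- sid
  wald <- structure(list(beta = res$beta, se = res$se,
                         z = res$beta / res$se, p = res$p,
                         hr = exp(res$beta)), class = "wald_result")
  structure(list(feature_pair = feature_pair,
                 cutoffs = c(res$c1, res$c2), design = design,
                 wald = wald, synergistic = res$p < min(p1, p2),
                 p_1d = c(p1, p2),
                 grouping = risk_grouping(lab, provenance = sprintf(
                   "scan_2d(%s,%s)", feature_pair[1L], feature_pair[2L])),
                 n_high = sum(risk_high), n_low = sum(!risk_high),
                 grid = list(c1 = c1s, c2 = c2s)),
            class = "pair_model_2d")
}

#' @export
print.pair_model_2d <- function(x, ...) {
  cat(sprintf("2D pair model (%s, %s): cut-offs (%.4g, %.4g), design %d, p %.3g%s\n",
              x$feature_pair[1L], x$feature_pair[2L], x$cutoffs[1L],
              x$cutoffs[2L], x$design$id, x$wald$p,
              if (x$synergistic) ", synergistic" else ""))
  invisible(x)
}

#' Count synergistic pairs per feature
#'
#' For every feature, the number of fitted pair models containing it that
#' are synergistic (the 2D P-value beats both 1D P-values) with a 2D
#' P-value below `p_threshold`.
#'
#' @param pair_models list of `pair_model_2d`.
#' @param p_threshold significance threshold for the pair; default 0.05.
#' @return named integer vector, one count per feature appearing in any
#'   pair.
#' @export
synergy_frequency <- function(pair_models, p_threshold = 0.05) {
  feats <- unique(unlist(lapply(pair_models, `[[`, "feature_pair")))
  counts <- stats::setNames(integer(length(feats)), feats)
  for (pm in pair_models) {
    if (isTRUE(pm$synergistic) && pm$wald$p < p_threshold) {
      counts[pm$feature_pair[1L]] <- counts[pm$feature_pair[1L]] + 1L
      counts[pm$feature_pair[2L]] <- counts[pm$feature_pair[2L]] + 1L
    }
  }
  counts
}
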
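#' Build the risk-vote matrix from fitted 1D cut-off models
#'
#' Each fitted single cut-off model casts one vote per patient: +1 when the
#' model's risk grouping labels the patient high-risk, -1 when low-risk.
#' (For a pro-oncogenic feature a +1 vote means expression above the
#' cut-off; for a tumor-suppressor-like feature it means expression at or
#' below it.)
#'
#' @param models list of `cutoff_model_1d` fitted on a common cohort.
#' @return integer matrix of votes in \{-1, +1\}, features x samples, with
#'   a `weights` attribute holding each model's -log10 Wald P-value.
#' @export
build_votes <- function(models) {
  if (length(models) == 0L) ss_stop("ValidationError", "no models supplied")
  sid <- sort(names(models[[1L]]$grouping$labels))
  votes <- matrix(0L, nrow = length(models), ncol = length(sid),
                  dimnames = list(vapply(models, `[[`, "", "feature_id"), sid))
  for (i in seq_along(models)) {
    g <- models[[i]]$grouping$labels
    if (!identical(sort(names(g)), sid))
      ss_stop("AlignmentError", "models were fitted on different cohorts")
    votes[i, ] <- ifelse(as.character(g[sid]) == "high", 1L, -1L)
  }
  attr(votes, "weights") <- vapply(models, function(m) neg_log10_p(m$wald$p),
                                   numeric(1))
  votes
}

#' Weighted voting patient score
#'
#' The statistically weighted voting score of patient i is the weight-
#' normalized vote mean, `sum_j w_j v_ij / sum_j w_j`, which lies in
#' `[-1, +1]`; weights are each feature's -log10 Wald P-value.
#'
#' @param votes vote matrix from [build_votes()].
#' @param weights positive per-feature weights; defaults to the `weights`
#'   attribute of `votes`.
#' @return named numeric vector of patient scores.
#' @export
score_patients <- function(votes, weights = attr(votes, "weights")) {
  if (is.null(weights) || length(weights) != nrow(votes))
    ss_stop("ValidationError", "one weight per feature is required")
  if (any(weights < 0)) ss_stop("ValidationError", "weights must be positive")
  if (sum(weights) <= 0) ss_stop("ValidationError", "total weight is zero")
  colSums(weights * votes) / sum(weights)
}

#' Stratify patients on their voting score
#'
#' Treats the voting score as a derived variable and applies the single
#' (k = 2) or double (k = 3) cut-off scan to it. Groups are labelled by
#' score side so that higher scores always mean higher risk (the score is
#' built from risk votes, so its hazard direction is positive by
#' construction).
#'
#' @param scores patient scores, named by sample id.
#' @param times,events aligned survival data.
#' @param k 2 or 3 risk groups.
#' @param min_group_frac minimum group fraction for the scans.
#' @return list with `grouping`, `overall_logrank_p`, `score_cutoffs`, and
#'   the underlying scan `model`.
#' @export
stratify_scores <- function(scores, times, events, k = 2L,
                            min_group_frac = 0.10) {
  if (!k %in% c(2L, 3L)) ss_stop("ValidationError", "k must be 2 or 3")
  if (k == 2L) {
    m <- scan_1d(scores, times, events, min_group_frac = min_group_frac,
                 feature_id = "swvg_score")
    lab <- ifelse(scores > m$cutoff, "high", "low")
    cuts <- m$cutoff
  } else {
    m <- scan_1d_double(scores, times, events,
                        min_group_frac = min_group_frac,
                        feature_id = "swvg_score")
    if (m$fallback) {
      lab <- ifelse(scores > m$cutoff_lo, "high", "low")
      cuts <- m$cutoff_lo
    } else {
      lab <- c("low", "intermediate", "high")[
        ifelse(scores <= m$cutoff_lo, 1L, ifelse(scores <= m$cutoff_hi, 2L, 3L))]
      cuts <- c(m$cutoff_lo, m$cutoff_hi)
    }
  }
  names(lab) <- names(scores)
  grouping <- risk_grouping(lab, provenance = sprintf("stratify_scores(k=%d)", k))
  lr <- logrank_test(grouping, times, events)
  list(grouping = grouping, overall_logrank_p = lr$p, score_cutoffs = cuts,
       model = m)
}

#' Statistically weighted voting grouping with forward feature selection
#'
#' Ranks candidate cut-off models by voting weight (-log10 Wald P-value),
#' then includes them one at a time, recording the stratification P-value at
#' every subset size. The selected size is the smallest one whose P-value is
#' within one order of magnitude of the global minimum of the trace
#' (parsimony: adding the remaining features does not practically change the
#' statistic).
#'
#' @param models list of `cutoff_model_1d` over a common cohort (>= 2).
#' @param times,events survival data aligned to the models' samples (in
#'   sorted sample-id order).
#' @param k number of risk groups (2 or 3).
#' @param min_group_frac minimum group fraction.
#' @return a `voting_model`: `selected_features` (in weight order),
#'   `weights`, `patient_scores`, `score_cutoffs`, `grouping`,
#'   `overall_logrank_p`, and `selection_trace` (subset size vs P-value).
#' @export
swvg_select <- function(models, times, events, k = 2L, min_group_frac = 0.10) {
  if (length(models) < 1L) ss_stop("ValidationError", "need at least one candidate model")
  votes <- build_votes(models)
  w <- attr(votes, "weights")
  ord <- order(-w)
  trace_p <- rep(NA_real_, length(models))
  strat <- vector("list", length(models))
  for (q in seq_along(models)) {
    idx <- ord[seq_len(q)]
    sc <- score_patients(votes[idx, , drop = FALSE], w[idx])
    strat[[q]] <- tryCatch(
      stratify_scores(sc, times, events, k = k, min_group_frac = min_group_frac),
      survstrat_error = function(e) NULL)
    if (!is.null(strat[[q]])) trace_p[q] <- strat[[q]]$overall_logrank_p
  }
  if (all(is.na(trace_p)))
    ss_stop("SelectionFailedError", "stratification failed at every subset size")
  # parsimony among subsets that reached the requested group count: a small
  # vote set may not span enough score levels for a three-way split
  got_k <- vapply(strat, function(s)
    if (is.null(s)) NA_integer_ else s$grouping$k, integer(1))
  use <- if (any(got_k == k, na.rm = TRUE)) !is.na(trace_p) & got_k == k
         else !is.na(trace_p)
  pmin_ <- min(trace_p[use])
  qstar <- which(use & trace_p <= pmin_ * 10)[1L]
  sel <- strat[[qstar]]
  idx <- ord[seq_len(qstar)]
  structure(list(
    selected_features = rownames(votes)[idx],
    weights = stats::setNames(w[idx], rownames(votes)[idx]),
    patient_scores = score_patients(votes[idx, , drop = FALSE], w[idx]),
    score_cutoffs = sel$score_cutoffs,
    grouping = sel$grouping,
    overall_logrank_p = sel$overall_logrank_p,
    k = sel$grouping$k,
    selection_trace = data.frame(q = seq_along(models), p = trace_p),
    candidate_order = rownames(votes)[ord]),
    class = "voting_model")
}

#' @export
print.voting_model <- function(x, ...) {
  cat(sprintf("SWVg voting model: %d features, k = %d, log-rank p %.3g\n",
              length(x$selected_features), x$k, x$overall_logrank_p))
  cat("  features:", paste(utils::head(x$selected_features, 10L), collapse = ", "),
      if (length(x$selected_features) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Cross-validated cut-off stability of a single feature
#'
#' Repeats a 10-fold partition of the cohort (stratified by event status so
#' every training split keeps events), refits the single cut-off scan on
#' each 9/10 training split, and summarizes stability as (a) the confidence
#' level: the fraction of fold fits significant at P < 0.05, and (b) the
#' coefficient of variation of the fold cut-offs in percent. The screening
#' flags reproduce the dual criterion confidence > 0.997 and cut-off
#' CV < 1%.
#'
#' @param x feature values (named by sample id).
#' @param times,events aligned survival data.
#' @param repeats number of independent fold partitions; default 100.
#' @param folds folds per partition; default 10.
#' @param min_group_frac minimum group fraction for the scans.
#' @param seed integer seed driving the fold partitions.
#' @return a `cv_stability` object: `fold_pvalues`, `fold_cutoffs`,
#'   `confidence`, `cutoff_cv` (percent), `pass_confidence`, `pass_cv`,
#'   `n_skipped`.
#' @export
cv_stability <- function(x, times, events, repeats = 100L, folds = 10L,
                         min_group_frac = 0.10, seed = 1L,
                         feature_id = "feature") {
  n <- length(x)
  set.seed(seed)
  ps <- cuts <- numeric(0)
  skipped <- 0L
  idx_event <- which(events == 1)
  idx_cens <- which(events == 0)
  for (r in seq_len(repeats)) {
    fold <- integer(n)
    fold[idx_event] <- sample(rep_len(seq_len(folds), length(idx_event)))
    fold[idx_cens] <- sample(rep_len(seq_len(folds), length(idx_cens)))
    for (f in seq_len(folds)) {
      tr <- fold != f
      m <- tryCatch(
        scan_1d(x[tr], times[tr], events[tr],
                min_group_frac = min_group_frac, feature_id = feature_id),
        survstrat_error = function(e) NULL)
      if (is.null(m)) { skipped <- skipped + 1L; next }
      ps <- c(ps, m$wald$p)
      cuts <- c(cuts, m$cutoff)
    }
  }
  total <- repeats * folds
  if (skipped > 0.2 * total)
    ss_stop("UnstablePartitionError",
            sprintf("%d of %d fold fits violated scan preconditions", skipped, total))
  confidence <- mean(ps < 0.05)
  cutoff_cv <- 100 * stats::sd(cuts) / mean(cuts)
  structure(list(feature_id = feature_id, fold_pvalues = ps,
                 fold_cutoffs = cuts, confidence = confidence,
                 cutoff_cv = cutoff_cv,
                 pass_confidence = confidence > 0.997,
                 pass_cv = is.finite(cutoff_cv) && cutoff_cv < 1,
                 n_skipped = skipped, repeats = repeats, folds = folds),
            class = "cv_stability")
}

#' @export
print.cv_stability <- function(x, ...) {
  cat(sprintf("CV stability '%s': confidence %.3f (pass: %s), cutoff CV %.2f%% (pass: %s)\n",
              x$feature_id, x$confidence, x$pass_confidence, x$cutoff_cv,
              x$pass_cv))
  invisible(x)
}
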
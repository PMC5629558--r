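#' Kaplan-Meier product-limit estimate
#'
#' Hand-rolled product-limit estimator (kept independent of
#' \pkg{survival}, which serves as the cross-check oracle in the test
#' suite). Censored observations reduce the at-risk count without creating a
#' step.
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators (1 = death observed).
#' @return a `km_curve` object: `event_times`, `survival`, `at_risk`,
#'   `deaths`.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0L) ss_stop("EmptyCohortError", "no samples")
  if (any(times <= 0)) ss_stop("ValidationError", "times must be positive")
  if (!all(events %in% c(0, 1))) ss_stop("ValidationError", "events must be 0/1")
  ord <- order(times)
  t <- times[ord]; e <- events[ord]
  ut <- unique(t[e == 1])
  n <- length(t)
  at_risk <- deaths <- numeric(length(ut))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at_risk[i] <- sum(t >= ut[i])
    deaths[i] <- sum(t == ut[i] & e == 1)
    s <- s * (1 - deaths[i] / at_risk[i])
    surv[i] <- s
  }
  structure(list(event_times = ut, survival = surv, at_risk = at_risk,
                 deaths = deaths, n = n), class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#' @param km a `km_curve`.
#' @param t times at which to evaluate S(t).
#' @return survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- sum(km$event_times <= tt)
    if (i == 0L) 1 else km$survival[i]
  }, numeric(1))
}

#' K-sample log-rank test
#'
#' Classical observed-minus-expected log-rank chi-squared statistic with
#' k - 1 degrees of freedom, computed from the hypergeometric mean and
#' covariance at each distinct event time. Kept independent of
#' \pkg{survival}, which the tests use as the oracle.
#'
#' @param grouping a `risk_grouping` (or a plain vector of group labels
#'   aligned to `times`).
#' @param times follow-up times, aligned to the grouping's samples.
#' @param events 0/1 event indicators.
#' @return list with `chisq`, `df`, `p`, and the per-group observed and
#'   expected event counts.
#' @export
logrank_test <- function(grouping, times, events) {
  g <- if (inherits(grouping, "risk_grouping")) as.character(grouping$labels) else as.character(grouping)
  if (length(g) != length(times))
    ss_stop("AlignmentError", "grouping and survival vectors differ in length")
  lev <- unique(g)
  k <- length(lev)
  if (k < 2L) ss_stop("DegenerateGroupError", "log-rank needs at least two groups")
  if (any(table(factor(g, levels = lev)) == 0L))
    ss_stop("DegenerateGroupError", "log-rank groups must be non-empty")
  if (sum(events) == 0L)
    ss_stop("ValidationError", "log-rank needs at least one event")
  gi <- match(g, lev)
  ut <- sort(unique(times[events == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (tt in ut) {
    at <- times >= tt
    n_t <- sum(at)
    d_t <- sum(times == tt & events == 1)
    n_g <- tabulate(gi[at], nbins = k)
    d_g <- tabulate(gi[times == tt & events == 1], nbins = k)
    O <- O + d_g
    E <- E + d_t * n_g / n_t
    if (n_t > 1) {
      f <- d_t * (n_t - d_t) / (n_t - 1)
      for (a in seq_len(k)) for (b in seq_len(k)) {
        V[a, b] <- V[a, b] +
          f * (n_g[a] / n_t) * ((a == b) - n_g[b] / n_t)
      }
    }
  }
  idx <- seq_len(k - 1L)
  x <- (O - E)[idx]
  Vi <- V[idx, idx, drop = FALSE]
  chisq <- tryCatch(drop(t(x) %*% solve(Vi, x)), error = function(e) {
    drop(t(x) %*% MASS_ginv(Vi) %*% x)
  })
  p <- stats::pchisq(chisq, df = k - 1L, lower.tail = FALSE)
  list(chisq = chisq, df = k - 1L, p = p, observed = O, expected = E,
       groups = lev)
}

# Moore-Penrose fallback for a singular log-rank covariance (tiny groups)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1L], 0)
  if (!any(pos)) return(array(0, dim(X)[2:1]))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Cox-Wald test for a binary covariate
#'
#' Fits the Cox proportional-hazards partial likelihood for a single binary
#' group indicator with the Efron tie correction (Newton-Raphson, compiled
#' core), and reports the two-sided Wald test. This fitter is what the
#' exhaustive cut-off scans call thousands of times; the test suite checks it
#' against \code{survival::coxph}.
#'
#' @param group_indicator logical or 0/1 vector (1 = "high" group).
#' @param times follow-up times.
#' @param events 0/1 event indicators.
#' @return a `wald_result`: `beta` (log hazard ratio for indicator = 1),
#'   `se`, `z`, `p` (two-sided), `hr`.
#' @export
cox_binary_wald <- function(group_indicator, times, events) {
  z <- as.integer(as.logical(group_indicator))
  if (length(unique(z)) < 2L)
    ss_stop("NoContrastError", "group indicator takes a single value")
  f <- cox1_fit_cpp(as.numeric(times), as.integer(events), z)
  if (f$status == 1L)
    ss_stop("NoContrastError", "each group needs at least one event")
  if (f$status == 2L)
    ss_stop("SeparationError", "monotone partial likelihood (separation)",
            beta_at_stop = f$beta)
  if (f$status != 0L)
    ss_stop("SeparationError", "Cox fit did not converge")
  structure(list(beta = f$beta, se = f$se, z = f$beta / f$se, p = f$p,
                 hr = exp(f$beta), loglik = f$loglik),
            class = "wald_result")
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted q-values via [stats::p.adjust()].
#'
#' @param pvalues vector of p-values in `[0, 1]`.
#' @return q-values, same order as input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    ss_stop("ValidationError", "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

# floor before -log10 so that p-values at double precision underflow do not
# produce infinite voting weights
P_FLOOR <- 1e-300

neg_log10_p <- function(p) -log10(pmax(p, P_FLOOR))

#' Linearly weighted kappa between two risk groupings
#'
#' Chance-corrected agreement between two ordinal labelings
#' (low < intermediate < high) with linear disagreement weights, plus the
#' asymptotic normal test of kappa = 0.
#'
#' @param labels_a,labels_b two `risk_grouping`s (or named label vectors)
#'   over the same samples.
#' @return list with `kappa`, `z`, `p`, and the contingency `table`.
#' @export
weighted_kappa <- function(labels_a, labels_b) {
  la <- if (inherits(labels_a, "risk_grouping")) labels_a$labels else labels_a
  lb <- if (inherits(labels_b, "risk_grouping")) labels_b$labels else labels_b
  common <- intersect(names(la), names(lb))
  if (length(common) == 0L)
    ss_stop("AlignmentError", "the two groupings share no samples")
  lv <- c("low", "intermediate", "high")
  lv <- lv[lv %in% union(as.character(la), as.character(lb))]
  a <- factor(as.character(la[common]), levels = lv)
  b <- factor(as.character(lb[common]), levels = lv)
  k <- length(lv)
  n <- length(common)
  tab <- table(a, b)
  P <- tab / n
  # linear agreement weights
  W <- 1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  po <- sum(W * P)
  pr <- rowSums(P); pc <- colSums(P)
  pe <- sum(W * outer(pr, pc))
  kappa <- (po - pe) / (1 - pe)
  # asymptotic variance under H0 (Fleiss/Everitt form, as used by kappa2)
  wr <- as.vector(W %*% pc)   # row-margin expected weights
  wc <- as.vector(t(W) %*% pr)
  num <- sum(outer(pr, pc) * (W - outer(wr, wc, "+"))^2) - pe^2
  se0 <- sqrt(num / (n * (1 - pe)^2))
  z <- kappa / se0
  p <- 2 * stats::pnorm(-abs(z))
  list(kappa = kappa, z = z, p = p, table = tab, n = n)
}
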
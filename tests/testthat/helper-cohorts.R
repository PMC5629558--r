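# Shared fixture builders. Everything is generated in code under explicit
# seeds; nothing is read from disk.

# censored survival times for given per-sample hazards
sim_surv <- function(h, cens_max = 8) {
  n <- length(h)
  t0 <- stats::rexp(n, rate = h)
  cc <- stats::runif(n, 0, cens_max)
  list(time = pmin(t0, cc), event = as.integer(t0 <= cc))
}

# one expression feature with a planted cut-off effect at quantile q
planted_feature <- function(n, hr, q = 0.6, h0 = log(2) / 2.43,
                            cens_max = 6, phenotype = "pro-oncogenic") {
  x <- rgpd(n, 4.1, 2, 0.12)
  cut <- qgpd(q, 4.1, 2, 0.12)
  high <- x > cut
  risky <- if (phenotype == "pro-oncogenic") high else !high
  sv <- sim_surv(h0 * hr^risky, cens_max)
  names(x) <- sprintf("S%04d", seq_len(n))
  list(x = x, time = sv$time, event = sv$event, cutoff = cut, high = high)
}

# survival with no relation to any feature
null_cohort <- function(n, cens_max = 8, h0 = 0.3) {
  sv <- sim_surv(rep(h0, n), cens_max)
  list(time = sv$time, event = sv$event)
}

# brute-force 1D scan oracle built on survival::coxph
oracle_scan_1d <- function(x, time, event, min_group_frac = 0.10) {
  n <- length(x)
  min_group <- ceiling(min_group_frac * n)
  cands <- sort(unique(x))
  best <- NULL
  for (cut in cands) {
    z <- x > cut
    if (sum(z) < min_group || sum(!z) < min_group) next
    if (sum(event[z]) < 1 || sum(event[!z]) < 1) next
    fit <- survival::coxph(survival::Surv(time, event) ~ z, ties = "efron")
    p <- unname(2 * stats::pnorm(-abs(stats::coef(fit) / sqrt(stats::vcov(fit)[1, 1]))))
    if (is.null(best) || p < best$p - 1e-15) best <- list(cutoff = cut, p = p,
                                                          beta = unname(stats::coef(fit)))
  }
  best
}

expect_survstrat_error <- function(expr, class) {
  expect_error(expr, class = class)
}

# two sample blobs in feature space, features x samples
blob_matrix <- function(n_per = 30, p = 20, sep = 10, sd = 1) {
  m <- cbind(matrix(stats::rnorm(p * n_per, 0, sd), p, n_per),
             matrix(stats::rnorm(p * n_per, sep, sd), p, n_per))
  dimnames(m) <- list(sprintf("f%02d", 1:p), sprintf("S%03d", 1:(2 * n_per)))
  as_expression_matrix(m)
}
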
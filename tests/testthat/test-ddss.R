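test_that("the seven grouping designs are the quadrant bipartitions up to
           label exchange", {
  ds <- enumerate_designs()
  expect_length(ds, 7L)
  # brute force: all 14 nonempty proper labelings, deduplicated under
  # label exchange, each design's higher-risk set matching exactly one class
  canon <- function(mask) min(mask, 15L - mask)
  all_masks <- setdiff(0:15, c(0L, 15L))
  classes <- sort(unique(vapply(all_masks, canon, integer(1))))
  expect_length(all_masks, 14L)
  expect_length(classes, 7L)
  ids <- vapply(ds, `[[`, integer(1), "id")
  expect_identical(sort(ids), classes)
  for (d in ds) {
    expect_true(all(c("higher-risk", "lower-risk") %in% d$risk_map))
    mask <- sum(c(1L, 2L, 4L, 8L)[d$risk_map == "higher-risk"])
    expect_identical(canon(mask), d$id)
  }
  # pairwise distinct bipartitions
  parts <- vapply(ds, function(d)
    paste(sort(names(d$risk_map)[d$risk_map == "higher-risk"]), collapse = "|"),
    character(1))
  expect_equal(anyDuplicated(parts), 0L)
})

test_that("phenotype classification admits exactly two determinate classes", {
  expect_identical(classify_phenotype(list(wald = list(beta = 0.7))),
                   "pro-oncogenic")
  expect_identical(classify_phenotype(list(wald = list(beta = -0.7))),
                   "tumor-suppressor-like")
  z <- classify_phenotype(list(wald = list(beta = 0)))
  expect_true(isTRUE(attr(z, "indeterminate")))
  set.seed(41)
  cls <- vapply(rnorm(50), function(b)
    classify_phenotype(list(wald = list(beta = b))), character(1))
  expect_identical(sort(unique(cls)),
                   c("pro-oncogenic", "tumor-suppressor-like"))
})

test_that("scan_1d equals the brute-force coxph oracle", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(60:200, 1)
    pf <- planted_feature(n, hr = sample(c(1, 2, 3), 1))
    or <- oracle_scan_1d(pf$x, pf$time, pf$event)
    m <- scan_1d(pf$x, pf$time, pf$event)
    expect_equal(m$cutoff, or$cutoff)
    expect_equal(m$wald$p, or$p, tolerance = 1e-7)
    expect_equal(m$wald$beta, or$beta, tolerance = 1e-7)
  }
})

test_that("scan_1d is deterministic under input permutation and enforces
           preconditions", {
  set.seed(43)
  pf <- planted_feature(150, hr = 2.5)
  m <- scan_1d(pf$x, pf$time, pf$event)
  perm <- sample.int(150)
  m2 <- scan_1d(pf$x[perm], pf$time[perm], pf$event[perm])
  expect_equal(m2$cutoff, m$cutoff)
  expect_equal(m2$wald$p, m$wald$p, tolerance = 1e-12)

  expect_survstrat_error(scan_1d(rep(5, 150), pf$time, pf$event),
                         "NoValidCutoffError")
  expect_survstrat_error(scan_1d(pf$x[1:20], pf$time[1:20], pf$event[1:20]),
                         "ValidationError")
})

test_that("relaxing the group-size floor never worsens the scan minimum", {
  set.seed(44)
  for (rep in 1:5) {
    pf <- planted_feature(120, hr = 2)
    p_tight <- scan_1d(pf$x, pf$time, pf$event, min_group_frac = 0.25)$wald$p
    p_loose <- scan_1d(pf$x, pf$time, pf$event, min_group_frac = 0.10)$wald$p
    expect_lte(p_loose, p_tight + 1e-12)
  }
})

test_that("scan_1d recovers a planted cut-off and phenotype", {
  set.seed(45)
  hits <- 0L
  for (s in 1:10) {
    pf <- planted_feature(400, hr = 3, q = 0.6)
    m <- scan_1d(pf$x, pf$time, pf$event)
    expect_identical(m$phenotype, "pro-oncogenic")
    if (abs(m$cutoff - pf$cutoff) <= 0.25) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
  # suppressor-like plant flips the phenotype
  pf <- planted_feature(400, hr = 3, q = 0.5, phenotype = "tumor-suppressor-like")
  m <- scan_1d(pf$x, pf$time, pf$event)
  expect_identical(m$phenotype, "tumor-suppressor-like")
})

test_that("permutation-adjusted p is calibrated against a planted effect", {
  set.seed(46)
  pf <- planted_feature(200, hr = 3)
  m <- scan_1d(pf$x, pf$time, pf$event, permutation_B = 99L)
  expect_lte(m$perm_p, 0.05)
  expect_gte(m$perm_p, m$wald$p)   # adjustment can only be less optimistic
})

test_that("double cut-off scan recovers three planted strata", {
  set.seed(47)
  n <- 600
  x <- rgpd(n, 4.1, 2, 0.12)
  names(x) <- sprintf("S%04d", 1:n)
  q1 <- qgpd(1 / 3, 4.1, 2, 0.12); q2 <- qgpd(2 / 3, 4.1, 2, 0.12)
  s <- ifelse(x <= q1, 1L, ifelse(x <= q2, 2L, 3L))
  sv <- sim_surv((log(2) / 2.43) * c(1, 2, 4)[s], cens_max = 6)
  m <- scan_1d_double(x, sv$time, sv$event)
  expect_false(m$fallback)
  expect_lt(abs(m$cutoff_lo - q1), 0.65)
  expect_lt(abs(m$cutoff_hi - q2), 0.65)
  expect_true(m$accepted)
  # hazard order follows the expression strata for this pro-oncogenic plant
  expect_true(all(diff(m$stratum_log_hazard) > 0))
  lab <- m$grouping$labels
  expect_identical(as.character(lab[x <= q1 - 0.3][1]), "low")
})

test_that("double cut-off scan falls back on a single-step hazard", {
  set.seed(48)
  n <- 300
  x <- sort(rnorm(n, 6)); names(x) <- sprintf("S%04d", 1:n)
  # hazard has a single sharp step: the profile has one dominant maximum
  sv <- sim_surv(0.25 * 4^(x > 6), cens_max = 8)
  m <- scan_1d_double(x, sv$time, sv$event, min_cutoff_gap_frac = 0.45)
  if (m$fallback) {
    expect_false(m$accepted)
    expect_true(is.na(m$cutoff_hi))
  } else {
    succeed("qualifying second maximum existed for this draw")
  }
})

test_that("2D search space nests the 1D search", {
  set.seed(49)
  pf <- planted_feature(250, hr = 2.5)
  pm <- scan_2d(pf$x, pf$x, pf$time, pf$event,
                feature_pair = c("f", "f"))
  m1 <- scan_1d(pf$x, pf$time, pf$event, candidates = pm$grid$c1)
  expect_lte(pm$wald$p, m1$wald$p + 1e-12)
})

test_that("2D scan with design fixed to high/high-vs-rest and open second
           axis reduces to the 1D scan", {
  set.seed(50)
  pf <- planted_feature(200, hr = 2.5)
  x2 <- rnorm(200, 8)
  cand <- quantile(pf$x, (1:20) / 21, names = FALSE)
  res <- survstrat:::scan2d_cpp(
    pf$time, as.integer(pf$event), as.numeric(pf$x), x2,
    cand, min(x2) - 1, matrix(c(0L, 0L, 0L, 1L), 1), 20L)
  m1 <- scan_1d(pf$x, pf$time, pf$event, min_group_frac = 0.10,
                candidates = cand)
  expect_equal(res$c1, m1$cutoff, tolerance = 1e-12)
  expect_equal(res$p, m1$wald$p, tolerance = 1e-10)
  expect_equal(res$beta, m1$wald$beta, tolerance = 1e-10)
})

test_that("planted 2D interaction is identified with both cut-offs", {
  set.seed(51)
  n <- 600
  x1 <- rgpd(n, 4.1, 2, 0.12); x2 <- rgpd(n, 4.1, 2, 0.12)
  names(x1) <- names(x2) <- sprintf("S%04d", 1:n)
  cut <- qgpd(0.6, 4.1, 2, 0.12)
  sv <- sim_surv((log(2) / 2.43) * 3^(x1 > cut & x2 > cut), cens_max = 6)
  pm <- scan_2d(x1, x2, sv$time, sv$event)
  hh <- pm$design$risk_map["high/high"]
  others <- pm$design$risk_map[setdiff(names(pm$design$risk_map), "high/high")]
  # the selected design isolates the high/high quadrant from the rest
  expect_true(all(others == others[1]) && hh != others[1])
  expect_lt(abs(pm$cutoffs[1] - cut), 0.5)
  expect_lt(abs(pm$cutoffs[2] - cut), 0.5)
})

test_that("synergy counts equal brute-force enumeration", {
  set.seed(52)
  n <- 150
  xs <- lapply(1:5, function(i) {
    x <- rgpd(n, 4.1, 2, 0.12); names(x) <- sprintf("S%04d", 1:n); x
  })
  names(xs) <- sprintf("f%d", 1:5)
  cut <- qgpd(0.6, 4.1, 2, 0.12)
  sv <- sim_surv(0.28 * 2.5^(xs[[1]] > cut) * 2^(xs[[2]] > cut & xs[[3]] > cut))
  pairs <- combn(5, 2)
  pms <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    scan_2d(xs[[i1]], xs[[i2]], sv$time, sv$event,
            feature_pair = c(names(xs)[i1], names(xs)[i2]))
  })
  freq <- synergy_frequency(pms, p_threshold = 0.05)
  brute <- setNames(integer(5), names(xs))
  for (pm in pms) {
    if (pm$synergistic && pm$wald$p < 0.05)
      brute[pm$feature_pair] <- brute[pm$feature_pair] + 1L
  }
  expect_identical(freq[names(brute)], brute)
  lone <- names(brute)[brute == 0]
  if (length(lone)) expect_identical(unname(freq[lone[1]]), 0L)
})
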
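test_that("product-limit estimator matches hand calculations", {
  km0 <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_length(km0$event_times, 0L)
  expect_equal(km_survival_at(km0, c(0.5, 2, 10)), c(1, 1, 1))

  km <- km_curve(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$event_times, c(1, 2))
  expect_equal(km$survival, c(2 / 3, 1 / 3))
  expect_equal(km_survival_at(km, c(0.5, 1.5, 5)), c(1, 2 / 3, 1 / 3))

  expect_survstrat_error(km_curve(numeric(0), integer(0)), "EmptyCohortError")
})

test_that("product-limit estimator agrees with survival::survfit and is
           permutation-invariant", {
  set.seed(21)
  for (rep in 1:3) {
    n <- 100
    tm <- round(rexp(n, 0.4), 2) + 0.01   # rounding forces ties
    ev <- rbinom(n, 1, 0.6)
    km <- km_curve(tm, ev)
    sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
    at <- sf$time[sf$n.event > 0]
    expect_lt(max(abs(km_survival_at(km, at) -
                        sf$surv[sf$n.event > 0])), 1e-12)
    perm <- sample.int(n)
    km2 <- km_curve(tm[perm], ev[perm])
    expect_equal(km2, km)
  }
})

test_that("log-rank matches a hand oracle and survival::survdiff", {
  # exchangeable groups: statistic exactly zero
  tm <- c(1, 2, 3, 1, 2, 3); ev <- c(1, 0, 1, 1, 0, 1)
  lr <- logrank_test(rep(c("a", "b"), each = 3), tm, ev)
  expect_equal(lr$chisq, 0)
  expect_equal(lr$p, 1)

  # 6-patient example against a brute-force observed-minus-expected oracle
  tm <- c(1, 3, 4, 2, 5, 6); ev <- c(1, 1, 0, 1, 1, 1)
  grp <- rep(c("a", "b"), each = 3)
  O <- E <- 0
  for (u in sort(unique(tm[ev == 1]))) {
    at <- tm >= u
    d <- sum(tm == u & ev == 1)
    O <- O + sum(tm == u & ev == 1 & grp == "a")
    E <- E + d * sum(at & grp == "a") / sum(at)
  }
  lr <- logrank_test(grp, tm, ev)
  expect_equal(unname(lr$observed[1] - lr$expected[1]), O - E,
               tolerance = 1e-10)

  # k = 3 against survdiff
  set.seed(22)
  for (rep in 1:3) {
    n <- 150
    g <- sample(c("low", "intermediate", "high"), n, replace = TRUE)
    h <- c(low = 0.2, intermediate = 0.4, high = 0.8)[g]
    sv <- sim_surv(h)
    lr <- logrank_test(g, sv$time, sv$event)
    sd_ <- survival::survdiff(survival::Surv(sv$time, sv$event) ~ g)
    expect_equal(lr$chisq, sd_$chisq, tolerance = 1e-8)
    expect_equal(lr$df, 2L)
  }
  expect_survstrat_error(logrank_test(rep("a", 6), tm, ev),
                         "DegenerateGroupError")
})

test_that("binary Cox-Wald agrees with survival::coxph and is label-symmetric", {
  set.seed(23)
  n <- 500
  z <- rbinom(n, 1, 0.4)
  sv <- sim_surv(0.25 * 3^z, cens_max = 10)   # planted HR = 3, ~30% censoring
  w <- cox_binary_wald(z, sv$time, sv$event)
  fit <- survival::coxph(survival::Surv(sv$time, sv$event) ~ z, ties = "efron")
  expect_equal(w$beta, unname(coef(fit)), tolerance = 1e-8)
  expect_equal(w$se, sqrt(vcov(fit)[1, 1]), tolerance = 1e-8)
  ci <- confint(fit)
  expect_gt(log(w$hr), ci[1]); expect_lt(log(w$hr), ci[2])
  expect_gt(w$hr, 1.5)  # planted effect direction

  w2 <- cox_binary_wald(1 - z, sv$time, sv$event)
  expect_equal(w2$beta, -w$beta, tolerance = 1e-10)
  expect_equal(w2$p, w$p, tolerance = 1e-10)

  expect_survstrat_error(cox_binary_wald(rep(1, n), sv$time, sv$event),
                         "NoContrastError")
})

test_that("Cox coefficient sign matches which KM curve lies below", {
  set.seed(24)
  n <- 300
  z <- rbinom(n, 1, 0.5)
  sv <- sim_surv(0.3 * 2.5^z, cens_max = 10)
  w <- cox_binary_wald(z, sv$time, sv$event)
  km1 <- km_curve(sv$time[z == 1], sv$event[z == 1])
  km0 <- km_curve(sv$time[z == 0], sv$event[z == 0])
  tmed <- median(sv$time)
  below <- km_survival_at(km1, tmed) < km_survival_at(km0, tmed)
  expect_identical(w$beta > 0, below)
})

test_that("BH-FDR equals the step-up definition", {
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(25)
  p <- runif(40)
  q <- bh_fdr(p)
  m <- length(p)
  ord <- order(p)
  qs <- vapply(seq_len(m),
               function(i) min(1, min(p[ord][i:m] * m / (i:m))), numeric(1))
  brute <- numeric(m)
  brute[ord] <- qs
  expect_equal(q, brute)
  expect_true(all(q >= p))
  expect_survstrat_error(bh_fdr(c(0.5, 1.2)), "ValidationError")
})

test_that("weighted kappa: perfect agreement, independence, symmetry", {
  lv <- c("low", "intermediate", "high")
  set.seed(26)
  a <- setNames(sample(lv, 500, replace = TRUE, prob = c(.4, .4, .2)),
                sprintf("S%03d", 1:500))
  k1 <- weighted_kappa(a, a)
  expect_equal(k1$kappa, 1)

  b <- setNames(sample(a), names(a))   # permuted: independent margins
  k0 <- weighted_kappa(a, b)
  expect_lt(abs(k0$kappa), 0.1)
  expect_gt(k0$p, 1e-4)

  ksym <- weighted_kappa(b, a)
  expect_equal(ksym$kappa, k0$kappa, tolerance = 1e-12)

  names(b) <- sprintf("T%03d", 1:500)
  expect_survstrat_error(weighted_kappa(a, b), "AlignmentError")
})
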
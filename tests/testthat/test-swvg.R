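make_models <- function(n = 200, hrs = c(3, 2.5, 2), seed = 61,
                        phenos = rep("pro-oncogenic", length(hrs))) {
  set.seed(seed)
  sid <- sprintf("S%04d", 1:n)
  sv <- NULL
  xs <- list()
  # shared survival driven by the first feature; the rest get refit anyway
  models <- list()
  h <- rep(log(2) / 2.43, n)
  for (i in seq_along(hrs)) {
    x <- rgpd(n, 4.1, 2, 0.12); names(x) <- sid
    cut <- qgpd(0.5, 4.1, 2, 0.12)
    risky <- if (phenos[i] == "pro-oncogenic") x > cut else x <= cut
    h <- h * hrs[i]^(0.5 * risky)
    xs[[i]] <- x
  }
  svv <- sim_surv(h, cens_max = 6)
  for (i in seq_along(hrs)) {
    models[[i]] <- scan_1d(xs[[i]], svv$time, svv$event,
                           feature_id = sprintf("f%d", i))
  }
  list(models = models, time = svv$time, event = svv$event, xs = xs, sid = sid)
}

test_that("votes follow the risk grouping of each model", {
  mm <- make_models(hrs = c(3, 3), phenos = c("pro-oncogenic",
                                              "tumor-suppressor-like"),
                    seed = 61)
  votes <- build_votes(mm$models)
  expect_true(all(votes %in% c(-1L, 1L)))
  for (i in 1:2) {
    m <- mm$models[[i]]
    lab <- m$grouping$labels[colnames(votes)]
    expect_identical(unname(votes[i, ] == 1L),
                     unname(as.character(lab) == "high"))
    # vote orientation vs the expression side of the cut-off
    above <- mm$xs[[i]][colnames(votes)] > m$cutoff
    if (m$phenotype == "pro-oncogenic") {
      expect_identical(unname(votes[i, above]), rep(1L, sum(above)))
    } else {
      expect_identical(unname(votes[i, above]), rep(-1L, sum(above)))
    }
  }
  # votes rebuilt from serialized models are identical
  paths <- replicate(2, withr::local_tempfile(fileext = ".json",
                                              .local_envir = parent.frame(2)))
  for (i in 1:2) save_model(mm$models[[i]], paths[i])
  votes2 <- build_votes(lapply(paths, load_model))
  expect_identical(votes2[, colnames(votes)], votes[, colnames(votes)])
})

test_that("patient scores are the weight-normalized vote mean", {
  v <- matrix(c(1, -1, 1), 3, 1, dimnames = list(c("a", "b", "c"), "S1"))
  expect_equal(unname(score_patients(v, c(3, 2, 1))), 1 / 3)
  v2 <- matrix(1L, 4, 2, dimnames = list(letters[1:4], c("S1", "S2")))
  expect_equal(unname(score_patients(v2, rep(2, 4))), c(1, 1))
  v3 <- matrix(c(1, -1), 2, 1, dimnames = list(c("a", "b"), "S1"))
  expect_equal(unname(score_patients(v3, c(1, 1))), 0)
  expect_survstrat_error(score_patients(v3, c(0, 0)), "ValidationError")

  # duplicating a feature with its weight split in half leaves scores alone
  set.seed(62)
  v4 <- matrix(sample(c(-1L, 1L), 30, TRUE), 3, 10,
               dimnames = list(c("a", "b", "c"), sprintf("S%d", 1:10)))
  w4 <- c(2, 1.4, 0.6)
  v5 <- rbind(v4, a2 = v4[1, ])
  expect_equal(score_patients(v5, c(1, 1.4, 0.6, 1)),
               score_patients(v4, w4))
})

test_that("score stratification is monotone in the score", {
  mm <- make_models(n = 300, hrs = c(3, 2.5, 2), seed = 63)
  votes <- build_votes(mm$models)
  sc <- score_patients(votes)
  st <- stratify_scores(sc, mm$time, mm$event, k = 2)
  lab <- st$grouping$labels[names(sc)]
  expect_lt(max(sc[lab == "low"]), min(sc[lab == "high"]) + 1e-12)
  expect_lt(st$overall_logrank_p, 0.05)
})

test_that("forward selection keeps informative features and improves on the
           best single model", {
  set.seed(64)
  n <- 400
  sid <- sprintf("S%04d", 1:n)
  n_inf <- 8; n_null <- 30
  xs <- c(lapply(seq_len(n_inf), function(i) {
    x <- rgpd(n, 4.1, 2, 0.12); names(x) <- sid; x
  }), lapply(seq_len(n_null), function(i) {
    x <- rgpd(n, 4.1, 2, 0.12); names(x) <- sid; x
  }))
  cut <- qgpd(0.5, 4.1, 2, 0.12)
  h <- rep(log(2) / 2.43, n)
  for (i in seq_len(n_inf)) h <- h * 1.45^(xs[[i]] > cut)
  sv <- sim_surv(h, cens_max = 6)
  models <- lapply(seq_along(xs), function(i)
    tryCatch(scan_1d(xs[[i]], sv$time, sv$event,
                     feature_id = sprintf("f%02d", i)),
             survstrat_error = function(e) NULL))
  models <- models[!vapply(models, is.null, NA)]
  vm <- swvg_select(models, sv$time, sv$event, k = 2)
  inf_sel <- sum(vm$selected_features %in% sprintf("f%02d", 1:n_inf))
  expect_gte(inf_sel, 5L)
  p_best_single <- min(vapply(models, function(m) m$wald$p, numeric(1)))
  expect_lte(vm$overall_logrank_p, p_best_single)
  # trace consistency at the full subset size
  votes <- build_votes(models)
  sc_all <- score_patients(votes)
  st_all <- stratify_scores(sc_all, sv$time, sv$event, k = 2)
  expect_equal(vm$selection_trace$p[length(models)],
               st_all$overall_logrank_p, tolerance = 1e-10)
})

test_that("a single candidate reproduces its own grouping", {
  mm <- make_models(n = 200, hrs = 3, seed = 65)
  vm <- swvg_select(mm$models[1], mm$time, mm$event, k = 2)
  m <- mm$models[[1]]
  expect_identical(as.character(vm$grouping$labels[names(m$grouping$labels)]),
                   as.character(m$grouping$labels))
})

test_that("three planted score clusters give ordered significant groups", {
  set.seed(66)
  ok <- 0L
  for (s in 1:5) {
    mm <- make_models(n = 600, hrs = c(2.6, 2.2, 1.9, 1.7), seed = 660 + s)
    vm <- tryCatch(swvg_select(mm$models, mm$time, mm$event, k = 3),
                   survstrat_error = function(e) NULL)
    if (is.null(vm) || vm$k != 3L) next
    lab <- vm$grouping$labels
    ids <- names(lab)
    pw <- combn(c("low", "intermediate", "high"), 2)
    ps <- vapply(seq_len(ncol(pw)), function(j) {
      keep <- as.character(lab) %in% pw[, j]
      logrank_test(as.character(lab)[keep],
                   mm$time[match(ids, mm$sid)][keep],
                   mm$event[match(ids, mm$sid)][keep])$p
    }, numeric(1))
    if (all(ps < 0.05)) ok <- ok + 1L
  }
  expect_gte(ok, 3L)
})

test_that("cut-off stability separates strong features from noise", {
  set.seed(67)
  pf <- planted_feature(500, hr = 5, q = 0.5)
  cvs <- cv_stability(pf$x, pf$time, pf$event, repeats = 5, folds = 10,
                      seed = 671, feature_id = "strong")
  expect_equal(cvs$confidence, 1.0)
  expect_lt(cvs$cutoff_cv, 5)
  # definitional identity
  expect_equal(cvs$cutoff_cv,
               100 * sd(cvs$fold_cutoffs) / mean(cvs$fold_cutoffs))

  nc <- null_cohort(500)
  x0 <- rgpd(500, 4.1, 2, 0.12); names(x0) <- sprintf("S%04d", 1:500)
  cv0 <- cv_stability(x0, nc$time, nc$event, repeats = 5, folds = 10,
                      seed = 672, feature_id = "noise")
  expect_lt(cv0$confidence, 0.997)
})
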
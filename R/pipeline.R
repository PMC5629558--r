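#' Default pipeline configuration
#'
#' All thresholds default to the method's standard settings: expression
#' filter 4.1, minimum group fraction 0.10, pairwise Wald level 0.05,
#' three-group log-rank level 0.005, 1000 K-means runs, 0.90 feature
#' co-clustering threshold, 10 cross-validation folds, top-100 feature
#' ranking, and a synergy membership threshold of 50 pairs. The number of
#' repeated CV partitions defaults to 10 (100 fold fits per feature).
#'
#' @param seed integer seed (mandatory for any stochastic stage).
#' @param out_dir output directory, or `NULL` to keep results in memory.
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed = NULL, out_dir = NULL) {
  list(
    input = list(expression = NULL, clinical = NULL),
    synthetic = list(enabled = TRUE, n_samples = 486L, n_features = 167L),
    seed = seed,
    out_dir = out_dir,
    min_expr = 4.1,
    min_group_frac = 0.10,
    p_pairwise = 0.05,
    p_logrank3 = 0.005,
    fdr = 0.05,
    fold_change = 1.5,
    kmeans_runs = 1000L,
    feature_threshold = 0.90,
    cv_folds = 10L,
    cv_repeats = 10L,
    cv_confidence = 0.997,
    cv_max_cv = 1,
    top_n = 100L,
    p_max = 0.05,
    pairs_top = 100L,
    grid_quantiles = 49L,
    min_pairs = 50L,
    k_risk = 3L
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys follow [default_run_config()].
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), user)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$seed))
    ss_stop("ConfigError", "a seed is mandatory: the pipeline has stochastic stages")
  chk <- function(val, lo, hi, nm) {
    if (!is.numeric(val) || val < lo || val > hi)
      ss_stop("ConfigError", sprintf("%s must lie in [%g, %g]", nm, lo, hi))
  }
  chk(cfg$min_group_frac, 0.01, 0.45, "min_group_frac")
  chk(cfg$p_pairwise, 0, 1, "p_pairwise")
  chk(cfg$p_logrank3, 0, 1, "p_logrank3")
  chk(cfg$feature_threshold, 0.5, 1, "feature_threshold")
  chk(cfg$cv_folds, 2, 20, "cv_folds")
  chk(cfg$kmeans_runs, 1, 1e6, "kmeans_runs")
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full stratification workflow
#'
#' Executes the stages in order: load or simulate the cohort, align,
#' expression filter, single cut-off scan of every feature, cross-validated
#' stability screen, paired scans over the top features, weighted voting
#' grouping, consensus K-means, and signature intersection. Every artifact
#' embeds the seed; re-running with the same config and seed reproduces the
#' summary byte for byte. A stage failure stops with the stage name;
#' artifacts of completed stages are already on disk.
#'
#' @param config a `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @param expr,surv optional in-memory inputs overriding the config paths.
#' @return the run summary (named list of per-stage counts and headline
#'   statistics), invisibly. With `out_dir` set, writes `summary.json`,
#'   per-stage TSV reports, and the voting model JSON there.
#' @export
run_pipeline <- function(config = default_run_config(), expr = NULL,
                         surv = NULL) {
  cfg <- validate_run_config(config)
  out <- cfg$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), error = function(e) {
      ss_stop("ConfigError",
              sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    message(sprintf("[survstrat] %-12s %6.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  summary <- list(seed = cfg$seed)

  cohort <- stage("input", {
    if (!is.null(expr) && !is.null(surv)) {
      list(expr = expr, surv = surv)
    } else if (isTRUE(cfg$synthetic$enabled)) {
      gen <- generate_cohort(
        synthetic_truth(n_samples = cfg$synthetic$n_samples,
                        n_features = cfg$synthetic$n_features),
        seed = cfg$seed)
      if (!is.null(out)) {
        write_expression(gen$expr, file.path(out, "expression.tsv"))
        write_clinical(gen$surv, file.path(out, "clinical.tsv"))
      }
      gen[c("expr", "surv")]
    } else {
      list(expr = read_expression(cfg$input$expression),
           surv = read_clinical(cfg$input$clinical))
    }
  })
  al <- align_cohort(cohort$expr, cohort$surv)
  ex <- al$expr; sv <- al$surv
  summary$n_samples <- ncol(ex)
  summary$n_features_input <- nrow(ex)

  ex <- stage("filter", filter_features(ex, min_expr = cfg$min_expr))
  summary$n_features_filtered <- nrow(ex)

  models <- stage("ddss1d", {
    ms <- list()
    for (f in rownames(ex)) {
      m <- tryCatch(scan_1d(ex[f, ], sv$time_years, sv$event,
                            min_group_frac = cfg$min_group_frac,
                            feature_id = f),
                    survstrat_error = function(e) NULL)
      if (!is.null(m)) ms[[f]] <- m
    }
    if (!is.null(out)) {
      rep1 <- data.frame(
        feature_id = vapply(ms, `[[`, "", "feature_id"),
        cutoff = vapply(ms, `[[`, 0, "cutoff"),
        hr = vapply(ms, function(m) m$wald$hr, 0),
        wald_p = vapply(ms, function(m) m$wald$p, 0),
        phenotype = vapply(ms, `[[`, "", "phenotype"))
      write_tsv(rep1[order(rep1$wald_p), ], file.path(out, "ddss1d.tsv"))
    }
    ms
  })
  summary$n_models_1d <- length(models)
  top_set <- rank_top(models, n = cfg$top_n, p_max = cfg$p_max)
  summary$n_top <- length(top_set)

  cv <- stage("cv", {
    lapply(stats::setNames(nm = top_set), function(f)
      cv_stability(ex[f, ], sv$time_years, sv$event,
                   repeats = cfg$cv_repeats, folds = cfg$cv_folds,
                   min_group_frac = cfg$min_group_frac,
                   seed = cfg$seed + 1L, feature_id = f))
  })
  cv_rep <- data.frame(
    feature_id = names(cv),
    confidence = vapply(cv, `[[`, 0, "confidence"),
    cutoff_cv = vapply(cv, `[[`, 0, "cutoff_cv"),
    pass = vapply(cv, function(z) z$pass_confidence && z$pass_cv, NA))
  if (!is.null(out)) write_tsv(cv_rep, file.path(out, "cv_stability.tsv"))
  cv_set <- cv_rep$feature_id[cv_rep$pass]
  summary$n_cv_confident <- sum(vapply(cv, `[[`, NA, "pass_confidence"))
  summary$n_cv_pass <- length(cv_set)

  pair_models <- stage("ddss2d", {
    feats <- utils::head(top_set, cfg$pairs_top)
    pms <- list()
    if (length(feats) >= 2L) {
      cmb <- utils::combn(feats, 2L)
      for (j in seq_len(ncol(cmb))) {
        pm <- tryCatch(
          scan_2d(ex[cmb[1L, j], ], ex[cmb[2L, j], ], sv$time_years,
                  sv$event, min_group_frac = cfg$min_group_frac,
                  grid_quantiles = cfg$grid_quantiles,
                  feature_pair = cmb[, j]),
          survstrat_error = function(e) NULL)
        if (!is.null(pm)) pms[[j]] <- pm
      }
    }
    pms[!vapply(pms, is.null, NA)]
  })
  summary$n_pairs_scanned <- length(pair_models)
  summary$n_synergistic <- sum(vapply(pair_models, function(pm)
    isTRUE(pm$synergistic) && pm$wald$p < cfg$p_pairwise, NA))
  syn_freq <- synergy_frequency(pair_models, p_threshold = cfg$p_pairwise)
  synergy_set <- names(syn_freq)[syn_freq >= cfg$min_pairs]
  summary$n_synergy_set <- length(synergy_set)
  if (!is.null(out) && length(syn_freq))
    write_tsv(data.frame(feature_id = names(syn_freq),
                         synergistic_pairs = as.integer(syn_freq)),
              file.path(out, "synergy.tsv"))

  voting <- stage("swvg", {
    swvg_select(models[top_set], sv$time_years[order(sv$sample_id)],
                sv$event[order(sv$sample_id)], k = cfg$k_risk,
                min_group_frac = cfg$min_group_frac)
  })
  summary$swvg_selected <- length(voting$selected_features)
  summary$swvg_logrank_p <- voting$overall_logrank_p
  if (!is.null(out)) save_model(voting, file.path(out, "voting_model.json"))

  km <- stage("kmeans", {
    robust_kmeans(ex, k = 2L, runs = cfg$kmeans_runs,
                  feature_threshold = cfg$feature_threshold,
                  seed = cfg$seed + 2L)
  })
  summary$kmeans_core_fraction <- km$core_fraction
  summary$kmeans_n_cores <- length(km$robust_sample_cores)
  summary$kmeans_logrank_p <- if (length(km$robust_sample_cores) >= 2L)
    compare_cores(km, sv)$p else NA_real_

  sig <- stage("signature", {
    withCallingHandlers(
      intersect_signature(top_set, cv_set, synergy_set, name = "pipeline"),
      survstrat_warning = function(w) invokeRestart("muffleWarning"))
  })
  summary$signature_size <- length(sig$members)
  summary$signature_members <- sig$members
  if (length(sig$members) >= 2L) {
    vs <- swvg_select(models[sig$members], sv$time_years[order(sv$sample_id)],
                      sv$event[order(sv$sample_id)], k = cfg$k_risk,
                      min_group_frac = cfg$min_group_frac)
    summary$signature_logrank_p <- vs$overall_logrank_p
    summary$signature_k <- vs$k
  }

  if (!is.null(out)) {
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(summary)
}
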
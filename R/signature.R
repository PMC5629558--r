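#' Rank the top survival-significant features
#'
#' Sorts fitted single cut-off models by Wald P-value and keeps the `n`
#' best that are significant at `p_max`.
#'
#' @param models list of `cutoff_model_1d`.
#' @param n maximum number of features; default 100.
#' @param p_max significance ceiling; default 0.05.
#' @return character vector of feature ids, most significant first.
#' @export
rank_top <- function(models, n = 100L, p_max = 0.05) {
  p <- vapply(models, function(m) m$wald$p, numeric(1))
  ids <- vapply(models, `[[`, "", "feature_id")
  keep <- order(p)[p[order(p)] < p_max]
  unname(utils::head(ids[keep], n))
}

#' Normalize miRNA identifiers
#'
#' Lower-cases and strips a leading `hsa-` prefix so that identifiers from
#' different sources compare; `-3p`/`-5p` arm suffixes are preserved as
#' distinct features.
#'
#' @param ids character vector of identifiers.
#' @return normalized identifiers.
#' @export
normalize_mirna_ids <- function(ids) {
  sub("^hsa-", "", tolower(trimws(ids)))
}

#' Three-way intersection signature
#'
#' Builds a signature as the intersection of the top-ranked 1D scan set,
#' the cross-validation stability set, and the 2D synergy set (features
#' with many synergistic pairs), recording each source's size.
#'
#' @param top_set,cv_set,synergy_set character vectors of feature ids over
#'   a shared universe.
#' @param name signature name.
#' @return a `signature_spec` with `members` and `construction` metadata.
#'   An empty intersection raises an `EmptySignatureWarning` (not an
#'   error).
#' @export
intersect_signature <- function(top_set, cv_set, synergy_set,
                                name = "intersection") {
  members <- Reduce(intersect, list(unique(top_set), unique(cv_set),
                                    unique(synergy_set)))
  if (length(members) == 0L)
    ss_warn("EmptySignatureWarning", "the three feature sets have an empty intersection")
  structure(list(name = name, members = members,
                 construction = list(type = "three-way intersection",
                                     source_sizes = c(top = length(unique(top_set)),
                                                      cv = length(unique(cv_set)),
                                                      synergy = length(unique(synergy_set))))),
            class = "signature_spec")
}

#' Literature-consensus signature
#'
#' Intersects the top-ranked feature set with the union of published
#' signature feature lists, after identifier normalization. Per member the
#' provenance records which literature set(s) matched; literature
#' identifiers that match nothing in the analysis universe are reported,
#' not silently dropped.
#'
#' @param top_set character vector of analysis feature ids.
#' @param literature_sets named list of character vectors of published
#'   feature ids.
#' @param name signature name.
#' @return a `signature_spec` with `members`, a `provenance` data frame,
#'   and `unmatched_literature_ids`.
#' @export
consensus_signature <- function(top_set, literature_sets,
                                name = "literature-consensus") {
  if (is.null(names(literature_sets)))
    names(literature_sets) <- sprintf("set%d", seq_along(literature_sets))
  top_norm <- normalize_mirna_ids(top_set)
  lit_norm <- lapply(literature_sets, normalize_mirna_ids)
  lit_union <- unique(unlist(lit_norm))
  hit <- top_norm %in% lit_union
  members <- unique(top_set[hit])
  if (length(members) == 0L)
    ss_warn("EmptySignatureWarning", "no top-set feature matches the literature union")
  prov <- do.call(rbind, lapply(members, function(f) {
    fn <- normalize_mirna_ids(f)
    srcs <- names(lit_norm)[vapply(lit_norm, function(s) fn %in% s, logical(1))]
    data.frame(feature_id = f, sources = paste(srcs, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  unmatched <- unlist(lapply(names(lit_norm), function(nm) {
    miss <- !(lit_norm[[nm]] %in% top_norm)
    literature_sets[[nm]][miss]
  }), use.names = FALSE)
  structure(list(name = name, members = members,
                 provenance = prov %||% data.frame(feature_id = character(0),
                                                   sources = character(0)),
                 unmatched_literature_ids = unique(unmatched),
                 construction = list(type = "top-set x literature union",
                                     source_sizes = c(top = length(unique(top_set)),
                                                      literature_union = length(lit_union)))),
            class = "signature_spec")
}

#' @export
print.signature_spec <- function(x, ...) {
  cat(sprintf("Signature '%s': %d members (%s)\n", x$name, length(x$members),
              x$construction$type))
  if (length(x$members)) cat("  ", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' Associate a risk grouping with categorical clinical variables
#'
#' For every clinical category, cross-tabulates it against the risk
#' grouping and reports the Pearson chi-square P-value (no continuity
#' correction) plus, when the category has the same number of levels as the
#' grouping, the linearly weighted kappa treating the category's sorted
#' levels as ordinal. Rows are flagged when more than 20% of expected cell
#' counts fall below 5.
#'
#' @param grouping a `risk_grouping`.
#' @param clinical data frame with `sample_id` and category columns
#'   (e.g. stage, grade, residual, therapy_outcome).
#' @param categories which columns to test; default every non-id column.
#' @return data frame with one row per tested category: `category`,
#'   `chisq_p`, `kappa`, `kappa_p`, `low_expected`, `n`.
#' @export
associate_clinical <- function(grouping, clinical,
                               categories = setdiff(colnames(clinical),
                                                    c("sample_id", "time_years",
                                                      "event", "excluded"))) {
  lab <- grouping$labels
  rows <- list()
  for (cat_ in categories) {
    v <- clinical[[cat_]]
    names(v) <- clinical$sample_id
    common <- intersect(names(lab), names(v)[!is.na(v)])
    if (length(common) == 0L) {
      message(sprintf("associate_clinical: '%s' has no non-missing values; skipped", cat_))
      next
    }
    g <- factor(as.character(lab[common]), levels = levels(lab))
    cv <- factor(as.character(v[common]))
    tab <- table(g, cv)
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    low_exp <- mean(chi$expected < 5) > 0.2
    kap <- kap_p <- NA_real_
    if (nlevels(cv) == nlevels(g)) {
      mapped <- levels(g)[as.integer(cv)]
      names(mapped) <- common
      kw <- weighted_kappa(lab[common], mapped)
      kap <- kw$kappa; kap_p <- kw$p
    }
    rows[[cat_]] <- data.frame(category = cat_, chisq_p = chi$p.value,
                               kappa = kap, kappa_p = kap_p,
                               low_expected = low_exp, n = length(common),
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
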
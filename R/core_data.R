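#' Validate or construct an expression matrix
#'
#' An expression matrix is a plain numeric matrix of log2 intensities with
#' features in rows and samples in columns. Row and column names are the
#' feature and sample identifiers; both must be unique and every cell must be
#' finite. Missing values are rejected rather than imputed: imputation policy
#' is the caller's responsibility and silently guessing one would change
#' every downstream cut-off.
#'
#' @param values numeric matrix, features x samples, with rownames and
#'   colnames set.
#' @return the validated matrix, invisibly classed as `expression_matrix`.
#' @export
as_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    ss_stop("ValidationError", "expression data must be a numeric matrix")
  fid <- rownames(values); sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    ss_stop("ValidationError", "expression matrix needs feature rownames and sample colnames")
  if (anyDuplicated(fid))
    ss_stop("DuplicateIdError",
            sprintf("duplicated feature id(s): %s",
                    paste(unique(fid[duplicated(fid)]), collapse = ", ")))
  if (anyDuplicated(sid))
    ss_stop("DuplicateIdError",
            sprintf("duplicated sample id(s): %s",
                    paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    ss_stop("ValidationError",
            sprintf("non-finite expression value at feature '%s', sample '%s'; pre-impute missing cells",
                    fid[bad[1]], sid[bad[2]]))
  }
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Read a tab-separated expression matrix
#'
#' Expects feature identifiers in the first column, sample identifiers in the
#' header row, and a numeric body of log2 intensities. Row and column order
#' are preserved.
#'
#' @param path path to a TSV file.
#' @return an `expression_matrix` (numeric matrix, features x samples).
#' @export
read_expression <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", row.names = NULL)
  if (ncol(raw) < 2L)
    ss_stop("ParseError", "expression file needs a feature-id column plus at least one sample column")
  fid <- raw[[1L]]
  if (anyDuplicated(fid))
    ss_stop("DuplicateIdError",
            sprintf("duplicated feature id(s): %s",
                    paste(unique(fid[duplicated(fid)]), collapse = ", ")))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (any(is.na(num) & !is.na(body))) {
    bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)[1, ]
    ss_stop("ParseError",
            sprintf("non-numeric cell at row %d ('%s'), column %d ('%s')",
                    bad[1], fid[bad[1]], bad[2], colnames(body)[bad[2]]))
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    ss_stop("ParseError",
            sprintf("missing cell at row %d ('%s'), column %d ('%s')",
                    bad[1], fid[bad[1]], bad[2], colnames(body)[bad[2]]))
  }
  rownames(num) <- fid
  colnames(num) <- colnames(body)
  as_expression_matrix(num)
}

#' Write an expression matrix as TSV
#'
#' Values are written at full precision so that a write/read round trip is
#' the identity.
#'
#' @param expr expression matrix.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(feature_id = rownames(expr),
                   format(expr, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

CLINICAL_COLS <- c("stage", "grade", "residual", "therapy_outcome", "age")

#' Read a per-sample clinical survival table
#'
#' Expects a header with `sample_id`, `time_years`, `event` and optionally
#' `stage`, `grade`, `residual`, `therapy_outcome`, `age`. Times are in
#' years. Rows with a missing time or event are kept but flagged in the
#' `excluded` column so exclusions are visible, never silent; the exclusion
#' count is stored in the `n_excluded` attribute.
#'
#' @param path path to a TSV file.
#' @return a `survival_table` data frame with columns `sample_id`,
#'   `time_years`, `event`, `excluded` and any clinical columns present.
#' @export
read_clinical <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("sample_id", "time_years", "event")
  if (!all(need %in% colnames(raw)))
    ss_stop("ParseError",
            sprintf("clinical file must contain columns %s", paste(need, collapse = ", ")))
  as_survival_table(raw)
}

#' Validate or construct a survival table
#'
#' @param df data frame with at least `sample_id`, `time_years`, `event`.
#' @return a validated `survival_table`.
#' @export
as_survival_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    ss_stop("DuplicateIdError",
            sprintf("duplicated sample id(s): %s",
                    paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")))
  time <- suppressWarnings(as.numeric(df$time_years))
  event <- suppressWarnings(as.numeric(df$event))
  excluded <- is.na(time) | is.na(event)
  if (any(!is.na(time) & time <= 0))
    ss_stop("ValidationError", "survival time must be strictly positive (years)")
  if (any(!is.na(event) & !event %in% c(0, 1)))
    ss_stop("ValidationError", "event indicator must be 0 (censored) or 1 (death)")
  out <- data.frame(sample_id = as.character(df$sample_id),
                    time_years = time, event = as.integer(event),
                    excluded = excluded, stringsAsFactors = FALSE)
  for (cc in intersect(CLINICAL_COLS, colnames(df))) out[[cc]] <- df[[cc]]
  attr(out, "n_excluded") <- sum(excluded)
  class(out) <- c("survival_table", class(out))
  out
}

#' Write a clinical survival table as TSV
#' @param surv survival table.
#' @param path output path.
#' @export
write_clinical <- function(surv, path) {
  keep <- setdiff(colnames(surv), "excluded")
  df <- as.data.frame(surv)[, keep, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Construct a risk grouping
#'
#' A risk grouping assigns every sample to one of the ordered labels
#' low < intermediate < high (k = 3) or low < high (k = 2).
#'
#' @param labels named character vector (names are sample ids) with values in
#'   `low`, `intermediate`, `high`.
#' @param provenance free-text note on the producing operation.
#' @return a `risk_grouping` object.
#' @export
risk_grouping <- function(labels, provenance = "") {
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    ss_stop("ValidationError", "risk grouping labels must be uniquely named by sample id")
  lv <- c("low", "intermediate", "high")
  if (!all(labels %in% lv))
    ss_stop("ValidationError", "risk labels must be in {low, intermediate, high}")
  used <- lv[lv %in% unique(labels)]
  f <- factor(labels, levels = used, ordered = TRUE)
  names(f) <- names(labels)
  if (nlevels(f) < 2L)
    ss_stop("DegenerateGroupError", "a risk grouping needs at least two non-empty groups")
  structure(list(labels = f, k = nlevels(f), provenance = provenance),
            class = "risk_grouping")
}

#' @export
print.risk_grouping <- function(x, ...) {
  cat(sprintf("Risk grouping: %d samples, k = %d (%s)\n",
              length(x$labels), x$k, paste(levels(x$labels), collapse = " < ")))
  print(table(x$labels))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Align an expression matrix and a survival table on shared samples
#'
#' Joins on the intersection of sample ids; samples flagged excluded in the
#' survival table are dropped. The counts of discarded samples from each side
#' are reported in attributes `n_dropped_expr` / `n_dropped_surv`, and the
#' result orders samples by sorted id so it does not depend on input file
#' row order.
#'
#' @param expr expression matrix.
#' @param surv survival table.
#' @return list with aligned `expr` (matrix) and `surv` (data frame).
#' @export
align_cohort <- function(expr, surv) {
  usable <- surv$sample_id[!surv$excluded]
  common <- sort(intersect(colnames(expr), usable))
  if (length(common) == 0L)
    ss_stop("AlignmentError", "no usable samples shared between expression and survival tables")
  ex <- expr[, common, drop = FALSE]
  sv <- as.data.frame(surv)[match(common, surv$sample_id), , drop = FALSE]
  rownames(sv) <- NULL
  out <- list(expr = ex, surv = sv)
  attr(out, "n_dropped_expr") <- ncol(expr) - length(common)
  attr(out, "n_dropped_surv") <- nrow(surv) - length(common)
  out
}

#' Serialize a fitted model to JSON
#'
#' All fitted model objects (1D/triple cut-off models, 2D pair models, voting
#' models) serialize to a JSON document carrying a `schema_version` and a
#' `model_type` so they can be re-read with [load_model()].
#'
#' @param model a fitted model object.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  doc <- list(schema_version = 1L, model_type = class(model)[1L],
              payload = model_payload(model))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

model_payload <- function(model) {
  strip <- function(x) {
    if (inherits(x, "risk_grouping")) {
      return(list(.risk_grouping = TRUE, labels = as.character(x$labels),
                  sample_ids = names(x$labels), k = x$k,
                  provenance = x$provenance))
    }
    if (is.list(x)) return(lapply(unclass(x), strip))
    unclass(x)
  }
  strip(model)
}

#' Load a fitted model from JSON
#' @param path path written by [save_model()].
#' @return the model object with its original class.
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version) || doc$schema_version != 1L)
    ss_stop("ParseError", "unsupported model schema version")
  restore <- function(x) {
    if (is.list(x) && isTRUE(x$.risk_grouping)) {
      lab <- x$labels
      names(lab) <- x$sample_ids
      return(risk_grouping(lab, provenance = x$provenance %||% ""))
    }
    if (is.list(x)) return(lapply(x, restore))
    x
  }
  out <- restore(doc$payload)
  class(out) <- doc$model_type
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
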
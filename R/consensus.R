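# connected components of a logical adjacency matrix, then split any
# non-clique component greedily so that every returned group is a clique
clique_groups <- function(adj) {
  n <- nrow(adj)
  diag(adj) <- TRUE
  seen <- logical(n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- s; frontier <- s; seen[s] <- TRUE
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nb] <- TRUE
      comp <- c(comp, nb)
      frontier <- nb
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  out <- list()
  for (comp in comps) {
    if (length(comp) < 2L) next
    sub <- adj[comp, comp, drop = FALSE]
    if (all(sub)) { out[[length(out) + 1L]] <- comp; next }
    nodes <- comp
    while (length(nodes) >= 2L) {
      deg <- colSums(adj[nodes, nodes, drop = FALSE])
      seedn <- nodes[which.max(deg)]
      clique <- seedn
      for (v in nodes[order(-deg)]) {
        if (v %in% clique) next
        if (all(adj[v, clique])) clique <- c(clique, v)
      }
      if (length(clique) >= 2L) out[[length(out) + 1L]] <- sort(clique)
      nodes <- setdiff(nodes, clique)
    }
  }
  out[order(-vapply(out, length, integer(1)))]
}

#' Robust consensus K-means subtyping
#'
#' Runs K-means many times with Manhattan (L1) distance, random data-point
#' initialization and component-wise median centroid updates, accumulating
#' how often every pair of samples (and of features) lands in the same
#' cluster. Robust sample cores are maximal groups co-clustered in 100% of
#' completed runs; robust feature clusters use the softer
#' `feature_threshold` (default co-clustered in > 90% of runs). Runs that
#' fail to stabilize within `max_iter` assignment iterations are discarded
#' and the denominator adjusted.
#'
#' @param expr expression matrix (features x samples); samples are
#'   clustered on their feature profiles and vice versa.
#' @param k number of clusters; default 2.
#' @param runs number of K-means repetitions; default 1000.
#' @param feature_threshold co-clustering frequency for feature clusters;
#'   default 0.90.
#' @param seed integer seed for the run initializations.
#' @param max_iter iteration cap per run; default 300.
#' @return a `consensus_result`: `sample_coassignment` and
#'   `feature_coassignment` frequency matrices, `robust_sample_cores`
#'   (list of sample-id vectors, largest first), `robust_feature_clusters`,
#'   `core_fraction` (fraction of samples in the two largest cores),
#'   `runs_completed`.
#' @export
robust_kmeans <- function(expr, k = 2L, runs = 1000L,
                          feature_threshold = 0.90, seed = 1L,
                          max_iter = 300L) {
  n <- ncol(expr); p <- nrow(expr)
  if (k > n / 2) ss_stop("ValidationError", "k must be at most half the sample count")
  if (any(!is.finite(expr))) ss_stop("ValidationError", "expression matrix must be finite")
  set.seed(seed)
  init_s <- t(vapply(seq_len(runs), function(i) sample.int(n, k), integer(k)))
  init_f <- t(vapply(seq_len(runs), function(i) sample.int(p, k), integer(k)))
  cs <- kmeans_consensus_cpp(t(expr), init_s, as.integer(max_iter))
  cf <- kmeans_consensus_cpp(unclass(expr), init_f, as.integer(max_iter))
  if (cs$completed == 0L || cf$completed == 0L)
    ss_stop("ValidationError", "no K-means run converged")
  fs <- cs$counts / cs$completed
  ff <- cf$counts / cf$completed
  dimnames(fs) <- list(colnames(expr), colnames(expr))
  dimnames(ff) <- list(rownames(expr), rownames(expr))
  cores_idx <- clique_groups(cs$counts == cs$completed)
  cores <- lapply(cores_idx, function(i) colnames(expr)[i])
  fclust_idx <- clique_groups(ff > feature_threshold)
  fclust <- lapply(fclust_idx, function(i) rownames(expr)[i])
  top2 <- sum(vapply(utils::head(cores, 2L), length, integer(1)))
  structure(list(sample_coassignment = fs, feature_coassignment = ff,
                 robust_sample_cores = cores,
                 robust_feature_clusters = fclust,
                 core_fraction = top2 / n,
                 in_core_fraction = sum(vapply(cores, length, integer(1))) / n,
                 runs_completed = cs$completed, runs_requested = runs,
                 k = k, feature_threshold = feature_threshold),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus K-means (k = %d, %d/%d runs completed)\n",
              x$k, x$runs_completed, x$runs_requested))
  cat(sprintf("  %d robust sample cores; two largest hold %.1f%% of samples\n",
              length(x$robust_sample_cores), 100 * x$core_fraction))
  cat(sprintf("  %d robust feature clusters at frequency > %.2f\n",
              length(x$robust_feature_clusters), x$feature_threshold))
  invisible(x)
}

#' Compare the survival of the two largest robust cores
#'
#' Log-rank test between the members of the two largest robust sample
#' cores.
#'
#' @param result a `consensus_result`.
#' @param surv survival table covering the core members.
#' @return list with `p`, `chisq`, and the two core memberships used.
#' @export
compare_cores <- function(result, surv) {
  if (length(result$robust_sample_cores) < 2L)
    ss_stop("DegenerateGroupError", "need at least two robust cores")
  c1 <- result$robust_sample_cores[[1L]]
  c2 <- result$robust_sample_cores[[2L]]
  ids <- c(c1, c2)
  sv <- as.data.frame(surv)
  m <- match(ids, sv$sample_id)
  if (anyNA(m)) ss_stop("AlignmentError", "core members missing from survival table")
  lr <- logrank_test(rep(c("core1", "core2"), c(length(c1), length(c2))),
                     sv$time_years[m], sv$event[m])
  list(p = lr$p, chisq = lr$chisq, cores = list(c1, c2))
}
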
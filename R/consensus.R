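#' Consensus clustering of tumors on a probe panel
#'
#' Repeatedly clusters row-subsampled data with k-means and records, for
#' each pair of samples, the fraction of co-subsampled runs in which they
#' fell in the same cluster. The final partition is a hierarchical
#' (average-linkage) cut of 1 - consensus into `k` groups. With
#' `subsample_fraction = 1` and a single resample the procedure reduces to
#' one plain k-means assignment.
#'
#' @param beta_subset Probes x samples beta matrix restricted to the
#'   selected panel (at least 2 probes, at least `2 * k` samples).
#' @param k Number of clusters (default 2: BRCA1-like vs BRCAx-like).
#' @param n_resamples Number of subsampled k-means runs (default 100).
#' @param subsample_fraction Fraction of samples drawn (without
#'   replacement) per run (default 0.8).
#' @param seed Integer seed; results are deterministic given it.
#' @param nstart Random restarts per k-means run (default 10).
#' @return List of class `consensus_result`: `consensus_matrix` (samples x
#'   samples, symmetric, unit diagonal), `assignments` (named integer
#'   vector of cluster labels 1..k), `k`.
#' @export
consensus_cluster <- function(beta_subset, k = 2L, n_resamples = 100L,
                              subsample_fraction = 0.8, seed = 1L,
                              nstart = 10L) {
  x <- t(as.matrix(beta_subset))        # samples x probes
  n <- nrow(x)
  if (ncol(x) < 2L) stop("need at least 2 probes")
  if (n < 2L * k) stop("need at least 2*k samples")
  if (nrow(unique(x)) < k)
    stop("degenerate input: fewer distinct sample profiles than clusters")
  withr::local_seed(seed)
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  co <- matrix(0, n, n, dimnames = list(ids, ids))
  both <- matrix(0, n, n, dimnames = list(ids, ids))
  m <- max(k, floor(subsample_fraction * n))
  for (r in seq_len(n_resamples)) {
    cl <- NULL
    for (attempt in seq_len(10L)) {     # redraw on empty-cluster failures
      idx <- sort(sample.int(n, m))
      sub <- x[idx, , drop = FALSE]
      if (nrow(unique(sub)) < k) next
      cl <- tryCatch(
        stats::kmeans(sub, centers = k, nstart = nstart, iter.max = 50L),
        error = function(e) NULL)
      if (!is.null(cl)) break
    }
    if (is.null(cl))
      stop("could not obtain k clusters in repeated resamples; input may be degenerate")
    same <- outer(cl$cluster, cl$cluster, "==")
    co[idx, idx] <- co[idx, idx] + same
    both[idx, idx] <- both[idx, idx] + 1
  }
  consensus <- ifelse(both > 0, co / both, 0)
  diag(consensus) <- 1
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  assignments <- stats::cutree(hc, k = k)
  structure(list(consensus_matrix = consensus,
                 assignments = assignments, k = k),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus clustering: %d samples, k = %d\n",
              nrow(x$consensus_matrix), x$k))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Call test-variant tumors from a consensus clustering
#'
#' Labels each cluster by the majority vote of its known-status members
#' (BRCA1-like or BRCAx-like); a tied vote makes the cluster ambiguous and
#' a cluster with no known-status member leaves its test tumors uncalled.
#' Each test-variant tumor then inherits its cluster's identity.
#'
#' @param result A [consensus_cluster()] result.
#' @param samples Sample sheet with `sample_id` and `group` (BRCA1 / BRCAx
#'   / test).
#' @return List: `cluster_identity` (per-cluster label: `"BRCA1-like"`,
#'   `"BRCAx-like"`, `"ambiguous"` or `"uncalled"`) and `test_calls`
#'   (data.frame `sample_id`, `cluster`, `call`).
#' @export
call_test_samples <- function(result, samples) {
  cl <- result$assignments
  grp <- stats::setNames(samples$group, samples$sample_id)[names(cl)]
  identity <- character(result$k)
  for (g in seq_len(result$k)) {
    members <- names(cl)[cl == g]
    known <- grp[members]
    n1 <- sum(known == "BRCA1"); nx <- sum(known == "BRCAx")
    identity[g] <- if (n1 + nx == 0L) "uncalled"
      else if (n1 > nx) "BRCA1-like"
      else if (nx > n1) "BRCAx-like"
      else "ambiguous"
  }
  test_ids <- names(cl)[grp == "test"]
  calls <- data.frame(
    sample_id = test_ids,
    cluster = unname(cl[test_ids]),
    call = ifelse(identity[cl[test_ids]] %in% c("BRCA1-like", "BRCAx-like"),
                  identity[cl[test_ids]], NA_character_),
    stringsAsFactors = FALSE
  )
  list(cluster_identity = identity, test_calls = calls)
}
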
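#' Sample-level quality control from array control metrics
#'
#' A sample fails QC if, for any control metric, its value lies more than
#' `sd_threshold` standard deviations away from that metric's mean across
#' all samples. Metrics with zero variance carry no information and are
#' skipped with a warning.
#'
#' @param control_metrics Numeric matrix, samples x metrics, with sample ids
#'   as row names (array internal-control summaries such as staining,
#'   hybridization, extension, bisulfite-conversion intensities).
#' @param sd_threshold Outlier threshold in standard deviations (default 3).
#' @return List of class `qc_report`: `passed_samples` (ids),
#'   `failed_samples` (data.frame `sample_id`, `metric`, `z`).
#' @export
sample_qc <- function(control_metrics, sd_threshold = 3) {
  m <- as.matrix(control_metrics)
  if (nrow(m) < 3L) stop("sample_qc needs at least 3 samples")
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("metric%d", seq_len(ncol(m)))
  fails <- list()
  for (j in seq_len(ncol(m))) {
    s <- stats::sd(m[, j])
    if (!is.finite(s) || s == 0) {
      warning(sprintf("metric '%s' has zero variance; skipped", colnames(m)[j]))
      next
    }
    z <- (m[, j] - mean(m[, j])) / s
    bad <- which(abs(z) > sd_threshold)
    if (length(bad))
      fails[[length(fails) + 1L]] <- data.frame(
        sample_id = rownames(m)[bad], metric = colnames(m)[j],
        z = unname(z[bad]), stringsAsFactors = FALSE)
  }
  failed <- if (length(fails)) do.call(rbind, fails) else
    data.frame(sample_id = character(0), metric = character(0),
               z = numeric(0), stringsAsFactors = FALSE)
  structure(list(
    passed_samples = setdiff(rownames(m), failed$sample_id),
    failed_samples = failed
  ), class = "qc_report")
}

#' Probe-level quality control from detection p-values
#'
#' A probe is discarded when it fails (detection p-value at or above
#' `p_cut`) in strictly more than `fail_fraction` of samples; a probe
#' failing in exactly that fraction is retained.
#'
#' @param detp Numeric matrix of detection p-values, probes x samples.
#' @param p_cut Per-call failure threshold on the detection p-value
#'   (default 0.05).
#' @param fail_fraction Tolerated fraction of failed samples per probe
#'   (default 0.20).
#' @return List of class `qc_report`: `retained_probes`, `dropped_probes`
#'   (ids), and `fail_fraction_per_probe`.
#' @export
probe_qc <- function(detp, p_cut = 0.05, fail_fraction = 0.20) {
  m <- as.matrix(detp)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty detection p-value matrix")
  if (is.null(rownames(m))) rownames(m) <- sprintf("cg%07d", seq_len(nrow(m)))
  frac <- rowMeans(m >= p_cut)
  dropped <- rownames(m)[frac > fail_fraction]
  structure(list(
    retained_probes = setdiff(rownames(m), dropped),
    dropped_probes = dropped,
    fail_fraction_per_probe = frac
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  if (!is.null(x$passed_samples))
    cat(sprintf("Sample QC: %d passed, %d failed\n",
                length(x$passed_samples),
                length(unique(x$failed_samples$sample_id))))
  if (!is.null(x$retained_probes))
    cat(sprintf("Probe QC: %d retained, %d dropped\n",
                length(x$retained_probes), length(x$dropped_probes)))
  invisible(x)
}
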
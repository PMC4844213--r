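#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted values: with p sorted ascending,
#' q(i) = min over j >= i of p(j) * m / j, mapped back to the input order
#' and capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1] with no missing entries")
  stats::p.adjust(p_values, method = "BH")
}

# rank-sum p for one probe; exact null when both groups are small and the
# data are tie-free, normal approximation with continuity correction
# otherwise
rank_sum_p <- function(x, y, exact_max_n = 8L) {
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- min(length(x), length(y)) <= exact_max_n && !has_ties
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)$p.value
  )
}

#' Per-probe two-group rank-sum screen
#'
#' Runs a two-sided Wilcoxon rank-sum test on every probe of a beta matrix
#' between the two groups defined by `labels`, reporting per-group medians,
#' the median difference (group2 - group1), and Benjamini-Hochberg
#' q-values. Samples with a missing label are excluded from this contrast
#' only.
#'
#' @param beta Probes x samples beta matrix.
#' @param labels Per-sample factor (or coercible) with exactly two levels;
#'   `NA` allowed. The first level is group 1 (for the mutation contrast,
#'   the BRCA1-mutant group, so `delta_beta` is BRCAx minus BRCA1).
#' @param contrast Label recorded in the output, one of `"mutation"`,
#'   `"ER"`, `"grade"` or any custom string.
#' @return data.frame: `probe_id`, `contrast`, `p_value`, `q_value`,
#'   `median_group1`, `median_group2`, `delta_beta`.
#' @export
wilcoxon_screen <- function(beta, labels, contrast = "mutation") {
  beta <- as.matrix(beta)
  if (length(labels) != ncol(beta))
    stop("labels must have one entry per sample")
  f <- factor(labels)
  keep <- !is.na(f)
  f <- droplevels(f[keep])
  if (nlevels(f) != 2L)
    stop(sprintf("contrast '%s': need exactly two groups after removing missing labels",
                 contrast))
  b <- beta[, keep, drop = FALSE]
  g1 <- f == levels(f)[1L]
  if (sum(g1) < 2L || sum(!g1) < 2L)
    stop(sprintf("contrast '%s': each group needs at least 2 samples", contrast))
  p <- apply(b, 1L, function(v) rank_sum_p(v[g1], v[!g1]))
  med1 <- apply(b[, g1, drop = FALSE], 1L, stats::median)
  med2 <- apply(b[, !g1, drop = FALSE], 1L, stats::median)
  data.frame(
    probe_id = rownames(b), contrast = contrast,
    p_value = unname(p), q_value = bh_fdr(unname(p)),
    median_group1 = unname(med1), median_group2 = unname(med2),
    delta_beta = unname(med2 - med1),
    stringsAsFactors = FALSE
  )
}

#' Probes unique to the mutation contrast
#'
#' The Venn-uniqueness step: keep probes significant (q below `q_cut`) in
#' the mutation contrast but not significant in either the ER or the grade
#' contrast. Probes absent from the ER or grade result tables (for example
#' because a contrast could not be run) count as not significant there.
#'
#' @param mutation_results,er_results,grade_results data.frames from
#'   [wilcoxon_screen()] on the same probe universe.
#' @param q_cut Significance threshold on the q-value (default 0.05).
#' @return Character vector of probe ids unique to the mutation contrast.
#' @export
venn_unique <- function(mutation_results, er_results, grade_results,
                        q_cut = 0.05) {
  sig <- function(res) {
    if (is.null(res) || nrow(res) == 0L) return(character(0))
    res$probe_id[res$q_value < q_cut]
  }
  setdiff(sig(mutation_results), union(sig(er_results), sig(grade_results)))
}

#' Filter candidate probes by absolute methylation difference
#'
#' Probes with an absolute median methylation difference between groups of
#' less than `min_abs_delta` are excluded; a probe exactly at the floor is
#' retained.
#'
#' @param candidates Character vector of candidate probe ids.
#' @param mutation_results [wilcoxon_screen()] output for the mutation
#'   contrast; every candidate must appear in it.
#' @param min_abs_delta Minimum absolute delta beta (default 0.05, i.e. 5%).
#' @return Character vector of probe ids passing the filter.
#' @export
effect_size_filter <- function(candidates, mutation_results,
                               min_abs_delta = 0.05) {
  missing <- setdiff(candidates, mutation_results$probe_id)
  if (length(missing))
    stop("candidates without a mutation-contrast result: ",
         paste(missing, collapse = ", "))
  d <- mutation_results$delta_beta[match(candidates,
                                         mutation_results$probe_id)]
  candidates[abs(d) >= min_abs_delta]
}

#' Genotype-by-group association test for a SNP-confounded probe
#'
#' Pearson chi-squared test (no continuity correction) of a 2 x k
#' genotype-count table; the probe is flagged for exclusion when genotype
#' frequencies differ between groups at p < 0.05, as for a CG>TG SNP in the
#' targeted CpG whose T allele is overrepresented in one group.
#'
#' @param genotype_counts Integer matrix, 2 rows (groups) x k genotype
#'   columns. All-zero genotype columns are dropped with a warning.
#' @param alpha Exclusion threshold (default 0.05).
#' @return List: `chi2`, `df`, `p`, `exclude`.
#' @export
snp_confound_test <- function(genotype_counts, alpha = 0.05) {
  m <- as.matrix(genotype_counts)
  if (nrow(m) != 2L || ncol(m) < 2L)
    stop("genotype_counts must be a 2 x k table with k >= 2")
  if (any(m < 0)) stop("counts must be nonnegative")
  zero <- colSums(m) == 0
  if (any(zero)) {
    warning("dropping all-zero genotype column(s): ",
            paste(which(zero), collapse = ", "))
    m <- m[, !zero, drop = FALSE]
  }
  if (ncol(m) < 2L) stop("fewer than 2 informative genotype columns")
  ## identical group distributions carry zero signal; chisq.test would
  ## still run but we report the exact degenerate answer
  tst <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(tst$statistic), df = unname(tst$parameter),
       p = unname(tst$p.value), exclude = unname(tst$p.value) < alpha)
}

#' Run the full probe-selection screen on a cohort
#'
#' Convenience wrapper chaining the three rank-sum screens (mutation status
#' on known-status samples, ER status and grade on all labelled samples),
#' the Venn-uniqueness step, and the effect-size filter. Grade is
#' dichotomized as low (grades 1-2) versus high (grade 3).
#'
#' @param beta Probes x samples beta matrix (post-QC).
#' @param samples Sample sheet with columns `sample_id`, `group`,
#'   `er_status`, `grade`.
#' @param q_cut FDR threshold (default 0.05).
#' @param min_abs_delta Effect-size floor (default 0.05).
#' @return List of class `selection_result`: the three per-contrast result
#'   tables, `significant_by_contrast` (id sets), `unique_to_mutation`,
#'   `passing_effect_filter`.
#' @export
select_probes <- function(beta, samples, q_cut = 0.05, min_abs_delta = 0.05) {
  beta <- as.matrix(beta)[, samples$sample_id, drop = FALSE]
  mut_lab <- factor(ifelse(samples$group == "BRCA1", "BRCA1",
                           ifelse(samples$group == "BRCAx", "BRCAx", NA)),
                    levels = c("BRCA1", "BRCAx"))
  er_lab <- factor(samples$er_status, levels = c("negative", "positive"))
  grade_lab <- factor(ifelse(is.na(samples$grade), NA,
                             ifelse(samples$grade >= 3, "high", "low")),
                      levels = c("low", "high"))
  res_mut <- wilcoxon_screen(beta, mut_lab, "mutation")
  res_er <- wilcoxon_screen(beta, er_lab, "ER")
  res_grade <- wilcoxon_screen(beta, grade_lab, "grade")
  uniq <- venn_unique(res_mut, res_er, res_grade, q_cut = q_cut)
  panel <- effect_size_filter(uniq, res_mut, min_abs_delta = min_abs_delta)
  structure(list(
    mutation = res_mut, ER = res_er, grade = res_grade,
    significant_by_contrast = list(
      mutation = res_mut$probe_id[res_mut$q_value < q_cut],
      ER = res_er$probe_id[res_er$q_value < q_cut],
      grade = res_grade$probe_id[res_grade$q_value < q_cut]
    ),
    unique_to_mutation = uniq,
    passing_effect_filter = panel
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  n <- vapply(x$significant_by_contrast, length, integer(1))
  cat(sprintf("Probe screen: %d mutation / %d ER / %d grade significant\n",
              n[["mutation"]], n[["ER"]], n[["grade"]]))
  cat(sprintf("  unique to mutation: %d; passing effect-size filter: %d\n",
              length(x$unique_to_mutation), length(x$passing_effect_filter)))
  invisible(x)
}
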
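#' Array-pyrosequencing agreement for one locus
#'
#' Intraclass correlation between array beta values and pyrosequencing
#' percent methylation (divided by 100 so both raters share the \[0, 1\]
#' scale) for matched samples. The two-way, single-measure,
#' absolute-agreement form ICC(A,1) is used, which penalizes systematic
#' scale shifts between platforms; the one-way and consistency forms are
#' available via `type`.
#'
#' @param array_beta Numeric vector of array beta values.
#' @param pyro_percent Numeric vector of pyrosequencing percent methylation
#'   for the same samples, same order. Pairs with a missing member are
#'   dropped; at least 3 complete pairs are required.
#' @param type `"agreement"` (default, ICC(A,1)), `"consistency"`
#'   (ICC(C,1)) or `"oneway"` (ICC(1)).
#' @return A single ICC value in \[-1, 1\].
#' @export
icc_array_vs_pyro <- function(array_beta, pyro_percent,
                              type = c("agreement", "consistency", "oneway")) {
  type <- match.arg(type)
  stopifnot(length(array_beta) == length(pyro_percent))
  ok <- stats::complete.cases(array_beta, pyro_percent)
  x <- array_beta[ok]
  y <- pyro_percent[ok] / 100
  if (length(x) < 3L) stop("insufficient pairs: need at least 3 complete pairs")
  n <- length(x); k <- 2L
  dat <- cbind(x, y)
  grand <- mean(dat); row_m <- rowMeans(dat); col_m <- colMeans(dat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((dat - grand)^2) - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  switch(type,
    agreement = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
    consistency = (msr - mse) / (msr + (k - 1) * mse),
    oneway = {
      msw <- (ssc + sse) / (n * (k - 1))
      (msr - msw) / (msr + (k - 1) * msw)
    })
}

#' Pairwise squared Pearson correlation between loci
#'
#' Squared Pearson correlation for every pair of loci in a pyrosequencing
#' table, using pairwise-complete observations. Pairs with fewer than 3
#' complete observations, or involving a constant locus, are reported as
#' `NA`.
#'
#' @param pyro Loci x samples percent-methylation matrix with `NA` for
#'   failed assays.
#' @param loci Loci to include (default: all rows).
#' @return Symmetric matrix of R-squared values with unit diagonal.
#' @export
pairwise_r2 <- function(pyro, loci = rownames(pyro)) {
  m <- as.matrix(pyro)[loci, , drop = FALSE]
  p <- length(loci)
  out <- matrix(NA_real_, p, p, dimnames = list(loci, loci))
  diag(out) <- 1
  if (p < 2L) return(out)
  for (i in seq_len(p - 1L)) {
    for (j in seq(i + 1L, p)) {
      ok <- stats::complete.cases(m[i, ], m[j, ])
      if (sum(ok) < 3L) next
      xi <- m[i, ok]; xj <- m[j, ok]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      out[i, j] <- out[j, i] <- stats::cor(xi, xj)^2
    }
  }
  out
}

# extract a Wald p for a term, NA if the coefficient did not estimate
wald_p <- function(fit, term) {
  ct <- summary(fit)$coefficients
  if (!term %in% rownames(ct)) return(NA_real_)
  ct[term, "Pr(>|z|)"]
}

#' Logistic-regression independence of methylation from ER and grade
#'
#' Fits three nested logistic regressions of mutation status on
#' methylation, adding ER status and then grade, on complete cases only,
#' and reports Wald p-values: a marker whose methylation term loses
#' significance once ER enters the model is not independent of ER and
#' should not be combined with pathology likelihood ratios downstream.
#' Perfect separation is flagged and the affected p-values reported as
#' missing.
#'
#' @param meth Per-sample methylation values (beta or percent).
#' @param mutation Binary mutation status (1 = pathogenic) per sample.
#' @param er Binary or factor ER status per sample.
#' @param grade Binary or factor grade (low/high) per sample.
#' @param min_complete Minimum number of complete cases (default 10).
#' @return List of class `independence_result`: `p_meth_alone`,
#'   `p_meth_given_ER`, `p_ER`, `p_meth_given_ER_grade`, `p_grade`,
#'   `n_complete_cases`, `separation`.
#' @export
independence_glm <- function(meth, mutation, er, grade,
                             min_complete = 10L) {
  df <- data.frame(meth = as.numeric(meth),
                   mutation = as.numeric(mutation),
                   er = factor(er), grade = factor(grade))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < min_complete)
    stop(sprintf("need at least %d complete cases, have %d",
                 min_complete, nrow(df)))
  separated <- FALSE
  fit_glm <- function(formula) {
    fit <- withCallingHandlers(
      stats::glm(formula, family = stats::binomial(), data = df),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    ## glm's own 0/1 check fires only at ~1e-15; catch separation earlier
    mu <- stats::fitted(fit)
    if (any(mu < 1e-8) || any(mu > 1 - 1e-8)) separated <<- TRUE
    fit
  }
  m1 <- fit_glm(mutation ~ meth)
  m2 <- fit_glm(mutation ~ meth + er)
  m3 <- fit_glm(mutation ~ meth + er + grade)
  if (separated)
    warning("perfect separation detected; affected p-values reported as NA")
  grab <- function(fit, term) if (separated) NA_real_ else wald_p(fit, term)
  er_term <- grep("^er", names(stats::coef(m2)), value = TRUE)[1]
  grade_term <- grep("^grade", names(stats::coef(m3)), value = TRUE)[1]
  structure(list(
    p_meth_alone = grab(m1, "meth"),
    p_meth_given_ER = grab(m2, "meth"),
    p_ER = grab(m2, er_term),
    p_meth_given_ER_grade = grab(m3, "meth"),
    p_grade = grab(m3, grade_term),
    n_complete_cases = nrow(df),
    separation = separated
  ), class = "independence_result")
}

#' @export
print.independence_result <- function(x, ...) {
  cat(sprintf("Logistic independence (n = %d complete cases)\n",
              x$n_complete_cases))
  cat(sprintf("  p(meth) alone: %.4g; given ER: %.4g; given ER+grade: %.4g\n",
              x$p_meth_alone, x$p_meth_given_ER, x$p_meth_given_ER_grade))
  if (x$separation) cat("  [perfect separation flagged]\n")
  invisible(x)
}

#' Rank-sum validation of pyrosequencing loci
#'
#' Two-sided Wilcoxon rank-sum test per locus comparing percent methylation
#' between the two labelled groups, dropping failed assays; loci whose
#' groups empty out after dropping are skipped with a warning.
#'
#' @param pyro Loci x samples percent-methylation matrix with `NA`.
#' @param labels Two-level factor (or coercible) per sample; the first
#'   level is group 1 so the reported difference is group2 - group1.
#' @return data.frame: `locus_id`, `p_value`, `median_group1`,
#'   `median_group2`, `difference`, `n_group1`, `n_group2`.
#' @export
validation_wilcoxon <- function(pyro, labels) {
  m <- as.matrix(pyro)
  if (length(labels) != ncol(m)) stop("labels must match samples")
  f <- factor(labels)
  if (nlevels(droplevels(f[!is.na(f)])) != 2L)
    stop("need exactly two groups")
  lev <- levels(droplevels(f[!is.na(f)]))
  rows <- lapply(rownames(m), function(loc) {
    v <- m[loc, ]
    ok <- !is.na(v) & !is.na(f)
    x <- v[ok & f == lev[1]]
    y <- v[ok & f == lev[2]]
    if (length(x) < 2L || length(y) < 2L) {
      warning(sprintf("locus '%s' skipped: a group is empty or too small after dropping missing values", loc))
      return(NULL)
    }
    data.frame(locus_id = loc, p_value = rank_sum_p(x, y),
               median_group1 = stats::median(x),
               median_group2 = stats::median(y),
               difference = stats::median(y) - stats::median(x),
               n_group1 = length(x), n_group2 = length(y),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
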
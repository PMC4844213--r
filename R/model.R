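#' z-score transform against stored reference statistics
#'
#' @param values Numeric vector (missing values stay missing).
#' @param ref_mean,ref_sd Reference mean and standard deviation; `ref_sd`
#'   must be positive.
#' @return `(values - ref_mean) / ref_sd`.
#' @export
zscore_transform <- function(values, ref_mean, ref_sd) {
  if (!is.finite(ref_sd) || ref_sd <= 0)
    stop("degenerate marker: reference standard deviation must be positive")
  (values - ref_mean) / ref_sd
}

# ridge-stabilized Newton (IRLS) logistic fit; lambda penalizes slopes only
ridge_logistic <- function(X, y, lambda = 1e-2, max_iter = 100L,
                           tol = 1e-10) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  b <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% b)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X1, X1 * w) + pen
    g <- crossprod(X1, y - mu) - pen %*% b
    step <- solve(H, g)
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  b
}

#' Fit the multi-marker logistic prediction model
#'
#' Maximum-likelihood logistic regression of pathogenicity on z-scored
#' marker values. Markers whose missingness leaves too few complete cases
#' are dropped greedily (most-missing first) until every class retains at
#' least `min_complete_per_class` complete cases — the same pruning that
#' removes a marker measurable in too few tumors. Under perfect separation
#' the fit falls back to a lightly ridge-penalized Newton solver with a
#' warning, keeping coefficients finite.
#'
#' @param z_matrix Samples x markers matrix of z-scored values (`NA`
#'   allowed); column names are the marker ids.
#' @param labels Binary outcome (1 = pathogenic) per sample.
#' @param ref_means,ref_sds Optional per-marker reference statistics to
#'   store in the model (defaults 0 / 1, i.e. `z_matrix` is already on the
#'   reference scale).
#' @param min_complete_per_class Minimum complete cases per class
#'   (default 5).
#' @param ridge_lambda Penalty used by the separation fallback.
#' @return Object of class `meth_logistic_model`: `marker_ids`,
#'   `ref_means`, `ref_sds`, `intercept`, `coefficients`, `training_n`,
#'   `dropped_markers`, `separation`.
#' @export
fit_logistic <- function(z_matrix, labels, ref_means = NULL, ref_sds = NULL,
                         min_complete_per_class = 5L, ridge_lambda = 1e-2) {
  z <- as.matrix(z_matrix)
  if (is.null(colnames(z))) colnames(z) <- sprintf("m%d", seq_len(ncol(z)))
  y <- as.numeric(labels)
  stopifnot(length(y) == nrow(z))
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("labels contain a single class; cannot fit")
  keep_rows <- !is.na(y)
  z <- z[keep_rows, , drop = FALSE]
  y <- y[keep_rows]

  markers <- colnames(z)
  dropped <- character(0)
  enough <- function(cols) {
    cc <- stats::complete.cases(z[, cols, drop = FALSE])
    sum(cc & y == 1) >= min_complete_per_class &&
      sum(cc & y == 0) >= min_complete_per_class
  }
  while (length(markers) > 0L && !enough(markers)) {
    n_miss <- colSums(is.na(z[, markers, drop = FALSE]))
    worst <- markers[which.max(n_miss)]
    dropped <- c(dropped, worst)
    markers <- setdiff(markers, worst)
  }
  if (length(markers) == 0L)
    stop("no marker subset leaves enough complete cases per class")
  cc <- stats::complete.cases(z[, markers, drop = FALSE])
  zf <- z[cc, markers, drop = FALSE]
  yf <- y[cc]
  if (length(unique(yf)) < 2L)
    stop("complete cases contain a single class; cannot fit")

  separation <- FALSE
  df <- data.frame(y = yf, zf, check.names = FALSE)
  fml <- stats::as.formula(paste("y ~", paste(sprintf("`%s`", markers),
                                              collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  mu <- stats::fitted(fit)
  if (any(mu < 1e-8) || any(mu > 1 - 1e-8)) separation <- TRUE
  if (separation || !fit$converged) {
    warning("perfect separation (or non-convergence); using ridge-stabilized fit")
    b <- ridge_logistic(zf, yf, lambda = ridge_lambda)
  } else {
    b <- unname(stats::coef(fit))
  }
  if (is.null(ref_means)) ref_means <- stats::setNames(rep(0, length(markers)), markers)
  if (is.null(ref_sds)) ref_sds <- stats::setNames(rep(1, length(markers)), markers)
  structure(list(
    marker_ids = markers,
    ref_means = ref_means[markers],
    ref_sds = ref_sds[markers],
    intercept = b[1L],
    coefficients = stats::setNames(b[-1L], markers),
    training_n = length(yf),
    dropped_markers = dropped,
    separation = separation
  ), class = "meth_logistic_model")
}

#' @export
print.meth_logistic_model <- function(x, ...) {
  cat(sprintf("Methylation logistic model: %d marker(s), trained on %d tumors\n",
              length(x$marker_ids), x$training_n))
  cat(sprintf("  intercept %.4f\n", x$intercept))
  for (m in x$marker_ids)
    cat(sprintf("  %s: coef %.4f (ref mean %.4f, sd %.4f)\n",
                m, x$coefficients[[m]], x$ref_means[[m]], x$ref_sds[[m]]))
  if (length(x$dropped_markers))
    cat("  dropped for missingness:",
        paste(x$dropped_markers, collapse = ", "), "\n")
  invisible(x)
}

#' Train a prediction model from raw marker values
#'
#' Computes per-marker z-score reference statistics (mean, sd) from the
#' known-status training samples, transforms, and fits the logistic model.
#' Reference statistics are stored in the model so that later test samples
#' are standardized against the training distribution, never their own.
#'
#' @param values Samples x markers matrix of raw marker values (beta or
#'   percent methylation; `NA` allowed).
#' @param labels Binary outcome per sample (1 = pathogenic).
#' @param ... Passed to [fit_logistic()].
#' @return A `meth_logistic_model`.
#' @export
train_prediction_model <- function(values, labels, ...) {
  v <- as.matrix(values)
  if (is.null(colnames(v))) colnames(v) <- sprintf("m%d", seq_len(ncol(v)))
  mu <- apply(v, 2L, mean, na.rm = TRUE)
  sg <- apply(v, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sg)) || any(sg <= 0))
    stop("degenerate marker: zero variance in training data")
  z <- sweep(sweep(v, 2L, mu), 2L, sg, "/")
  fit_logistic(z, labels, ref_means = mu, ref_sds = sg, ...)
}

#' Predict per-tumor probability of pathogenicity
#'
#' Applies the stored z-score references and logistic coefficients to new
#' marker values. Prediction is complete-case: samples missing any model
#' marker are skipped and listed with the reason. Probabilities are clamped
#' to \[1e-12, 1 - 1e-12\] so downstream likelihood ratios stay finite.
#'
#' @param model A `meth_logistic_model`.
#' @param marker_values Samples x markers matrix of raw marker values with
#'   sample ids as row names; must contain every model marker as a column.
#' @return data.frame: `sample_id`, `probability`, `predicted`
#'   (probability >= 0.5), plus attribute `"skipped"` (data.frame of
#'   skipped samples with reasons).
#' @export
predict_prob <- function(model, marker_values) {
  v <- as.matrix(marker_values)
  if (is.null(rownames(v))) rownames(v) <- sprintf("S%03d", seq_len(nrow(v)))
  miss <- setdiff(model$marker_ids, colnames(v))
  if (length(miss))
    stop("marker_values lacks model marker(s): ", paste(miss, collapse = ", "))
  v <- v[, model$marker_ids, drop = FALSE]
  cc <- stats::complete.cases(v)
  skipped <- data.frame(sample_id = rownames(v)[!cc],
                        reason = rep("missing marker value", sum(!cc)),
                        stringsAsFactors = FALSE)
  z <- sweep(sweep(v[cc, , drop = FALSE], 2L, model$ref_means), 2L,
             model$ref_sds, "/")
  eta <- model$intercept + drop(z %*% model$coefficients)
  p <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  out <- data.frame(sample_id = rownames(v)[cc], probability = unname(p),
                    predicted = unname(p >= 0.5), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Leave-one-out cross-validation of the prediction model
#'
#' Refits the model n times, each time holding out one sample, and predicts
#' it at threshold 0.5. By default the z-score reference statistics are
#' recomputed inside every fold so no information from the held-out sample
#' leaks into its own standardization; set `refit_reference = FALSE` to
#' standardize all folds against the full-cohort references. A fold whose
#' model cannot be fitted counts as incorrect with a warning.
#'
#' @param values Samples x markers matrix of raw marker values.
#' @param labels Binary outcome per sample.
#' @param refit_reference Recompute z references per fold (default TRUE).
#' @param ... Passed to the per-fold [fit_logistic()].
#' @return List: `accuracy`, `n_correct`, `n`, `probabilities` (held-out
#'   probability per sample, `NA` for unfittable folds).
#' @export
loocv <- function(values, labels, refit_reference = TRUE, ...) {
  v <- as.matrix(values)
  if (is.null(rownames(v))) rownames(v) <- sprintf("S%03d", seq_len(nrow(v)))
  y <- as.numeric(labels)
  n <- nrow(v)
  prob <- stats::setNames(rep(NA_real_, n), rownames(v))
  correct <- logical(n)
  for (i in seq_len(n)) {
    fit <- tryCatch({
      if (refit_reference)
        train_prediction_model(v[-i, , drop = FALSE], y[-i], ...)
      else {
        mu <- apply(v, 2L, mean, na.rm = TRUE)
        sg <- apply(v, 2L, stats::sd, na.rm = TRUE)
        z <- sweep(sweep(v, 2L, mu), 2L, sg, "/")
        fit_logistic(z[-i, , drop = FALSE], y[-i],
                     ref_means = mu, ref_sds = sg, ...)
      }
    }, error = function(e) NULL)
    if (is.null(fit)) {
      warning(sprintf("fold %d unfittable; counted as incorrect", i))
      next
    }
    pr <- tryCatch(predict_prob(fit, v[i, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(pr) || nrow(pr) == 0L) next
    prob[i] <- pr$probability[1L]
    correct[i] <- (pr$probability[1L] >= 0.5) == (y[i] == 1)
  }
  list(accuracy = mean(correct), n_correct = sum(correct), n = n,
       probabilities = prob)
}

#' Positive and negative predictive value
#'
#' @param predicted Logical/binary predicted labels.
#' @param truth Logical/binary true labels.
#' @return List: `ppv` = TP/(TP+FP), `npv` = TN/(TN+FN); `NA` when a
#'   denominator is empty.
#' @export
ppv_npv <- function(predicted, truth) {
  p <- as.logical(predicted); t <- as.logical(truth)
  stopifnot(length(p) == length(t))
  tp <- sum(p & t); fp <- sum(p & !t)
  tn <- sum(!p & !t); fn <- sum(!p & t)
  list(ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}
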
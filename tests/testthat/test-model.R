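test_that("z-score transform obeys its defining identities", {
  expect_equal(zscore_transform(5, 5, 2), 0)
  expect_equal(zscore_transform(7, 5, 2), 1)
  expect_error(zscore_transform(1, 0, 0), "degenerate marker")
  x <- c(1, 4, NA, 9)
  z <- zscore_transform(x, 2, 3)
  expect_true(is.na(z[3]))
  ## standardizing a column by its own statistics gives mean 0, sd 1
  set.seed(1)
  v <- rnorm(50, 10, 4)
  z2 <- zscore_transform(v, mean(v), sd(v))
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(sd(z2), 1, tolerance = 1e-12)
})

test_that("logistic fit matches a Newton-Raphson oracle to 1e-6", {
  set.seed(11)
  n <- 80
  X <- cbind(m1 = rnorm(n), m2 = rnorm(n))
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * X[, 1] - 0.5 * X[, 2]))
  fit <- fit_logistic(X, y)
  oracle <- nr_logistic(X, y)
  expect_equal(fit$intercept, oracle[1], tolerance = 1e-6)
  expect_equal(unname(fit$coefficients), oracle[2:3], tolerance = 1e-6)
})

test_that("null markers give near-zero slopes and a class-balance intercept", {
  set.seed(21)
  n <- 1500
  X <- cbind(m1 = rnorm(n))
  y <- rbinom(n, 1, 0.3)
  fit <- fit_logistic(X, y)
  expect_lt(abs(fit$coefficients[["m1"]]), 0.15)
  expect_equal(fit$intercept, qlogis(mean(y)), tolerance = 0.05)
})

test_that("a balanced symmetric single marker gives a near-zero intercept", {
  x <- c(-3, -2, -1, 1, 2, 3, -3, -2, -1, 1, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1, 0, 0, 1, 0, 1, 1)
  fit <- fit_logistic(matrix(x, ncol = 1, dimnames = list(NULL, "m1")), y)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
})

test_that("generative coefficients are recovered within 2 SE at n = 400", {
  set.seed(4)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.2 + 1.5 * x))
  fit <- fit_logistic(matrix(x, ncol = 1, dimnames = list(NULL, "m1")), y)
  se <- sqrt(diag(vcov(glm(y ~ x, family = binomial()))))[2]
  expect_lt(abs(fit$coefficients[["m1"]] - 1.5), 2 * se)
})

test_that("markers are dropped greedily by missingness", {
  set.seed(7)
  n <- 24
  X <- cbind(good = rnorm(n), bad = rnorm(n))
  X[1:16, "bad"] <- NA             # too few complete cases with 'bad' kept
  y <- rep(c(0, 1), each = 12)
  fit <- fit_logistic(X, y, min_complete_per_class = 5)
  expect_equal(fit$dropped_markers, "bad")
  expect_equal(fit$marker_ids, "good")
  expect_error(fit_logistic(X, rep(1, n)), "single class")
})

test_that("perfect separation falls back to a finite ridge fit", {
  x <- c(-(5:1), 1:5)
  y <- rep(c(0, 1), each = 5)
  expect_warning(
    fit <- fit_logistic(matrix(x, ncol = 1, dimnames = list(NULL, "m1")), y),
    "separation")
  expect_true(is.finite(fit$coefficients[["m1"]]))
  expect_gt(fit$coefficients[["m1"]], 0)
})

test_that("stored references standardize test samples without leakage", {
  set.seed(14)
  n <- 60
  vals <- cbind(mk1 = rnorm(n, 50, 10), mk2 = rnorm(n, 30, 5))
  rownames(vals) <- sprintf("S%02d", seq_len(n))
  y <- rbinom(n, 1, plogis(0.05 * (vals[, 1] - 50)))
  model <- train_prediction_model(vals, y)
  expect_equal(unname(model$ref_means), unname(colMeans(vals)))
  ## all z = 0 -> probability = logistic(intercept)
  newv <- matrix(model$ref_means, nrow = 1,
                 dimnames = list("T01", model$marker_ids))
  expect_equal(predict_prob(model, newv)$probability,
               plogis(model$intercept), tolerance = 1e-12)
})

test_that("predictions are monotone in positively weighted markers", {
  model <- structure(list(
    marker_ids = "m1", ref_means = c(m1 = 0), ref_sds = c(m1 = 1),
    intercept = 0, coefficients = c(m1 = 1), training_n = 10,
    dropped_markers = character(0), separation = FALSE),
    class = "meth_logistic_model")
  grid <- matrix(seq(-3, 3, length.out = 13), ncol = 1,
                 dimnames = list(NULL, "m1"))
  p <- predict_prob(model, grid)$probability
  expect_true(all(diff(p) > 0))
  expect_equal(p[7], 0.5)          # intercept 0, z = 0
  ## missing marker values are skipped with a recorded reason
  withna <- matrix(c(1, NA), ncol = 1,
                   dimnames = list(c("A", "B"), "m1"))
  out <- predict_prob(model, withna)
  expect_equal(out$sample_id, "A")
  expect_equal(attr(out, "skipped")$sample_id, "B")
})

test_that("probabilities are clamped away from 0 and 1", {
  model <- structure(list(
    marker_ids = "m1", ref_means = c(m1 = 0), ref_sds = c(m1 = 1),
    intercept = 0, coefficients = c(m1 = 50), training_n = 10,
    dropped_markers = character(0), separation = FALSE),
    class = "meth_logistic_model")
  ext <- matrix(c(-10, 10), ncol = 1, dimnames = list(c("a", "b"), "m1"))
  p <- predict_prob(model, ext)$probability
  expect_true(all(p >= 1e-12 & p <= 1 - 1e-12))
  expect_no_error(prob_to_lr(p))
})

test_that("LOOCV equals the definitional per-sample exclusion oracle", {
  set.seed(33)
  n <- 24
  vals <- cbind(mk = rnorm(n, 40, 10))
  rownames(vals) <- sprintf("S%02d", seq_len(n))
  y <- rbinom(n, 1, plogis(0.08 * (vals[, 1] - 40)))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  cv <- loocv(vals, y)
  oracle <- vapply(seq_len(n), function(i) {
    mu <- mean(vals[-i, 1]); sg <- sd(vals[-i, 1])
    z_tr <- (vals[-i, 1] - mu) / sg
    fit <- glm(y[-i] ~ z_tr, family = binomial())
    unname(plogis(coef(fit)[1] + coef(fit)[2] * (vals[i, 1] - mu) / sg))
  }, numeric(1))
  expect_equal(unname(cv$probabilities), oracle, tolerance = 1e-9)
  expect_equal(cv$accuracy, mean((oracle >= 0.5) == (y == 1)))
})

test_that("LOOCV is perfect on separated data and near chance under a null", {
  vals <- cbind(mk = c(10, 11, 12, 13, 14, 30, 31, 32, 33, 34))
  rownames(vals) <- sprintf("S%02d", 1:10)
  y <- rep(c(0, 1), each = 5)
  cv <- suppressWarnings(loocv(vals, y, min_complete_per_class = 2))
  expect_equal(cv$accuracy, 1)

  set.seed(17)
  accs <- replicate(15, {
    yy <- sample(rep(0:1, each = 8))
    vv <- cbind(mk = rnorm(16))
    rownames(vv) <- sprintf("S%02d", 1:16)
    suppressWarnings(loocv(vv, yy)$accuracy)
  })
  expect_gt(mean(accs), 0.2)
  expect_lt(mean(accs), 0.7)
})

test_that("PPV and NPV follow their confusion-matrix definitions", {
  ## TP=3 FP=1 TN=4 FN=2
  pred <- c(rep(TRUE, 4), rep(FALSE, 6))
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  r <- ppv_npv(pred, truth)
  expect_equal(r$ppv, 0.75)
  expect_equal(r$npv, 2 / 3)
  all_right <- ppv_npv(truth, truth)
  expect_equal(all_right$ppv, 1)
  expect_equal(all_right$npv, 1)
  none_pos <- ppv_npv(rep(FALSE, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_true(is.na(none_pos$ppv))
})

test_that("held-out predictions are calibrated at large n", {
  set.seed(50)
  n <- 500
  x_tr <- cbind(mk = rnorm(n)); rownames(x_tr) <- sprintf("A%03d", 1:n)
  y_tr <- rbinom(n, 1, plogis(0.3 + 1.2 * x_tr[, 1]))
  x_te <- cbind(mk = rnorm(n)); rownames(x_te) <- sprintf("B%03d", 1:n)
  y_te <- rbinom(n, 1, plogis(0.3 + 1.2 * x_te[, 1]))
  model <- train_prediction_model(x_tr, y_tr)
  p <- predict_prob(model, x_te)$probability
  slope <- coef(glm(y_te ~ qlogis(p), family = binomial()))[2]
  expect_lt(abs(slope - 1), 0.3)
})

test_that("model JSON round-trips through disk", {
  set.seed(3)
  vals <- cbind(m1 = rnorm(30, 40, 8), m2 = rnorm(30, 60, 8))
  rownames(vals) <- sprintf("S%02d", 1:30)
  y <- rep(0:1, 15)
  model <- train_prediction_model(vals, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(model, path)
  back <- read_model_json(path)
  expect_equal(back$coefficients, model$coefficients, tolerance = 1e-12)
  expect_equal(back$ref_means, model$ref_means, tolerance = 1e-12)
  p1 <- predict_prob(model, vals)$probability
  p2 <- predict_prob(back, vals)$probability
  expect_equal(p1, p2, tolerance = 1e-12)
})
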
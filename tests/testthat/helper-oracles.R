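# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks.

# BH step-up via its threshold characterization:
# q_i = min over observed thresholds t >= p_i of t * m / #{p <= t}, capped
brute_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, min(ts * m / vapply(ts, function(t) sum(p <= t), numeric(1))))
  }, numeric(1))
}

# exact two-sided rank-sum p by full enumeration of group assignments
# (tie-free data only)
enum_ranksum_p <- function(x, y) {
  nx <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  obs <- sum(r[seq_len(nx)])
  sets <- utils::combn(length(all_v), nx)
  ws <- apply(sets, 2, function(idx) sum(r[idx]))
  p_le <- mean(ws <= obs)
  p_ge <- mean(ws >= obs)
  min(1, 2 * min(p_le, p_ge))
}

# unpenalized Newton-Raphson logistic regression from a zero start
nr_logistic <- function(X, y, max_iter = 200, tol = 1e-12) {
  X1 <- cbind(1, X)
  b <- rep(0, ncol(X1))
  for (i in seq_len(max_iter)) {
    mu <- stats::plogis(drop(X1 %*% b))
    W <- mu * (1 - mu)
    step <- solve(crossprod(X1, X1 * W), crossprod(X1, y - mu))
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  unname(b)
}

# Pearson chi-squared by the definitional formula
chisq_formula <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(chi2 = stat, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# ICC(A,1) via aov()-derived mean squares (independent ANOVA machinery)
aov_icc_a1 <- function(x, y) {
  n <- length(x)
  d <- data.frame(value = c(x, y),
                  subject = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(value ~ subject + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

# small, fast cohort used by several integration tests
tiny_cohort <- function(seed = 42, ...) {
  generate_cohort(sim_config(
    n_brca1 = 12, n_brcax = 12, n_test = 8, n_probes = 300,
    n_mut_probes = 10, n_er_probes = 40, n_grade_probes = 4,
    mut_effect_range = c(0.15, 0.30), er_mut_log_odds = 0.5,
    seed = seed, ...))
}
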
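#' Configuration for a synthetic tumor-methylation cohort
#'
#' Builds the parameter set that drives [generate_cohort()] and its companion
#' generators. Defaults emulate the study conditions the pipeline was designed
#' around: a 20/20/20 cohort of BRCA1-pathogenic, BRCAx (BRCA1-wild-type) and
#' test-variant tumors; a small set of mutation-associated probes with
#' absolute methylation differences between 5% and 30%; a much larger set of
#' ER-associated probes (estrogen-receptor status is the dominant driver of
#' breast-tumor methylation); very few grade-associated probes; strong
#' confounding between ER status and mutation status; per-assay
#' pyrosequencing dropout between 30% and 75%; and one locus whose targeted
#' CpG carries a CG>TG SNP at minor allele frequency 0.2, with the T allele
#' overrepresented in the BRCAx group.
#'
#' @param n_brca1,n_brcax,n_test Samples per group (all must be > 0).
#' @param n_probes Total number of array probes simulated.
#' @param n_mut_probes Probes with a planted mutation-status effect. The
#'   first of these is the SNP-confounded locus.
#' @param n_er_probes Probes with a planted ER-status effect.
#' @param n_grade_probes Probes with a planted grade effect.
#' @param n_overlap_probes Probes carrying both a mutation and an ER effect
#'   (declared overlap between the two sets).
#' @param mut_effect_range Length-2 vector: range of absolute methylation
#'   difference (delta beta) planted at mutation probes. The lower bound
#'   defaults to 0.05, the downstream effect-size filter floor.
#' @param er_effect_range,grade_effect_range Effect ranges for ER and grade
#'   probes, on the same absolute beta scale.
#' @param er_mut_log_odds Log-odds increase in the probability of being
#'   ER-negative for tumors of truly pathogenic genotype; this single number
#'   controls the strength of the ER-mutation confounding.
#' @param er_neg_baseline Probability of ER-negative status for
#'   non-pathogenic tumors.
#' @param prop_high_grade Probability that a tumor is grade 3 (high grade;
#'   grades 1-2 are pooled as low grade).
#' @param pyro_dropout_range Length-2 vector: per-assay fraction of samples
#'   failing pyrosequencing QC, drawn uniformly per locus.
#' @param pyro_noise_sd Gaussian noise (percentage points) added to
#'   pyrosequencing percent-methylation values.
#' @param snp_maf Minor (T) allele frequency of the CG>TG SNP at the
#'   confounded locus in the BRCAx / non-pathogenic samples.
#' @param snp_maf_pathogenic T-allele frequency among truly pathogenic
#'   samples; setting it below `snp_maf` overrepresents the T allele in the
#'   BRCAx group, reproducing the genotype-group association that forces the
#'   locus's exclusion.
#' @param noise_concentration Concentration (precision) of the beta
#'   distribution used for measurement noise around each probe's mean; the
#'   per-probe standard deviation is approximately
#'   `sqrt(m * (1 - m) / (noise_concentration + 1))`.
#' @param missing_er,missing_grade Number of samples whose ER status or grade
#'   is withheld from the sample sheet (the latent value still drives the
#'   simulated methylation).
#' @param seed Integer seed; all generators are bit-reproducible given the
#'   configuration.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()], [generate_pyro_panel()],
#'   [generate_detection_pvalues()]
#' @export
sim_config <- function(n_brca1 = 20, n_brcax = 20, n_test = 20,
                       n_probes = 2000,
                       n_mut_probes = 20, n_er_probes = 300,
                       n_grade_probes = 8, n_overlap_probes = 0,
                       mut_effect_range = c(0.05, 0.30),
                       er_effect_range = c(0.05, 0.30),
                       grade_effect_range = c(0.05, 0.15),
                       er_mut_log_odds = 2, er_neg_baseline = 0.3,
                       prop_high_grade = 0.4,
                       pyro_dropout_range = c(0.30, 0.75),
                       pyro_noise_sd = 3,
                       snp_maf = 0.2, snp_maf_pathogenic = 0.05,
                       noise_concentration = 50,
                       missing_er = 2, missing_grade = 2,
                       seed = 1L) {
  cfg <- list(
    n_brca1 = as.integer(n_brca1), n_brcax = as.integer(n_brcax),
    n_test = as.integer(n_test), n_probes = as.integer(n_probes),
    n_mut_probes = as.integer(n_mut_probes),
    n_er_probes = as.integer(n_er_probes),
    n_grade_probes = as.integer(n_grade_probes),
    n_overlap_probes = as.integer(n_overlap_probes),
    mut_effect_range = as.numeric(mut_effect_range),
    er_effect_range = as.numeric(er_effect_range),
    grade_effect_range = as.numeric(grade_effect_range),
    er_mut_log_odds = as.numeric(er_mut_log_odds),
    er_neg_baseline = as.numeric(er_neg_baseline),
    prop_high_grade = as.numeric(prop_high_grade),
    pyro_dropout_range = as.numeric(pyro_dropout_range),
    pyro_noise_sd = as.numeric(pyro_noise_sd),
    snp_maf = as.numeric(snp_maf),
    snp_maf_pathogenic = as.numeric(snp_maf_pathogenic),
    noise_concentration = as.numeric(noise_concentration),
    missing_er = as.integer(missing_er),
    missing_grade = as.integer(missing_grade),
    seed = as.integer(seed)
  )
  if (any(c(cfg$n_brca1, cfg$n_brcax, cfg$n_test) <= 0L))
    stop("degenerate cohort: every group must contain at least one sample")
  if (cfg$n_probes <= 0L) stop("n_probes must be positive")
  n_special <- cfg$n_mut_probes + cfg$n_er_probes + cfg$n_grade_probes +
    cfg$n_overlap_probes
  if (n_special > cfg$n_probes)
    stop("planted probe counts exceed n_probes")
  for (nm in c("mut_effect_range", "er_effect_range", "grade_effect_range",
               "pyro_dropout_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || any(r < 0) || any(r > 1) || r[1] > r[2])
      stop(sprintf("%s must be an increasing pair of fractions in [0,1]", nm))
  }
  for (nm in c("er_neg_baseline", "prop_high_grade", "snp_maf",
               "snp_maf_pathogenic")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop(sprintf("%s must lie in [0,1]", nm))
  }
  if (cfg$noise_concentration <= 0)
    stop("noise_concentration must be positive")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic methylation cohort configuration\n")
  cat(sprintf("  samples: %d BRCA1 / %d BRCAx / %d test-variant\n",
              x$n_brca1, x$n_brcax, x$n_test))
  cat(sprintf("  probes: %d total; planted %d mutation (+%d overlap), %d ER, %d grade\n",
              x$n_probes, x$n_mut_probes, x$n_overlap_probes, x$n_er_probes,
              x$n_grade_probes))
  cat(sprintf("  |delta beta| mutation effects: %.2f-%.2f; ER-mutation log-odds %.2f\n",
              x$mut_effect_range[1], x$mut_effect_range[2],
              x$er_mut_log_odds))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# beta draw around mean m with concentration nu, vectorized over m
rbeta_mean <- function(m, nu) {
  m <- pmin(pmax(m, 0.02), 0.98)
  stats::rbeta(length(m), m * nu, (1 - m) * nu)
}

#' Generate a synthetic cohort of tumor methylation profiles
#'
#' Simulates a beta-value matrix (probes x samples), a sample sheet, and the
#' ground truth used by the test suite. Methylation values are drawn from
#' beta distributions whose means are shifted additively by planted
#' mutation, ER and grade effects and then constrained to (0, 1). ER status
#' is sampled with elevated log-odds of ER-negativity in pathogenic tumors,
#' so ER and mutation status are confounded at the label level; ER probes
#' respond to ER status only. One mutation probe is SNP-confounded: samples
#' carrying the T allele at the targeted CpG lose signal in proportion to
#' allele dosage, and the T allele is more frequent in non-pathogenic
#' samples.
#'
#' A subset of test variants is represented by two tumors (mostly from
#' different individuals, one variant by two tumors of the same individual)
#' so that downstream likelihood-ratio combination over independent tumors
#' is exercised.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `meth_cohort` with elements
#'   \describe{
#'     \item{beta}{numeric matrix, probes x samples, values in (0, 1).}
#'     \item{samples}{data.frame: `sample_id`, `group` (BRCA1 / BRCAx /
#'       test), `variant_id`, `individual_id`, `er_status`
#'       (positive/negative/NA), `grade` (1-3, NA allowed).}
#'     \item{truth}{list: per-probe baseline means, planted probe-id sets,
#'       per-sample true pathogenicity, planted effect sizes, SNP genotypes
#'       and the SNP-confounded probe id.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)

  n <- config$n_brca1 + config$n_brcax + config$n_test
  sample_id <- sprintf("S%03d", seq_len(n))
  group <- rep(c("BRCA1", "BRCAx", "test"),
               c(config$n_brca1, config$n_brcax, config$n_test))

  ## true pathogenicity: known for BRCA1/BRCAx; ~half of test variants
  pathogenic <- as.integer(group == "BRCA1")
  idx_test <- which(group == "test")
  path_test <- stats::rbinom(length(idx_test), 1L, 0.5)
  if (length(idx_test) >= 2L) {           # guarantee both classes appear
    if (sum(path_test) == 0L) path_test[1L] <- 1L
    if (sum(path_test) == length(path_test)) path_test[1L] <- 0L
  }
  pathogenic[idx_test] <- path_test

  ## variants and individuals: known-status tumors are one per individual;
  ## among test samples, pair up some variants (2 tumors each) - all pairs
  ## from different individuals except the first, which shares an individual
  variant_id <- ifelse(group == "BRCA1", "pathogenic_control",
                       ifelse(group == "BRCAx", "wildtype_control", NA))
  individual_id <- sprintf("I%03d", seq_len(n))
  if (length(idx_test) > 0L) {
    n_pairs <- min(length(idx_test) %/% 4L, 3L)
    v <- 0L
    i <- 1L
    while (i <= length(idx_test)) {
      v <- v + 1L
      if (n_pairs > 0L && i + 1L <= length(idx_test)) {
        vid <- sprintf("VUS%02d", v)
        variant_id[idx_test[c(i, i + 1L)]] <- vid
        pathogenic[idx_test[i + 1L]] <- pathogenic[idx_test[i]]  # same allele
        if (n_pairs == 1L)  # one variant with two tumors, same individual
          individual_id[idx_test[i + 1L]] <- individual_id[idx_test[i]]
        n_pairs <- n_pairs - 1L
        i <- i + 2L
      } else {
        variant_id[idx_test[i]] <- sprintf("VUS%02d", v)
        i <- i + 1L
      }
    }
  }

  ## ER status (latent drives methylation; sheet may censor some entries)
  p_erneg <- stats::plogis(stats::qlogis(config$er_neg_baseline) +
                             config$er_mut_log_odds * pathogenic)
  er_negative <- stats::rbinom(n, 1L, p_erneg)
  high_grade <- stats::rbinom(n, 1L, config$prop_high_grade)
  grade <- ifelse(high_grade == 1L, 3L, sample(1:2, n, replace = TRUE))

  ## probe roles
  probe_id <- sprintf("cg%07d", seq_len(config$n_probes))
  idx <- 0L
  take <- function(k) {
    out <- probe_id[idx + seq_len(k)]
    idx <<- idx + k
    out
  }
  mut_ids <- take(config$n_mut_probes)
  er_ids <- take(config$n_er_probes)
  grade_ids <- take(config$n_grade_probes)
  overlap_ids <- take(config$n_overlap_probes)
  snp_probe <- if (config$n_mut_probes > 0L) mut_ids[1L] else NA_character_

  base_mean <- 0.05 + 0.9 * stats::rbeta(config$n_probes, 0.8, 0.8)
  names(base_mean) <- probe_id

  draw_effect <- function(ids, range) {
    if (length(ids) == 0L) return(numeric(0))
    e <- stats::runif(length(ids), range[1], range[2]) *
      sample(c(-1, 1), length(ids), replace = TRUE)
    names(e) <- ids
    e
  }
  mut_delta <- draw_effect(c(mut_ids, overlap_ids), config$mut_effect_range)
  er_delta <- draw_effect(c(er_ids, overlap_ids), config$er_effect_range)
  grade_delta <- draw_effect(grade_ids, config$grade_effect_range)

  mean_mat <- matrix(base_mean, nrow = config$n_probes, ncol = n,
                     dimnames = list(probe_id, sample_id))
  if (length(mut_delta))
    mean_mat[names(mut_delta), ] <- mean_mat[names(mut_delta), ] +
      outer(mut_delta, pathogenic)
  if (length(er_delta))
    mean_mat[names(er_delta), ] <- mean_mat[names(er_delta), ] +
      outer(er_delta, er_negative)
  if (length(grade_delta))
    mean_mat[names(grade_delta), ] <- mean_mat[names(grade_delta), ] +
      outer(grade_delta, high_grade)

  beta <- matrix(rbeta_mean(as.vector(mean_mat), config$noise_concentration),
                 nrow = config$n_probes, ncol = n,
                 dimnames = list(probe_id, sample_id))

  ## SNP-confounded locus: T allele removes the CpG; measured signal scales
  ## with C-allele dosage, T more frequent in non-pathogenic samples
  snp_genotypes <- rep(NA_character_, n)
  if (!is.na(snp_probe)) {
    q_t <- ifelse(pathogenic == 1L, config$snp_maf_pathogenic, config$snp_maf)
    n_t <- stats::rbinom(n, 2L, q_t)
    snp_genotypes <- c("CC", "CT", "TT")[n_t + 1L]
    beta[snp_probe, ] <- beta[snp_probe, ] * (2L - n_t) / 2
  }

  er_status <- ifelse(er_negative == 1L, "negative", "positive")
  if (config$missing_er > 0L)
    er_status[sample(n, min(config$missing_er, n))] <- NA
  if (config$missing_grade > 0L)
    grade[sample(n, min(config$missing_grade, n))] <- NA

  samples <- data.frame(
    sample_id = sample_id, group = group, variant_id = variant_id,
    individual_id = individual_id, er_status = er_status,
    grade = as.integer(grade), stringsAsFactors = FALSE
  )
  truth <- list(
    base_mean = base_mean,
    mut_probe_ids = c(mut_ids, overlap_ids),
    er_probe_ids = c(er_ids, overlap_ids),
    grade_probe_ids = grade_ids,
    overlap_probe_ids = overlap_ids,
    pathogenic = stats::setNames(pathogenic, sample_id),
    mut_delta = mut_delta, er_delta = er_delta, grade_delta = grade_delta,
    snp_probe_id = snp_probe,
    snp_genotypes = stats::setNames(snp_genotypes, sample_id)
  )
  structure(list(beta = beta, samples = samples, truth = truth),
            class = "meth_cohort")
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic methylation cohort: %d probes x %d samples\n",
              nrow(x$beta), ncol(x$beta)))
  print(table(x$samples$group))
  invisible(x)
}

#' Simulate a pyrosequencing validation panel from array beta values
#'
#' Converts array beta values at selected loci to percent methylation
#' (100 x beta), adds bounded Gaussian measurement noise, and introduces
#' per-locus missingness emulating the high, assay-dependent QC failure
#' rates of FFPE-derived DNA: each locus's dropout fraction is drawn
#' uniformly from `config$pyro_dropout_range` and samples are censored
#' completely at random.
#'
#' @param beta Probes x samples beta matrix.
#' @param loci Character vector of probe ids to assay (must exist in `beta`).
#' @param config A [sim_config()]; uses `pyro_dropout_range` and
#'   `pyro_noise_sd`.
#' @param seed Integer seed (defaults to `config$seed + 1` so that array and
#'   pyro noise are independent but jointly reproducible).
#' @return Numeric matrix loci x samples of percent methylation in
#'   \[0, 100\], with `NA` for failed assays.
#' @export
generate_pyro_panel <- function(beta, loci, config,
                                seed = config$seed + 1L) {
  missing_loci <- setdiff(loci, rownames(beta))
  if (length(missing_loci))
    stop("unknown locus id(s): ", paste(missing_loci, collapse = ", "))
  withr::local_seed(seed)
  pct <- 100 * beta[loci, , drop = FALSE]
  if (config$pyro_noise_sd > 0)
    pct <- pct + stats::rnorm(length(pct), 0, config$pyro_noise_sd)
  pct <- pmin(pmax(pct, 0), 100)
  for (i in seq_along(loci)) {
    rate <- stats::runif(1, config$pyro_dropout_range[1],
                         config$pyro_dropout_range[2])
    drop <- stats::runif(ncol(pct)) < rate
    pct[i, drop] <- NA_real_
  }
  pct
}

#' Simulate a detection p-value matrix
#'
#' Designates a fraction of probes as failing: these receive detection
#' p-values of at least 0.05 in well over 20% of samples, so the probe-QC
#' rule discards them; all remaining calls get p < 0.01.
#'
#' @param beta Probes x samples beta matrix (dimensions and names are
#'   reused).
#' @param fail_probe_fraction Fraction of probes planted as failing.
#' @param seed Integer seed.
#' @return List: `detp` (matrix of detection p-values) and `failing_probes`
#'   (planted ids).
#' @export
generate_detection_pvalues <- function(beta, fail_probe_fraction, seed = 1L) {
  stopifnot(fail_probe_fraction >= 0, fail_probe_fraction <= 1)
  withr::local_seed(seed)
  np <- nrow(beta); ns <- ncol(beta)
  detp <- matrix(stats::runif(np * ns, 0, 0.009), np, ns,
                 dimnames = dimnames(beta))
  n_fail <- round(fail_probe_fraction * np)
  failing <- if (n_fail > 0) sample(rownames(beta), n_fail) else character(0)
  for (p in failing) {
    k <- sample(seq(ceiling(0.2 * ns) + 1L, ns), 1L)
    idx <- sample(ns, k)
    detp[p, idx] <- stats::runif(k, 0.05, 1)
  }
  list(detp = detp, failing_probes = failing)
}

#' Simulate per-variant sequence-bioinformatics evidence
#'
#' Produces the prior-probability ingredients the classification stage
#' consumes: a missense prior per test variant (drawn from the discrete
#' prior values in routine use, higher for truly pathogenic alleles), and
#' for a subset of variants a splice-site context with raw maximum-entropy
#' scores and calibration statistics, so the calibrated splicing prior path
#' is exercised.
#'
#' @param samples Sample sheet from [generate_cohort()].
#' @param truth Truth list from [generate_cohort()].
#' @param seed Integer seed.
#' @return List with `evidence` (data.frame: `variant_id`, `missense_prior`,
#'   `override_prior`) and `splice` (data.frame of splice contexts:
#'   `variant_id`, `site_type`, `raw_mes_wt`, `raw_mes_variant`,
#'   `calibration_mean`, `calibration_sd`).
#' @export
generate_variant_evidence <- function(samples, truth, seed = 1L) {
  withr::local_seed(seed)
  test <- samples[samples$group == "test", , drop = FALSE]
  variants <- unique(test$variant_id)
  path <- vapply(variants, function(v) {
    truth$pathogenic[[test$sample_id[test$variant_id == v][1L]]]
  }, numeric(1))
  missense <- ifelse(path == 1,
                     sample(c(0.34, 0.66, 0.81), length(variants), TRUE),
                     sample(c(0.02, 0.02, 0.03), length(variants), TRUE))
  ev <- data.frame(variant_id = variants, missense_prior = missense,
                   override_prior = NA_real_, stringsAsFactors = FALSE)
  ## give the first two variants a donor splice context; pathogenic alleles
  ## lose score (z << 0), benign ones keep it
  n_splice <- min(2L, length(variants))
  spl <- NULL
  if (n_splice > 0L) {
    vs <- variants[seq_len(n_splice)]
    cal_mean <- 8.1; cal_sd <- 1.6
    wt <- stats::rnorm(n_splice, cal_mean, 0.5)
    varscore <- ifelse(path[seq_len(n_splice)] == 1,
                       cal_mean - stats::runif(n_splice, 2.5, 5) * cal_sd,
                       wt - stats::runif(n_splice, 0, 0.2))
    spl <- data.frame(variant_id = vs, site_type = "donor",
                      raw_mes_wt = wt, raw_mes_variant = varscore,
                      calibration_mean = cal_mean, calibration_sd = cal_sd,
                      stringsAsFactors = FALSE)
  }
  list(evidence = ev, splice = spl)
}
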
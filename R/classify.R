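#' Convert a probability of pathogenicity to a likelihood ratio
#'
#' @param p Probability strictly inside (0, 1).
#' @return `p / (1 - p)`.
#' @seealso [lr_to_prob()]
#' @export
prob_to_lr <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("probability must lie strictly in (0, 1)")
  p / (1 - p)
}

#' Convert a likelihood ratio back to a probability
#'
#' @param lr Positive likelihood ratio.
#' @return `lr / (1 + lr)`.
#' @export
lr_to_prob <- function(lr) {
  if (any(!is.finite(lr)) || any(lr <= 0)) stop("likelihood ratio must be positive")
  lr / (1 + lr)
}

#' Combine per-tumor likelihood ratios across individuals
#'
#' Only tumors from different individuals are independent: the combined LR
#' is the product over individuals of one contribution per individual.
#' When an individual contributed several tumors, their LRs are reduced to
#' a single contribution by the configured reducer (default: geometric
#' mean). The range of combined LRs attainable by instead picking a single
#' tumor per individual is also reported.
#'
#' @param lrs Positive likelihood ratios, one per tumor.
#' @param individuals Individual id per tumor (default: all distinct, i.e.
#'   all tumors independent).
#' @param reducer Within-individual reducer: `"geometric_mean"` (default),
#'   `"min"`, or `"max"`.
#' @return List: `combined_lr`, `lr_range` (c(min, max) over single-tumor
#'   choices), `n_tumors`, `n_independent`.
#' @export
combine_lrs <- function(lrs, individuals = NULL,
                        reducer = c("geometric_mean", "min", "max")) {
  reducer <- match.arg(reducer)
  if (length(lrs) == 0L) stop("no likelihood ratios supplied")
  if (any(!is.finite(lrs)) || any(lrs <= 0))
    stop("likelihood ratios must be positive")
  if (is.null(individuals)) individuals <- as.character(seq_along(lrs))
  stopifnot(length(individuals) == length(lrs))
  red <- switch(reducer,
                geometric_mean = function(v) exp(mean(log(v))),
                min = min, max = max)
  per_ind <- tapply(lrs, individuals, red)
  lo <- tapply(lrs, individuals, min)
  hi <- tapply(lrs, individuals, max)
  list(combined_lr = unname(prod(per_ind)),
       lr_range = c(min = unname(prod(lo)), max = unname(prod(hi))),
       n_tumors = length(lrs),
       n_independent = length(per_ind))
}

#' Calibrated splice-site score z
#'
#' Standardizes a raw maximum-entropy splice-site score against the
#' calibration distribution of wild-type splice junctions.
#'
#' @param raw Raw score.
#' @param calibration_mean,calibration_sd Mean and standard deviation of
#'   wild-type junction scores; sd must be positive.
#' @return `(raw - calibration_mean) / calibration_sd`.
#' @export
mes_zscore <- function(raw, calibration_mean, calibration_sd) {
  if (!is.finite(calibration_sd) || calibration_sd <= 0)
    stop("calibration_sd must be positive")
  (raw - calibration_mean) / calibration_sd
}

#' Splicing prior probability from a calibrated splice context
#'
#' Applies the calibrated splice-score bands: for native donor/acceptor
#' sites the prior applies only when the variant reduces the raw score
#' (a damaged site), and for de novo donors only when it increases it.
#' Donors: z below -2 gives 0.97, z in \[-2, 0) gives 0.34. Acceptors:
#' z below -1.5 gives 0.97, z in \[-1.5, 0.5) gives 0.34. De novo donors:
#' z above 0 gives 0.64, z in \[-2, 0\] gives 0.30. Outside these bands (or
#' with the wrong direction of score change) no splicing prior applies and
#' `NA` is returned.
#'
#' @param site_type `"donor"`, `"acceptor"` or `"de_novo_donor"`.
#' @param raw_mes_wt,raw_mes_variant Raw scores of the wild-type and
#'   variant sequence contexts.
#' @param calibration_mean,calibration_sd Wild-type junction calibration
#'   statistics.
#' @return Prior probability, or `NA` when no splicing prior applies.
#' @export
splicing_prior <- function(site_type, raw_mes_wt, raw_mes_variant,
                           calibration_mean, calibration_sd) {
  z <- mes_zscore(raw_mes_variant, calibration_mean, calibration_sd)
  switch(site_type,
    donor = {
      if (raw_mes_variant >= raw_mes_wt) return(NA_real_)
      if (z < -2) 0.97 else if (z < 0) 0.34 else NA_real_
    },
    acceptor = {
      if (raw_mes_variant >= raw_mes_wt) return(NA_real_)
      if (z < -1.5) 0.97 else if (z < 0.5) 0.34 else NA_real_
    },
    de_novo_donor = {
      if (raw_mes_variant <= raw_mes_wt) return(NA_real_)
      if (z > 0) 0.64 else if (z >= -2) 0.30 else NA_real_
    },
    stop("unknown site_type: ", site_type)
  )
}

#' Combined bioinformatic prior for a variant
#'
#' An explicit override takes precedence; otherwise the higher of the
#' missense prior and any splicing prior wins.
#'
#' @param missense_prior Missense (conservation-based) prior, or `NA`.
#' @param splicing_priors Numeric vector of splicing priors (possibly with
#'   `NA`s), or `NULL`.
#' @param override_prior Externally supplied prior taking precedence, or
#'   `NA`.
#' @return A single prior probability.
#' @export
combined_prior <- function(missense_prior = NA_real_,
                           splicing_priors = NULL,
                           override_prior = NA_real_) {
  if (!is.na(override_prior)) return(override_prior)
  pool <- c(missense_prior, splicing_priors)
  pool <- pool[!is.na(pool)]
  if (length(pool) == 0L)
    stop("no prior source present for this variant")
  max(pool)
}

#' Posterior probability of pathogenicity
#'
#' Posterior odds are the prior odds multiplied by the combined likelihood
#' ratio; the posterior probability is odds / (odds + 1).
#'
#' @param prior Prior probability strictly in (0, 1).
#' @param lr Positive combined likelihood ratio.
#' @return Posterior probability in (0, 1).
#' @export
posterior_probability <- function(prior, lr) {
  if (any(!is.finite(prior)) || any(prior <= 0) || any(prior >= 1))
    stop("prior must lie strictly in (0, 1)")
  if (any(!is.finite(lr)) || any(lr <= 0))
    stop("likelihood ratio must be positive")
  odds <- prior / (1 - prior) * lr
  odds / (odds + 1)
}

#' Five-tier IARC class from a posterior probability
#'
#' Class 1 (not pathogenic): posterior below 0.001; Class 2: 0.001 up to
#' but excluding 0.05; Class 3 (uncertain): 0.05 up to but excluding 0.95;
#' Class 4 (likely pathogenic): 0.95 up to and including 0.99; Class 5
#' (pathogenic): strictly above 0.99.
#'
#' @param posterior Posterior probability in (0, 1) (vectorized).
#' @return Integer class 1-5.
#' @export
iarc_class <- function(posterior) {
  if (any(!is.finite(posterior)) || any(posterior <= 0) || any(posterior >= 1))
    stop("posterior must lie strictly in (0, 1)")
  ifelse(posterior < 0.001, 1L,
  ifelse(posterior < 0.05, 2L,
  ifelse(posterior < 0.95, 3L,
  ifelse(posterior <= 0.99, 4L, 5L))))
}

#' Likelihood-ratio guard on class assignments
#'
#' Classification guidelines require the combined LR to clear evidence
#' thresholds before a variant may leave the uncertain class: below 0.5 to
#' reach Class 1 or 2, above 2.0 to reach Class 4 or 5. Proposed classes
#' failing the guard are demoted to Class 3. Disabled, the proposed class
#' passes through.
#'
#' @param proposed_class Integer class 1-5 (vectorized).
#' @param combined_lr Positive combined likelihood ratio (vectorized).
#' @param enabled Apply the guard (default TRUE).
#' @return Integer final class.
#' @export
enigma_guard <- function(proposed_class, combined_lr, enabled = TRUE) {
  stopifnot(all(proposed_class %in% 1:5))
  if (!enabled) return(as.integer(proposed_class))
  demote <- (proposed_class %in% c(1L, 2L) & combined_lr >= 0.5) |
            (proposed_class %in% c(4L, 5L) & combined_lr <= 2.0)
  ifelse(demote, 3L, as.integer(proposed_class))
}

#' Classify variants from per-tumor predictions and sequence evidence
#'
#' End of the pipeline: per-tumor probabilities become likelihood ratios,
#' LRs are combined across independent tumors per variant, the
#' bioinformatic prior is assembled (override, else max of missense and
#' splicing priors), and posterior probability plus IARC class are
#' reported, optionally LR-guarded.
#'
#' @param predictions data.frame with `sample_id`, `variant_id`,
#'   `individual_id`, `probability` (one row per test tumor).
#' @param evidence data.frame with `variant_id`, `missense_prior`,
#'   `override_prior` (NAs allowed).
#' @param splice Optional data.frame of splice contexts (`variant_id`,
#'   `site_type`, `raw_mes_wt`, `raw_mes_variant`, `calibration_mean`,
#'   `calibration_sd`).
#' @param guard Apply the LR guard to final classes (default FALSE,
#'   reporting the methylation-only classification).
#' @param extra_lrs Optional data.frame `variant_id`, `lr` of additional
#'   independent likelihood ratios (segregation, pathology, ...)
#'   multiplied into the combined LR.
#' @return data.frame of class `classification_result`: `variant_id`,
#'   `n_tumors`, `n_independent`, `prior`, `combined_lr`, `posterior`,
#'   `posterior_min`, `posterior_max`, `iarc_class`, `guard_applied`.
#' @export
classify_variants <- function(predictions, evidence, splice = NULL,
                              guard = FALSE, extra_lrs = NULL) {
  stopifnot(all(c("sample_id", "variant_id", "individual_id",
                  "probability") %in% names(predictions)))
  rows <- lapply(split(predictions, predictions$variant_id), function(pv) {
    v <- pv$variant_id[1L]
    comb <- combine_lrs(prob_to_lr(pv$probability), pv$individual_id)
    lr <- comb$combined_lr
    lr_rng <- comb$lr_range
    if (!is.null(extra_lrs)) {
      ex <- extra_lrs$lr[extra_lrs$variant_id == v]
      if (length(ex)) {
        lr <- lr * prod(ex)
        lr_rng <- lr_rng * prod(ex)
      }
    }
    ev <- evidence[evidence$variant_id == v, , drop = FALSE]
    if (nrow(ev) == 0L)
      stop("no evidence record for variant ", v)
    sp <- NULL
    if (!is.null(splice)) {
      sv <- splice[splice$variant_id == v, , drop = FALSE]
      if (nrow(sv))
        sp <- mapply(splicing_prior, sv$site_type, sv$raw_mes_wt,
                     sv$raw_mes_variant, sv$calibration_mean,
                     sv$calibration_sd)
    }
    prior <- combined_prior(ev$missense_prior[1L], sp, ev$override_prior[1L])
    post <- posterior_probability(prior, lr)
    cls <- enigma_guard(iarc_class(post), lr, enabled = guard)
    data.frame(
      variant_id = v, n_tumors = comb$n_tumors,
      n_independent = comb$n_independent, prior = prior, combined_lr = lr,
      posterior = post,
      posterior_min = posterior_probability(prior, lr_rng[["min"]]),
      posterior_max = posterior_probability(prior, lr_rng[["max"]]),
      iarc_class = cls, guard_applied = guard,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("classification_result", class(out))
  out
}
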
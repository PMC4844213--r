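#' Default pipeline configuration
#'
#' Assembles the full set of tunables for [run_pipeline()]: the synthetic
#' cohort parameters, every analysis threshold, stage toggles, output
#' directory and global seed. A YAML file with any subset of these fields
#' may be passed to [run_pipeline()] instead.
#'
#' @param outdir Output directory for artifacts.
#' @param seed Global seed (drives cohort, dropout, resampling).
#' @param sim Optional [sim_config()] (default: `sim_config(seed = seed)`).
#' @return A list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(outdir = tempfile("methclass_run_"),
                                    seed = 1L, sim = NULL) {
  structure(list(
    outdir = outdir,
    seed = as.integer(seed),
    sim = if (is.null(sim)) sim_config(seed = seed) else sim,
    stages = list(simulate = TRUE, qc = TRUE, select = TRUE,
                  cluster = TRUE, validate = TRUE, fit = TRUE,
                  classify = TRUE),
    fail_probe_fraction = 0.007,
    q_cut = 0.05,
    min_abs_delta = 0.05,
    k = 2L,
    n_resamples = 100L,
    subsample_fraction = 0.8,
    n_markers = 4L,
    min_complete_per_class = 5L,
    guard = FALSE
  ), class = "pipeline_config")
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    raw <- yaml::read_yaml(config)
    cfg <- default_pipeline_config(
      outdir = raw$outdir %||% tempfile("methclass_run_"),
      seed = raw$seed %||% 1L,
      sim = if (is.null(raw$sim)) NULL else
        do.call(sim_config, raw$sim))
    for (nm in setdiff(names(raw), c("outdir", "seed", "sim", "stages")))
      cfg[[nm]] <- raw[[nm]]
    if (!is.null(raw$stages))
      cfg$stages[names(raw$stages)] <- raw$stages
    return(cfg)
  }
  stopifnot(inherits(config, "pipeline_config"))
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate, QC, probe selection, consensus clustering, marker
#' validation, model fitting/prediction and variant classification,
#' writing every intermediate artifact (TSV/CSV/JSON) plus a manifest with
#' md5 checksums into the configured output directory. Stages can be
#' toggled; disabled downstream stages are simply skipped. The run is
#' deterministic given the configuration.
#'
#' @param config A `pipeline_config` (see [default_pipeline_config()]) or a
#'   path to a YAML file of overrides.
#' @return A run report (list of class `pipeline_report`): per-stage counts
#'   (samples passing QC, probes at each filter, markers in the model,
#'   variants classified), key results and the artifact manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  cfg <- load_pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(cfg$outdir, name)
  report <- list(seed = cfg$seed, outdir = cfg$outdir, counts = list())
  on_stage <- function(s) isTRUE(cfg$stages[[s]])

  if (!on_stage("simulate")) {
    report$counts$stages_run <- 0L
    class(report) <- "pipeline_report"
    return(report)
  }

  ## --- simulate -----------------------------------------------------------
  cohort <- generate_cohort(cfg$sim)
  detsim <- generate_detection_pvalues(cohort$beta,
                                       cfg$fail_probe_fraction,
                                       seed = cfg$seed + 101L)
  write_beta_tsv(cohort$beta, art("beta.tsv"))
  write_beta_tsv(detsim$detp, art("detection_p.tsv"))
  write_sample_sheet(cohort$samples, art("samples.csv"))
  jsonlite::write_json(
    list(mut_probe_ids = cohort$truth$mut_probe_ids,
         er_probe_ids = cohort$truth$er_probe_ids,
         grade_probe_ids = cohort$truth$grade_probe_ids,
         pathogenic = as.list(cohort$truth$pathogenic),
         snp_probe_id = cohort$truth$snp_probe_id,
         snp_genotypes = as.list(cohort$truth$snp_genotypes)),
    art("truth.json"), auto_unbox = TRUE, digits = NA)
  report$counts$n_samples <- ncol(cohort$beta)
  report$counts$n_probes <- nrow(cohort$beta)

  ## --- qc -----------------------------------------------------------------
  beta <- cohort$beta
  if (on_stage("qc")) {
    pq <- probe_qc(detsim$detp)
    beta <- beta[pq$retained_probes, , drop = FALSE]
    jsonlite::write_json(list(retained_probes = pq$retained_probes,
                              dropped_probes = pq$dropped_probes),
                         art("qc.json"), auto_unbox = FALSE)
    report$counts$probes_pass_qc <- length(pq$retained_probes)
    report$counts$probes_dropped_qc <- length(pq$dropped_probes)
  }

  ## --- probe selection ----------------------------------------------------
  panel <- NULL
  if (on_stage("select")) {
    sel <- select_probes(beta, cohort$samples, q_cut = cfg$q_cut,
                         min_abs_delta = cfg$min_abs_delta)
    for (ct in c("mutation", "ER", "grade"))
      utils::write.table(sel[[ct]], art(sprintf("screen_%s.tsv", ct)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    panel <- sel$passing_effect_filter

    ## SNP-confound exclusion at the planted CG>TG locus
    excluded_snp <- character(0)
    snp_id <- cohort$truth$snp_probe_id
    if (!is.na(snp_id) && snp_id %in% panel) {
      known <- cohort$samples$group %in% c("BRCA1", "BRCAx")
      tab <- table(group = cohort$samples$group[known],
                   genotype = cohort$truth$snp_genotypes[known])
      if (ncol(tab) >= 2L) {
        snp_res <- snp_confound_test(unclass(tab))
        if (snp_res$exclude) {
          panel <- setdiff(panel, snp_id)
          excluded_snp <- snp_id
        }
        report$snp_test <- snp_res
      }
    }
    jsonlite::write_json(
      list(significant_by_contrast = sel$significant_by_contrast,
           unique_to_mutation = sel$unique_to_mutation,
           passing_effect_filter = sel$passing_effect_filter,
           excluded_snp_probes = excluded_snp,
           final_panel = panel),
      art("selection.json"), auto_unbox = FALSE)
    report$counts$probes_significant_mutation <-
      length(sel$significant_by_contrast$mutation)
    report$counts$probes_unique_to_mutation <- length(sel$unique_to_mutation)
    report$counts$probes_in_panel <- length(panel)
  }

  ## --- consensus clustering ----------------------------------------------
  if (on_stage("cluster") && !is.null(panel) && length(panel) >= 2L) {
    cons <- consensus_cluster(beta[panel, , drop = FALSE], k = cfg$k,
                              n_resamples = cfg$n_resamples,
                              subsample_fraction = cfg$subsample_fraction,
                              seed = cfg$seed + 202L)
    calls <- call_test_samples(cons, cohort$samples)
    utils::write.table(
      data.frame(sample_id = rownames(cons$consensus_matrix),
                 cons$consensus_matrix, check.names = FALSE),
      art("consensus_matrix.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.csv(
      data.frame(sample_id = names(cons$assignments),
                 cluster = unname(cons$assignments)),
      art("assignments.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(calls$test_calls, art("test_calls.csv"),
                     row.names = FALSE, quote = FALSE)
    report$cluster_identity <- calls$cluster_identity
    report$counts$test_samples_called <- sum(!is.na(calls$test_calls$call))
  }

  ## --- pyro panel + validation -------------------------------------------
  pyro <- NULL
  markers <- if (!is.null(panel)) utils::head(panel, cfg$n_markers)
             else character(0)
  if (length(markers) >= 2L) {
    pyro <- generate_pyro_panel(cohort$beta, markers, cfg$sim,
                                seed = cfg$seed + 303L)
    write_pyro_csv(pyro, art("pyrosequencing.csv"))
  }
  if (on_stage("validate") && !is.null(pyro)) {
    mut_lab <- factor(ifelse(cohort$samples$group == "BRCA1", "BRCA1",
                             ifelse(cohort$samples$group == "BRCAx",
                                    "BRCAx", NA)),
                      levels = c("BRCA1", "BRCAx"))
    vw <- suppressWarnings(validation_wilcoxon(pyro, mut_lab))
    icc <- vapply(markers, function(loc)
      tryCatch(icc_array_vs_pyro(cohort$beta[loc, ], pyro[loc, ]),
               error = function(e) NA_real_), numeric(1))
    vw$icc <- icc[vw$locus_id]
    utils::write.table(vw, art("validation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    r2 <- pairwise_r2(pyro)
    utils::write.table(
      data.frame(locus_id = rownames(r2), r2, check.names = FALSE),
      art("pairwise_r2.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    report$validation <- vw
  }

  ## --- model fit / predict ------------------------------------------------
  predictions <- NULL
  if (on_stage("fit") && length(markers) >= 2L) {
    known <- cohort$samples$group %in% c("BRCA1", "BRCAx")
    vals <- t(cohort$beta[markers, , drop = FALSE])
    y <- as.numeric(cohort$samples$group == "BRCA1")
    model <- train_prediction_model(vals[known, , drop = FALSE], y[known],
                                    min_complete_per_class =
                                      cfg$min_complete_per_class)
    write_model_json(model, art("model.json"))
    cv <- suppressWarnings(
      loocv(vals[known, , drop = FALSE], y[known],
            min_complete_per_class = cfg$min_complete_per_class))
    report$loocv_accuracy <- cv$accuracy
    pred_known <- predict_prob(model, vals[known, , drop = FALSE])
    pn <- ppv_npv(pred_known$predicted, y[known] == 1)
    report$ppv <- pn$ppv
    report$npv <- pn$npv
    test_idx <- cohort$samples$group == "test"
    pred <- predict_prob(model, vals[test_idx, , drop = FALSE])
    pred$variant_id <- cohort$samples$variant_id[
      match(pred$sample_id, cohort$samples$sample_id)]
    pred$individual_id <- cohort$samples$individual_id[
      match(pred$sample_id, cohort$samples$sample_id)]
    utils::write.csv(pred, art("predictions.csv"), row.names = FALSE,
                     quote = FALSE)
    predictions <- pred
    report$counts$markers_in_model <- length(model$marker_ids)
  }

  ## --- classification -----------------------------------------------------
  if (on_stage("classify") && !is.null(predictions) &&
      nrow(predictions) > 0L) {
    evd <- generate_variant_evidence(cohort$samples, cohort$truth,
                                     seed = cfg$seed + 404L)
    utils::write.csv(evd$evidence, art("evidence.csv"), row.names = FALSE,
                     quote = FALSE)
    cls <- classify_variants(predictions, evd$evidence,
                             splice = evd$splice, guard = cfg$guard)
    utils::write.csv(cls, art("classification.csv"), row.names = FALSE,
                     quote = FALSE)
    ## per-sample log-LR table for plotting
    utils::write.csv(
      data.frame(sample_id = predictions$sample_id,
                 variant_id = predictions$variant_id,
                 log_lr = log(prob_to_lr(predictions$probability))),
      art("log_lr.csv"), row.names = FALSE, quote = FALSE)
    report$classification <- cls
    report$counts$variants_classified <- nrow(cls)
  }

  ## --- manifest -----------------------------------------------------------
  files <- list.files(cfg$outdir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       digits = NA)
  report$manifest <- manifest
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("methclass pipeline run (seed", x$seed, ")\n")
  for (nm in names(x$counts))
    cat(sprintf("  %s: %s\n", nm, x$counts[[nm]]))
  if (!is.null(x$loocv_accuracy))
    cat(sprintf("  LOOCV accuracy: %.3f (PPV %.3f, NPV %.3f)\n",
                x$loocv_accuracy, x$ppv, x$npv))
  if (!is.null(x$classification)) {
    cat("  classification:\n")
    print(x$classification[, c("variant_id", "n_tumors", "prior",
                               "combined_lr", "posterior", "iarc_class")])
  }
  invisible(x)
}
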
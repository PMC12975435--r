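#' Pipeline configuration
#'
#' Bundles every stage setting of the end-to-end analysis. Cohort data come
#' either from the synthetic generator (`cohort` spec) or from CSV paths
#' (`features_csv` + `outcomes_csv`). The optional phantom stage exercises
#' the imaging path (segmentation + feature extraction) on a synthetic
#' phantom and records the extracted vector length.
#'
#' @param cohort a [cohort_spec()] (ignored when CSV paths are given).
#' @param features_csv,outcomes_csv optional paths to pre-computed tables.
#' @param reference harmonization reference batch (the development centre).
#' @param alpha Mann-Whitney retention level.
#' @param rho_max Spearman redundancy bound.
#' @param hp [mlp_hyperparams()].
#' @param split_ratio training fraction of the development cohort.
#' @param k CV folds.
#' @param include_phantom run the imaging stage (default TRUE).
#' @param phantom a [phantom_spec()] for the imaging stage.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, features_csv = NULL,
                            outcomes_csv = NULL, reference = "center1",
                            alpha = 0.05, rho_max = 0.7,
                            hp = mlp_hyperparams(), split_ratio = 0.6,
                            k = 10L, include_phantom = TRUE, phantom = NULL,
                            seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(cohort) && is.null(features_csv))
    cohort <- cohort_spec(seed = seed)
  if (include_phantom && is.null(phantom))
    phantom <- phantom_spec(shape = c(40, 40, 40),
                            liver = list(center = c(16, 16, 16), mean = 2.0,
                                         sd = 0.2),
                            lesions = list(list(center = c(32, 32, 32),
                                                radius = 6, amplitude = 8,
                                                texture = "speckled")),
                            seed = seed + 11L)
  structure(list(cohort = cohort, features_csv = features_csv,
                 outcomes_csv = outcomes_csv, reference = reference,
                 alpha = alpha, rho_max = rho_max, hp = hp,
                 split_ratio = split_ratio, k = as.integer(k),
                 include_phantom = include_phantom, phantom = phantom,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate/ingest the two-centre tables; (optionally)
#' the imaging stage on a synthetic phantom (PERCIST segmentation and
#' 856-feature extraction); reference-batch ComBat harmonization; two-step
#' feature selection on the development cohort only; MEL-RAD model building
#' (60/40 split, 10-fold CV, backward elimination, EFF threshold) on the
#' development cohort; frozen-threshold evaluation on the testing cohort;
#' and Kaplan-Meier / log-rank / Cox stratification of PFS and OS in both
#' cohorts. The testing cohort never enters selection, training or
#' threshold choice. Deterministic under the config seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every intermediate table
#'   and a metrics summary are written there.
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  # -- ingest / simulate ------------------------------------------------
  dat <- stage("ingest", {
    if (!is.null(config$features_csv)) {
      list(features = read_feature_table(config$features_csv),
           outcomes = read_outcome_table(config$outcomes_csv))
    } else generate_cohort(config$cohort)
  })
  # -- imaging stage on a phantom --------------------------------------
  imaging <- NULL
  if (isTRUE(config$include_phantom)) {
    imaging <- stage("imaging", {
      ph <- generate_phantom(config$phantom)
      vol <- resample_isotropic(ph$volume, 1)
      ref <- liver_reference(vol, ph$liver_center)
      thr <- percist_threshold(ref)
      seg <- segment_lesions(vol, thr, exclusions = ph$exclusion_masks)
      fv <- extract_features(vol, seg$mask)
      list(liver_mean = ref$mean, liver_sd = ref$sd, threshold = thr,
           n_components = length(seg$component_sizes),
           dice = {
             gt <- resample_mask(ph$lesion_mask, config$phantom$spacing, 1)
             2 * sum(seg$mask & gt) / (sum(seg$mask) + sum(gt))
           },
           n_features = length(fv), features = fv)
    })
  }
  # -- harmonize --------------------------------------------------------
  cm <- stage("harmonize", combat_fit(dat$features, config$reference))
  harmonized <- stage("harmonize", combat_apply(cm, dat$features))
  dev_rows <- harmonized$batch == config$reference
  dev_feat <- harmonized[dev_rows, , drop = FALSE]
  test_feat <- harmonized[!dev_rows, , drop = FALSE]
  dev_out <- dat$outcomes[dev_rows, , drop = FALSE]
  test_out <- dat$outcomes[!dev_rows, , drop = FALSE]
  # -- select (development only) ---------------------------------------
  sel <- stage("select",
               select_features(dev_feat, dev_out$status_1y,
                               alpha = config$alpha, rho_max = config$rho_max))
  stop_if_not(length(sel$step2) >= 1,
              "feature selection retained nothing; no model can be built")
  # -- train / eliminate / threshold (development) ----------------------
  fit <- stage("train",
               melrad_fit(dev_feat[, sel$step2, drop = FALSE],
                          dev_out$status_1y, hp = config$hp,
                          split_ratio = config$split_ratio, k = config$k,
                          seed = config$seed))
  # -- evaluate both cohorts at the frozen threshold --------------------
  dev_prob <- predict(fit, dev_feat[, fit$features, drop = FALSE])
  test_prob <- predict(fit, test_feat[, fit$features, drop = FALSE])
  dev_eval <- stage("evaluate",
                    evaluate(dev_prob, dev_out$status_1y, fit$threshold))
  test_eval <- stage("evaluate",
                     evaluate(test_prob, test_out$status_1y, fit$threshold))
  # -- survival stratification ------------------------------------------
  surv <- stage("survival", {
    strat <- function(out, prob) {
      pos <- as.integer(prob > fit$threshold)
      if (length(unique(pos)) < 2) return(NULL)
      list(pfs = stratified_survival(out$pfs_time, out$pfs_event, pos),
           os = stratified_survival(out$os_time, out$os_event, pos))
    }
    list(development = strat(dev_out, dev_prob),
         testing = strat(test_out, test_prob))
  })
  metrics <- rbind(cbind(cohort = "development", as.data.frame(dev_eval)),
                   cbind(cohort = "testing", as.data.frame(test_eval)))
  report <- structure(list(
    config = config, imaging = imaging, combat = cm,
    selection = sel, fit = fit,
    development = list(outcomes = dev_out, prob = dev_prob,
                       evaluation = dev_eval),
    testing = list(outcomes = test_out, prob = test_prob,
                   evaluation = test_eval),
    survival = surv, metrics = metrics,
    provenance = list(
      selection_inputs = "development cohort only",
      training_inputs = "development cohort only",
      threshold_source = "development validation split",
      testing_usage = "frozen-threshold evaluation and survival only"),
    seeds = list(master = config$seed,
                 cohort = if (!is.null(config$cohort)) config$cohort$seed,
                 phantom = if (!is.null(config$phantom)) config$phantom$seed)),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(report, dat, harmonized, out_dir)
  report
}

write_pipeline_report <- function(report, dat, harmonized, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(dat$features, file.path(out_dir, "features_raw.csv"))
  write_feature_table(harmonized, file.path(out_dir, "features_harmonized.csv"))
  write_outcome_table(dat$outcomes, file.path(out_dir, "outcomes.csv"))
  sel <- report$selection
  utils::write.csv(data.frame(feature = names(sel$p_values),
                              p = unname(sel$p_values),
                              kept_step1 = names(sel$p_values) %in% sel$step1,
                              kept_step2 = names(sel$p_values) %in% sel$step2),
                   file.path(out_dir, "selection.csv"), row.names = FALSE)
  utils::write.csv(report$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    selected_features = report$fit$features,
    threshold = report$fit$threshold,
    validation_auc = report$fit$val_auc,
    cv_auc = report$fit$cv_auc,
    seeds = report$seeds,
    provenance = report$provenance),
    file.path(out_dir, "run_summary.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c(sprintf("melrad pipeline run, seed %d", report$seeds$master),
               sprintf("R version: %s", R.version.string),
               sprintf("selected: %s",
                       paste(report$fit$features, collapse = ", ")),
               sprintf("threshold: %.3f", report$fit$threshold)),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("melrad pipeline report\n")
  if (!is.null(x$imaging))
    cat(sprintf("  imaging: T = %.3f SUV, %d component(s), Dice %.3f, %d features\n",
                x$imaging$threshold, x$imaging$n_components, x$imaging$dice,
                x$imaging$n_features))
  cat(sprintf("  selection: %d -> %d -> %d features\n",
              length(x$selection$p_values), length(x$selection$step1),
              length(x$selection$step2)))
  cat(sprintf("  model: %d feature(s), threshold %.1f%%\n",
              length(x$fit$features), 100 * x$fit$threshold))
  cat("  development: "); print(x$development$evaluation)
  cat("  testing:     "); print(x$testing$evaluation)
  invisible(x)
}
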
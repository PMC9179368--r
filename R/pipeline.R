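#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end workflow: the two acquisition
#' regimes, cohort sizes for the synthetic demo, QC thresholds, the
#' reference grid, the classifier configuration, and the master seed.
#'
#' @param original_params,validation_params Acquisition parameters of the
#'   training and validation regimes.
#' @param n_mut_train,n_wt_train,n_mut_val,n_wt_val Synthetic cohort
#'   sizes. The training default 17/17 reflects a balanced design; the
#'   validation default 23/44 mirrors a realistic mutant prevalence of
#'   about one third.
#' @param sim Base [sim_config()] settings (basis and nuisance model);
#'   its `params` field is replaced per regime.
#' @param thresholds [qc_thresholds()] for the quality gate.
#' @param grid [reference_grid()] the classifier operates on.
#' @param classifier [classifier_config()].
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(original_params = regime_params("3T-original"),
                            validation_params = regime_params("1.5T-validation"),
                            n_mut_train = 17, n_wt_train = 17,
                            n_mut_val = 23, n_wt_val = 44,
                            sim = sim_config(),
                            thresholds = qc_thresholds(),
                            grid = reference_grid(),
                            classifier = classifier_config(),
                            seed = 1) {
  structure(
    list(original_params = original_params,
         validation_params = validation_params,
         n_mut_train = n_mut_train, n_wt_train = n_wt_train,
         n_mut_val = n_mut_val, n_wt_val = n_wt_val,
         sim = sim, thresholds = thresholds, grid = grid,
         classifier = classifier, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# rebuild a sim_config for a given regime, keeping basis/nuisance settings
regime_sim_config <- function(sim, params) {
  sim_config(
    basis = sim$basis, params = params, noise_sd = sim$noise_sd,
    baseline_amplitude = sim$baseline_amplitude,
    baseline_order = sim$baseline_order,
    ppm_jitter_sd = sim$ppm_jitter_sd,
    global_scale_range = sim$global_scale_range,
    fwhm_reference_tesla = sim$fwhm_reference_tesla
  )
}

#' Run the full synthetic workflow
#'
#' Executes the complete pipeline on simulated data: simulate a training
#' cohort under the 3 T regime and a validation cohort under the 1.5 T
#' regime, quality-gate both, harmonize everything onto the reference
#' grid, select the feature count by cross-validation and train the
#' linear SVM on the full training cohort, predict the validation
#' cohort, and compute the diagnostic report and ROC/AUC.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the model, predictions
#'   (TSV), report (JSON) and exclusion ledger are written there.
#' @return A list of class `mrs_pipeline_result`: cohorts, harmonized
#'   matrices, `model`, `predictions`, `report`, `roc`, `ledger`, and the
#'   `config` (seed included) for provenance.
#' @examples
#' \donttest{
#' res <- run_end_to_end(pipeline_config(seed = 7))
#' res$report
#' }
#' @export
run_end_to_end <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("Pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  train_co <- stage("simulate-train", simulate_cohort(
    regime_sim_config(config$sim, config$original_params),
    config$n_mut_train, config$n_wt_train,
    seed = sub_seed(config$seed, 1), prefix = "orig"
  ))
  val_co <- stage("simulate-validation", simulate_cohort(
    regime_sim_config(config$sim, config$validation_params),
    config$n_mut_val, config$n_wt_val,
    seed = sub_seed(config$seed, 2), prefix = "val"
  ))

  train_kept <- stage("qc", apply_exclusions(train_co, config$thresholds))
  val_kept <- stage("qc", apply_exclusions(val_co, config$thresholds))

  h_train <- stage("harmonize", harmonize_cohort(train_kept, config$grid))
  h_val <- stage("harmonize", harmonize_cohort(val_kept, config$grid))

  if (all(h_train$label == "unknown")) {
    stop("Pipeline stage 'train' failed: training cohort has no labels.",
         call. = FALSE)
  }
  model <- stage("train", mrs_train(h_train, config = config$classifier))
  predictions <- stage("predict", stats::predict(model, h_val))

  cm <- stage("evaluate", confusion(h_val$label, predictions$label))
  report <- diagnostic_report(cm)
  roc <- roc_auc(predictions$score, h_val$label)

  result <- structure(
    list(train_cohort = train_kept, validation_cohort = val_kept,
         harmonized_train = h_train, harmonized_validation = h_val,
         model = model, predictions = predictions,
         report = report, roc = roc,
         ledger = list(train = exclusion_ledger(train_kept),
                       validation = exclusion_ledger(val_kept)),
         config = config),
    class = "mrs_pipeline_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_model(model, file.path(out_dir, "model.json"))
    utils::write.table(
      predictions, file.path(out_dir, "predictions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write_report(report, file.path(out_dir, "report.json"), auc = roc$auc)
    ledgers <- dplyr::bind_rows(
      dplyr::mutate(result$ledger$train, cohort = "train"),
      dplyr::mutate(result$ledger$validation, cohort = "validation")
    )
    utils::write.table(ledgers, file.path(out_dir, "exclusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  result
}

#' @export
print.mrs_pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<mrs_pipeline_result> seed %d | train %d spectra, validation %d spectra | k = %d | AUC = %.3f\n",
    x$config$seed, nrow(x$train_cohort), nrow(x$validation_cohort),
    x$model$k, x$roc$auc
  ))
  print(x$report)
  invisible(x)
}

#' One-command synthetic demo
#'
#' Runs [run_end_to_end()] with default settings and prints the resulting
#' report.
#'
#' @param out_dir Optional output directory for artifacts.
#' @param seed Master seed.
#' @return The pipeline result, invisibly.
#' @export
run_demo <- function(out_dir = NULL, seed = 1) {
  res <- run_end_to_end(pipeline_config(seed = seed), out_dir = out_dir)
  print(res)
  invisible(res)
}
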
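# Plain-text persistence: cohort CSVs, pipeline artifacts, config files.
# Missing items are encoded as empty cells.

#' Write a cohort to CSV files
#'
#' Writes `records.csv` (`physician_id`, `wave`, `invited`, `item_1` ...
#' `item_10`; unanswered items empty), `features.csv` (`physician_id`,
#' `wave`, `gender`, `age`, feature columns), and — when ground truth is
#' present — `truth.csv` (`physician_id`, `wave`, `latent_burnout`,
#' `true_propensity`, `responded`) and `truth_summary.csv`
#' (`true_prevalence`). The generator configuration is echoed to
#' `config.json`.
#'
#' @param cohort A `synthetic_cohort` or compatible list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$records, file.path(dir, "records.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$features, file.path(dir, "features.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(cohort$truth)) {
    utils::write.csv(cohort$truth$per_invitation,
                     file.path(dir, "truth.csv"), row.names = FALSE)
    utils::write.csv(data.frame(true_prevalence =
                                  cohort$truth$true_prevalence),
                     file.path(dir, "truth_summary.csv"), row.names = FALSE)
  }
  if (!is.null(cohort$config))
    jsonlite::write_json(unclass(cohort$config),
                         file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort from CSV files
#'
#' Inverse of [write_cohort()]; `truth.csv` is optional (real data has no
#' ground truth).
#'
#' @param dir Directory holding `records.csv` and `features.csv`.
#' @return A list of class `synthetic_cohort` (the `truth` element is NULL
#'   when no truth files are present).
#' @export
read_cohort <- function(dir) {
  records <- utils::read.csv(file.path(dir, "records.csv"),
                             stringsAsFactors = FALSE)
  features <- utils::read.csv(file.path(dir, "features.csv"),
                              stringsAsFactors = FALSE)
  truth <- NULL
  if (file.exists(file.path(dir, "truth.csv"))) {
    per_inv <- utils::read.csv(file.path(dir, "truth.csv"),
                               stringsAsFactors = FALSE)
    per_inv$responded <- as.logical(per_inv$responded)
    tp <- utils::read.csv(file.path(dir, "truth_summary.csv"))
    truth <- list(per_invitation = per_inv,
                  true_prevalence = tp$true_prevalence[1L])
  }
  config <- NULL
  if (file.exists(file.path(dir, "config.json")))
    config <- jsonlite::read_json(file.path(dir, "config.json"),
                                  simplifyVector = TRUE)
  structure(list(records = records, features = features, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

ensemble_to_list <- function(ens) {
  list(
    beta = as.list(ens$beta),
    sigmoid_scale = ens$s,
    burnout_threshold = ens$threshold,
    operating_threshold = ens$operating_threshold,
    feature_schema = ens$schema,
    seed = ens$seed,
    split = ens$split,
    models = lapply(ens$models, function(m) list(
      lambda = m$lambda,
      coefficients = stats::setNames(as.list(m$coefficients[, 1L]),
                                     rownames(m$coefficients)),
      std_coefficients = as.list(m$std_coefficients)
    ))
  )
}

#' Write every pipeline artifact to a directory
#'
#' Emits `scores.csv`, `categories.csv`, `comparisons.csv`,
#' `paired_comparisons.csv`, `propensity.csv` (propensities plus the three
#' weight columns), `model.json` (both ensembles: coefficients, bias
#' correction, sigmoid scale, feature schema, seeds), `evaluation.csv`,
#' `prevalence.csv` and `manifest.json` (configuration echo, package and R
#' versions, seeds).
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name),
                                           row.names = FALSE, na = "")
  w(result$scores, "scores.csv")
  w(result$categories, "categories.csv")
  w(as.data.frame(result$comparisons), "comparisons.csv")
  if (!is.null(result$paired_comparisons))
    w(as.data.frame(result$paired_comparisons), "paired_comparisons.csv")
  pr <- result$propensity$propensities
  pr$w_unweighted <- compute_weights(pr$p, "unweighted")
  pr$w_inverse_p <- compute_weights(pr$p, "inverse_p")
  pr$w_one_minus_p <- compute_weights(pr$p, "one_minus_p")
  w(pr, "propensity.csv")
  w(result$predicted_nonresponders, "predicted_nonresponders.csv")

  jsonlite::write_json(
    list(ensemble = ensemble_to_list(result$ensemble),
         final_ensemble = ensemble_to_list(result$final_ensemble),
         propensity = list(
           lambda = result$propensity$lambda,
           coefficients = stats::setNames(
             as.list(result$propensity$coefficients[, 1L]),
             rownames(result$propensity$coefficients)))),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  ev <- result$test_evaluation
  eval_df <- data.frame(
    metric = c("response_auroc", "response_auroc_lo", "response_auroc_hi",
               "burnout_auroc", "burnout_auroc_lo", "burnout_auroc_hi",
               "burnout_auprc", "burnout_auprc_lo", "burnout_auprc_hi",
               "sensitivity", "specificity", "operating_threshold"),
    value = c(result$response_auroc$auroc, result$response_auroc$ci,
              if (is.null(ev)) rep(NA_real_, 9) else
                c(ev$auroc, ev$auroc_ci, ev$auprc, ev$auprc_ci,
                  ev$sensitivity, ev$specificity, ev$operating_threshold)))
  w(eval_df, "evaluation.csv")

  pv <- result$prevalence
  w(data.frame(
    weighting_level = pv$weighting_level,
    n_responses = pv$n_responses, n_nonresponses = pv$n_nonresponses,
    observed_prevalence = pv$observed_prevalence,
    predicted_prevalence = pv$predicted_prevalence,
    predicted_lo = pv$predicted_ci[1], predicted_hi = pv$predicted_ci[2],
    population_prevalence = pv$population_prevalence,
    population_lo = pv$population_ci[1], population_hi = pv$population_ci[2]
  ), "prevalence.csv")

  jsonlite::write_json(
    list(package = "burnoutprev",
         version = as.character(utils::packageVersion("burnoutprev")),
         r_version = R.version.string,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = unclass(result$config)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
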
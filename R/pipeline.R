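# End-to-end orchestration: scoring -> categorization -> comparisons ->
# propensity -> weighted ensemble -> population prevalence estimate.

#' Pipeline configuration
#'
#' All stage seeds are derived deterministically from the single base seed,
#' so a configuration fully determines the run.
#'
#' @param n_folds Cross-validation folds for the propensity model.
#' @param frac_train Training fraction of the physician-level
#'   train/calibration split.
#' @param n_boot Bootstrap replicates for all confidence intervals.
#' @param weighting_level Prevalence combination level, `"survey"` or
#'   `"physician"`.
#' @param seed Base integer seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_folds = 10L, frac_train = 0.8, n_boot = 500L,
                            weighting_level = c("survey", "physician"),
                            seed = 1L) {
  weighting_level <- match.arg(weighting_level)
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(
    n_folds = check_count(n_folds, "n_folds", min = 2L),
    frac_train = check_number(frac_train, "frac_train", 0, 1,
                              open_lower = TRUE, open_upper = TRUE),
    n_boot = check_count(n_boot, "n_boot"),
    weighting_level = weighting_level,
    seed = seed,
    seed_propensity = seed * 13L + 101L,
    seed_ensemble = seed * 13L + 202L,
    seed_final = seed * 13L + 303L,
    seed_boot = seed * 13L + 404L,
    seed_reduce = seed * 13L + 505L
  ), class = "pipeline_config")
}

# Align the feature table to the (physician_id, wave) order of the records.
align_features <- function(features, records) {
  key_f <- paste(features$physician_id, features$wave)
  key_r <- paste(records$physician_id, records$wave)
  idx <- match(key_r, key_f)
  if (anyNA(idx))
    stop("features are missing rows for some invitations", call. = FALSE)
  features[idx, , drop = FALSE]
}

# Feature rows of partial responders in their response / nonresponse years,
# in matching physician order.
partial_year_tables <- function(features, scores, categories) {
  partial <- categories$physician_id[categories$category == "partial"]
  if (length(partial) == 0L) return(NULL)
  sc <- scores[scores$physician_id %in% partial, ]
  fe <- align_features(features, sc)
  resp <- sc$is_response
  ord_r <- order(sc$physician_id[resp])
  ord_n <- order(sc$physician_id[!resp])
  list(response_year = fe[resp, , drop = FALSE][ord_r, , drop = FALSE],
       nonresponse_year = fe[!resp, , drop = FALSE][ord_n, , drop = FALSE])
}

#' Run the full nonresponse-adjusted prevalence pipeline
#'
#' Executes, in order: survey scoring, responder categorization, descriptive
#' group and paired-year comparisons, grouped cross-validated response
#' propensities, the bias-corrected weighted burnout ensemble (trained on
#' always responders, evaluated on partial responders' response years), a
#' final refit on all responses, prediction of all nonresponses, and the
#' combined population prevalence estimate.
#'
#' @param cohort A `synthetic_cohort` (or any list with `records` and
#'   `features` in the documented schemas, e.g. from [read_cohort()]).
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, all artifacts are
#'   written there as CSV/JSON via [write_pipeline_artifacts()].
#' @return Object of class `pipeline_result` with elements `scores`,
#'   `categories`, `comparisons`, `paired_comparisons`, `propensity`,
#'   `response_auroc`, `ensemble`, `test_evaluation`, `final_ensemble`,
#'   `predicted_nonresponders` (data.frame), `prevalence`, `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         output_dir = NULL) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  records <- cohort$records
  features <- align_features(cohort$features, records)

  scores <- score_surveys(records)
  categories <- categorize_responders(scores)
  comparisons <- compare_groups(features, categories)
  py <- partial_year_tables(features, scores, categories)
  paired <- if (is.null(py)) NULL else {
    meas <- setdiff(names(features), c("physician_id", "wave", "gender"))
    compare_paired_years(py$response_year[meas], py$nonresponse_year[meas])
  }

  propensity <- fit_propensity(features, scores$is_response,
                               n_folds = config$n_folds,
                               seed = config$seed_propensity)
  response_auroc <- evaluate_response_auroc(propensity, scores$is_response,
                                            n_boot = config$n_boot,
                                            seed = config$seed_boot)
  p <- propensity$propensities$p

  cat_of <- stats::setNames(as.character(categories$category),
                            categories$physician_id)
  row_cat <- cat_of[scores$physician_id]
  is_resp <- scores$is_response

  # ensemble trained on always responders only
  always_rows <- row_cat == "always" & is_resp
  ensemble <- train_burnout_ensemble(features[always_rows, , drop = FALSE],
                                     scores$score[always_rows],
                                     p[always_rows],
                                     frac_train = config$frac_train,
                                     seed = config$seed_ensemble)

  # evaluated on partial responders' response years
  test_rows <- row_cat == "partial" & is_resp
  test_evaluation <- NULL
  if (sum(test_rows) >= 2L) {
    prob_test <- score_to_probability(
      predict_ensemble(ensemble, features[test_rows, , drop = FALSE]),
      ensemble)
    actual_test <- scores$burnout[test_rows]
    test_evaluation <- tryCatch(
      evaluate_predictions(prob_test, actual_test,
                           scores$physician_id[test_rows],
                           operating_threshold = ensemble$operating_threshold,
                           n_boot = config$n_boot, seed = config$seed_boot),
      error = function(e) NULL)
  }

  # final refit on all responses, then predict all nonresponses
  final_ensemble <- train_burnout_ensemble(features[is_resp, , drop = FALSE],
                                           scores$score[is_resp],
                                           p[is_resp],
                                           frac_train = config$frac_train,
                                           seed = config$seed_final)
  nr_rows <- !is_resp
  predicted_nonresponders <- data.frame(
    physician_id = scores$physician_id[nr_rows],
    wave = scores$wave[nr_rows],
    predicted_score = numeric(sum(nr_rows)),
    predicted_probability = numeric(sum(nr_rows)))
  if (any(nr_rows)) {
    sc_hat <- predict_ensemble(final_ensemble,
                               features[nr_rows, , drop = FALSE])
    predicted_nonresponders$predicted_score <- sc_hat
    predicted_nonresponders$predicted_probability <-
      score_to_probability(sc_hat, final_ensemble)
  }

  prevalence <- combine_prevalence(
    observed = scores$burnout[is_resp],
    predicted = predicted_nonresponders$predicted_probability,
    observed_ids = scores$physician_id[is_resp],
    predicted_ids = predicted_nonresponders$physician_id,
    weighting_level = config$weighting_level,
    n_boot = config$n_boot, seed = config$seed_boot)

  result <- structure(list(
    scores = scores, categories = categories, comparisons = comparisons,
    paired_comparisons = paired, propensity = propensity,
    response_auroc = response_auroc, ensemble = ensemble,
    test_evaluation = test_evaluation, final_ensemble = final_ensemble,
    predicted_nonresponders = predicted_nonresponders,
    prevalence = prevalence, config = config
  ), class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_artifacts(result, output_dir)
  result
}

#' Synthetic response-rate-reduction experiment
#'
#' Validates the pipeline against a lower response rate: runs the full
#' pipeline, selects synthetic nonresponders among the responding physicians
#' by jitter-and-select on their fitted average propensities
#' ([select_synthetic_nonresponders()]), conceals those physicians'
#' responses, and re-runs every stage (propensity, ensemble, combination) on
#' the reduced response set.
#'
#' @param cohort Cohort as for [run_pipeline()].
#' @param config A [pipeline_config()].
#' @param reduction A [reduction_config()]; its `seed` defaults to the
#'   pipeline's derived reduction seed when left at the constructor default.
#' @return Object of class `reduction_result`: `full` and `reduced` pipeline
#'   results, `selected` physician ids, and the headline triple
#'   (`observed_prevalence` excluding synthetic nonresponders,
#'   `predicted_prevalence` over true + synthetic nonresponses,
#'   `population_prevalence`) plus `shift` versus the fully informed
#'   estimate.
#' @export
run_reduction_experiment <- function(cohort, config = pipeline_config(),
                                     reduction = reduction_config()) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  if (!inherits(reduction, "reduction_config"))
    reduction <- do.call(reduction_config, reduction)
  full <- run_pipeline(cohort, config)

  responding <- full$categories$physician_id[full$categories$n_responses > 0]
  pr <- full$propensity$propensities
  pr <- pr[pr$physician_id %in% responding, ]
  selected <- if (reduction$frac_selected == 0) character(0) else
    select_synthetic_nonresponders(pr, reduction)

  reduced_cohort <- cohort
  conceal <- reduced_cohort$records$physician_id %in% selected
  item_cols <- paste0("item_", seq_len(PFI_N_ITEMS))
  reduced_cohort$records[conceal, item_cols] <- NA_integer_

  red_scores <- score_surveys(reduced_cohort$records)
  n_resp_phys <- length(unique(red_scores$physician_id[red_scores$is_response]))
  if (n_resp_phys < 10L)
    stop("reduced response set too small to fit (fewer than 10 responding ",
         "physicians)", call. = FALSE)
  reduced <- run_pipeline(reduced_cohort, config)

  structure(list(
    full = full, reduced = reduced, selected = selected,
    observed_prevalence = reduced$prevalence$observed_prevalence,
    predicted_prevalence = reduced$prevalence$predicted_prevalence,
    population_prevalence = reduced$prevalence$population_prevalence,
    shift = reduced$prevalence$population_prevalence -
      full$prevalence$population_prevalence
  ), class = "reduction_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("nonresponse-adjusted burnout prevalence pipeline\n")
  tab <- table(x$categories$category)
  cat(sprintf("  physicians: %d (never %d / partial %d / always %d)\n",
              nrow(x$categories), tab[["never"]], tab[["partial"]],
              tab[["always"]]))
  cat(sprintf("  invitations: %d, responses: %d (%.1f%%)\n",
              nrow(x$scores), sum(x$scores$is_response),
              100 * mean(x$scores$is_response)))
  cat(sprintf("  response-propensity AUROC: %.3f (95%% CI %.3f-%.3f)\n",
              x$response_auroc$auroc, x$response_auroc$ci[1],
              x$response_auroc$ci[2]))
  if (!is.null(x$test_evaluation))
    cat(sprintf("  burnout AUROC on partial responders: %.3f\n",
                x$test_evaluation$auroc))
  print(x$prevalence)
  invisible(x)
}

#' @export
print.reduction_result <- function(x, ...) {
  cat("synthetic response-rate reduction\n")
  cat(sprintf("  synthetic nonresponders: %d physicians\n",
              length(x$selected)))
  cat(sprintf("  observed %.1f%% / predicted %.1f%% / population %.1f%%\n",
              100 * x$observed_prevalence, 100 * x$predicted_prevalence,
              100 * x$population_prevalence))
  cat(sprintf("  shift vs fully informed estimate: %+.1f points\n",
              100 * x$shift))
  invisible(x)
}
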
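# Response-propensity modelling: grouped cross-validated penalized logistic
# regression on the EHR feature table, plus the three weighting schemas.

#' Build the numeric design matrix from a feature table
#'
#' Numeric measures enter as-is; categorical measures (e.g. gender) are
#' expanded to treatment-coded dummies. Used internally by every model-fitting
#' step so that training and prediction share one schema.
#'
#' @param features Feature table with `physician_id`, `wave` and measure
#'   columns.
#' @param template Optional character vector of column names from a previous
#'   call; prediction matrices are conformed to it, and a missing column is a
#'   schema error naming the column.
#' @return Numeric matrix with one row per (physician, wave).
#' @export
build_feature_matrix <- function(features, template = NULL) {
  measures <- setdiff(names(features), c("physician_id", "wave"))
  df <- features[measures]
  is_num <- vapply(df, is.numeric, logical(1))
  mats <- list(as.matrix(df[is_num]))
  for (nm in names(df)[!is_num]) {
    f <- factor(df[[nm]])
    mm <- stats::model.matrix(~ f)[, -1, drop = FALSE]
    colnames(mm) <- paste0(nm, sub("^f", "_", colnames(mm)))
    mats <- c(mats, list(mm))
  }
  x <- do.call(cbind, mats)
  if (!is.null(template)) {
    missing_cols <- setdiff(template, colnames(x))
    if (length(missing_cols))
      stop("feature table is missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    x <- x[, template, drop = FALSE]
  }
  x
}

#' Estimate cross-validated response propensities
#'
#' Fits an elastic-net penalized logistic regression (mixing 0.5) of survey
#' response on the EHR features, with the penalty strength chosen by
#' cross-validated deviance. Propensities are produced out-of-fold: the
#' invitations are partitioned into `n_folds` folds grouped by physician
#' (both waves of a physician stay together), and each invitation is scored
#' by the model trained on the other folds. Features are standardized inside
#' each training fit (glmnet's internal standardization).
#'
#' @param features Feature table (`physician_id`, `wave`, measures).
#' @param response Logical vector, one per row of `features`: did the
#'   invitation yield a survey response (>= 4 of 10 items answered)?
#' @param n_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @return Object of class `propensity_result`: data.frame `propensities`
#'   (`physician_id`, `wave`, `fold`, `p`), full-data `coefficients`,
#'   penalty `lambda`, and the feature `schema` (column names).
#' @export
fit_propensity <- function(features, response, n_folds = 10L, seed = 1L) {
  response <- as.logical(response)
  if (length(response) != nrow(features))
    stop("response must have one entry per feature row", call. = FALSE)
  if (all(response) || !any(response))
    stop("degenerate outcome: need both responses and nonresponses",
         call. = FALSE)
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  x <- build_feature_matrix(features)
  fold <- grouped_folds(features$physician_id, n_folds, seed)
  p <- rep(NA_real_, nrow(x))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (all(response[tr]) || !any(response[tr]))
      stop("degenerate outcome inside training fold ", f, call. = FALSE)
    inner <- grouped_folds(features$physician_id[tr],
                           min(10L, length(unique(features$physician_id[tr]))),
                           seed + f)
    cv <- glmnet::cv.glmnet(x[tr, , drop = FALSE], response[tr],
                            family = "binomial", alpha = 0.5,
                            foldid = inner, type.measure = "deviance",
                            standardize = TRUE)
    p[!tr] <- as.numeric(stats::predict(cv, x[!tr, , drop = FALSE],
                                        s = "lambda.min", type = "response"))
  }
  # full-data fit for reporting / downstream reuse
  inner_all <- grouped_folds(features$physician_id,
                             min(10L, length(unique(features$physician_id))),
                             seed)
  cv_all <- glmnet::cv.glmnet(x, response, family = "binomial", alpha = 0.5,
                              foldid = inner_all, type.measure = "deviance",
                              standardize = TRUE)
  structure(list(
    propensities = data.frame(physician_id = features$physician_id,
                              wave = features$wave, fold = fold, p = p),
    coefficients = as.matrix(stats::coef(cv_all, s = "lambda.min")),
    lambda = cv_all$lambda.min,
    schema = colnames(x)
  ), class = "propensity_result")
}

#' Observation weights from response propensities
#'
#' Three schemas: `unweighted` (all 1, approximating the responder
#' population), `inverse_p` (`1 / max(p, 0.1)`, approximating the full
#' population; the propensity is floored at 0.1 to prevent extreme weights,
#' so weights lie in `[1, 10]`), and `one_minus_p` (`1 - p`, approximating the
#' nonresponder population; weights in `[0, 1]`). The floor applies only in
#' the `inverse_p` schema, never to stored propensities.
#'
#' @param p Response propensities in `(0, 1]`.
#' @param schema One of `"unweighted"`, `"inverse_p"`, `"one_minus_p"`.
#' @return Numeric weight vector.
#' @examples
#' compute_weights(c(0.05, 0.5, 1), "inverse_p")  # 10, 2, 1
#' @export
compute_weights <- function(p, schema = c("unweighted", "inverse_p",
                                          "one_minus_p")) {
  schema <- match.arg(schema)
  if (!is.numeric(p) || anyNA(p) || any(p <= 0 | p > 1))
    stop("propensities must lie in (0, 1]", call. = FALSE)
  switch(schema,
         unweighted = rep(1, length(p)),
         inverse_p = 1 / pmax(p, 0.1),
         one_minus_p = 1 - p)
}

#' AUROC of the response-propensity model with a bootstrap CI
#'
#' Discrimination of the out-of-fold propensities for the binary response
#' outcome; the confidence interval resamples physicians (not invitations)
#' with replacement, percentile method.
#'
#' @param result A `propensity_result` from [fit_propensity()].
#' @param response Logical response vector aligned with
#'   `result$propensities`.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level.
#' @return List: `auroc`, `ci` (length 2), `n_boot`.
#' @export
evaluate_response_auroc <- function(result, response, n_boot = 1000L,
                                    seed = 1L, level = 0.95) {
  stopifnot(inherits(result, "propensity_result"))
  pr <- result$propensities
  response <- as.logical(response)
  point <- auroc(pr$p, response)
  reps <- boot_by_physician(pr$physician_id, n_boot, seed, function(idx) {
    y <- response[idx]
    if (all(y) || !any(y)) return(NA_real_)
    auroc(pr$p[idx], y)
  })
  list(auroc = point, ci = percentile_ci(reps, level), n_boot = n_boot)
}

#' @export
print.propensity_result <- function(x, ...) {
  cat(sprintf("response propensities for %d invitations (%d folds)\n",
              nrow(x$propensities), length(unique(x$propensities$fold))))
  cat(sprintf("  propensity range: %.3f - %.3f; penalty lambda = %.4g\n",
              min(x$propensities$p), max(x$propensities$p), x$lambda))
  nz <- sum(x$coefficients[-1, 1] != 0)
  cat(sprintf("  nonzero coefficients: %d of %d\n", nz,
              nrow(x$coefficients) - 1L))
  invisible(x)
}
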
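# Burnout-score prediction: three response-propensity weighted penalized
# linear regressions, bias-corrected on a held-out calibration split of
# always responders, with a sigmoid conversion of predicted scores to
# burnout probabilities.

WEIGHT_SCHEMAS <- c("unweighted", "inverse_p", "one_minus_p")

#' Split physicians into training and calibration sets
#'
#' Physician-level split (both waves of one physician end up on the same
#' side). The training count is `round(frac_train * n)`, so 340 physicians at
#' 0.8 give exactly 272 / 68.
#'
#' @param physician_ids Character vector of physician ids (duplicates
#'   allowed; the split operates on the unique set).
#' @param frac_train Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with character vectors `train` and `calibration`.
#' @export
split_train_calibrate <- function(physician_ids, frac_train = 0.8, seed = 1L) {
  frac_train <- check_number(frac_train, "frac_train", 0, 1,
                             open_lower = TRUE, open_upper = TRUE)
  uid <- unique(physician_ids)
  if (length(uid) < 5L)
    stop("need at least 5 physicians to split", call. = FALSE)
  set.seed(seed)
  shuffled <- sample(uid)
  n_train <- max(1L, min(length(uid) - 1L, round(frac_train * length(uid))))
  list(train = sort(shuffled[seq_len(n_train)]),
       calibration = sort(shuffled[-seq_len(n_train)]))
}

#' Fit one weighted penalized linear burnout model
#'
#' Elastic-net (mixing 0.5) regression of the 0-10 burnout score on the
#' features, with observation weights from one weighting schema and penalty
#' strength chosen by cross-validated mean squared error grouped by
#' physician.
#'
#' @param x Numeric design matrix (see [build_feature_matrix()]).
#' @param y Burnout scores (0-10 scale).
#' @param weights Nonnegative observation weights, not all zero.
#' @param physician_id Ids used to group the internal CV folds.
#' @param seed Integer seed for fold assignment.
#' @return List of class `weighted_burnout_model`: `coefficients` (raw),
#'   `std_coefficients` (scaled by feature SD, for reporting), `lambda`,
#'   `schema_cols`, and the underlying `cv.glmnet` fit.
#' @export
fit_weighted_burnout_model <- function(x, y, weights, physician_id,
                                       seed = 1L) {
  if (length(unique(y)) < 2L)
    stop("need at least 2 distinct burnout scores to fit", call. = FALSE)
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be nonnegative and not all zero", call. = FALSE)
  keep <- weights > 0
  xk <- x[keep, , drop = FALSE]; yk <- y[keep]; wk <- weights[keep]
  idk <- physician_id[keep]
  foldid <- grouped_folds(idk, min(10L, length(unique(idk))), seed)
  cv <- glmnet::cv.glmnet(xk, yk, weights = wk, family = "gaussian",
                          alpha = 0.5, foldid = foldid,
                          type.measure = "mse", standardize = TRUE)
  beta <- as.matrix(stats::coef(cv, s = "lambda.min"))
  sds <- apply(xk, 2L, stats::sd)
  structure(list(coefficients = beta,
                 std_coefficients = beta[-1L, 1L] * sds,
                 lambda = cv$lambda.min,
                 schema_cols = colnames(x),
                 fit = cv),
            class = "weighted_burnout_model")
}

predict_schema <- function(model, x) {
  as.numeric(stats::predict(model$fit, x, s = "lambda.min"))
}

#' Bias-correction coefficients from a calibration split
#'
#' Ordinary least squares of the actual burnout scores on the three
#' schema-specific predictions (with intercept):
#' `actual ~ b0 + b1 * unweighted + b2 * inverse_p + b3 * one_minus_p`.
#' A rank-deficient design (e.g. collinear predictions) falls back to ridge
#' with a tiny penalty, with a warning.
#'
#' @param actual Actual burnout scores in the calibration split.
#' @param predictions Matrix or data.frame with one column per schema.
#' @return Named numeric vector `(intercept, unweighted, inverse_p,
#'   one_minus_p)`.
#' @export
fit_bias_correction <- function(actual, predictions) {
  predictions <- as.matrix(predictions)
  if (length(actual) < 5L)
    stop("calibration split must have at least 5 observations", call. = FALSE)
  if (anyNA(predictions) || any(!is.finite(predictions)))
    stop("predictions must be finite", call. = FALSE)
  X <- cbind(1, predictions)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("collinear schema predictions; using ridge fallback for ",
            "bias correction")
    XtX <- crossprod(X) + diag(1e-8, ncol(X))
    beta <- solve(XtX, crossprod(X, actual))[, 1L]
  } else {
    beta <- qr.coef(qrX, actual)
  }
  stats::setNames(as.numeric(beta), c("intercept", WEIGHT_SCHEMAS))
}

#' Train the bias-corrected burnout prediction ensemble
#'
#' End-to-end training procedure on the always-responder pool:
#' \enumerate{
#'   \item split physicians 80/20 into training and calibration sets
#'     ([split_train_calibrate()]);
#'   \item on the training set, fit one penalized linear model per weighting
#'     schema (unweighted, 1/p, 1-p) using the supplied response
#'     propensities ([fit_weighted_burnout_model()]);
#'   \item predict the calibration set with each model and regress actual
#'     scores on the three predictions ([fit_bias_correction()]);
#'   \item set the sigmoid scale `s` so that a logistic error distribution
#'     matches the calibration residual SD (`s = sd * sqrt(3) / pi`), and
#'     pick the probability operating threshold by Youden's J on the
#'     calibration split.
#' }
#'
#' @param features Feature table for the training pool (always responders'
#'   responses).
#' @param scores Burnout scores aligned with `features` rows.
#' @param propensities Response propensities aligned with `features` rows.
#' @param frac_train Training fraction for the physician-level split.
#' @param seed Integer seed (split and fold assignment).
#' @return Object of class `burnout_ensemble`: per-schema models, `beta`
#'   bias-correction coefficients, sigmoid scale `s`, burnout `threshold`
#'   (3.325), probability `operating_threshold`, feature `schema`, and the
#'   split.
#' @export
train_burnout_ensemble <- function(features, scores, propensities,
                                   frac_train = 0.8, seed = 1L) {
  stopifnot(nrow(features) == length(scores),
            length(scores) == length(propensities))
  x <- build_feature_matrix(features)
  split <- split_train_calibrate(features$physician_id, frac_train, seed)
  tr <- features$physician_id %in% split$train
  models <- lapply(WEIGHT_SCHEMAS, function(sch) {
    w <- compute_weights(propensities[tr], sch)
    fit_weighted_burnout_model(x[tr, , drop = FALSE], scores[tr], w,
                               features$physician_id[tr], seed = seed)
  })
  names(models) <- WEIGHT_SCHEMAS
  pred_cal <- vapply(models, predict_schema, numeric(sum(!tr)),
                     x = x[!tr, , drop = FALSE])
  beta <- fit_bias_correction(scores[!tr], pred_cal)
  ens_cal <- as.numeric(cbind(1, pred_cal) %*% beta)
  resid_sd <- stats::sd(scores[!tr] - ens_cal)
  s <- max(resid_sd * sqrt(3) / pi, 1e-6)
  prob_cal <- stats::plogis((ens_cal - PFI_BURNOUT_THRESHOLD) / s)
  actual_cal <- scores[!tr] >= PFI_BURNOUT_THRESHOLD
  op <- if (any(actual_cal) && !all(actual_cal))
    youden_threshold(prob_cal, actual_cal) else 0.5
  structure(list(models = models, beta = beta, s = s,
                 threshold = PFI_BURNOUT_THRESHOLD,
                 operating_threshold = op,
                 schema = colnames(x), split = split, seed = seed),
            class = "burnout_ensemble")
}

#' Predict bias-corrected burnout scores
#'
#' Applies the three schema models and combines them with the
#' bias-correction coefficients: `b0 + sum_k b_k * yhat_k`. Predictions are
#' deliberately not clamped to `[0, 10]`; downstream estimation uses
#' probabilities, not scores.
#'
#' @param ensemble A `burnout_ensemble` from [train_burnout_ensemble()].
#' @param features Feature table with the columns used in training (a
#'   missing column is an error naming the column).
#' @return Numeric vector of predicted scores.
#' @export
predict_ensemble <- function(ensemble, features) {
  stopifnot(inherits(ensemble, "burnout_ensemble"))
  x <- build_feature_matrix(features, template = ensemble$schema)
  preds <- vapply(ensemble$models, predict_schema, numeric(nrow(x)), x = x)
  if (nrow(x) == 1L) preds <- matrix(preds, nrow = 1L)
  as.numeric(cbind(1, preds) %*% ensemble$beta)
}

#' Convert a predicted burnout score to a burnout probability
#'
#' Logistic (sigmoid) conversion centered at the burnout threshold:
#' `plogis((score - 3.325) / s)`. Strictly increasing in the score, exactly
#' 0.5 at the threshold.
#'
#' @param score Predicted burnout score(s).
#' @param ensemble A `burnout_ensemble`, or a single positive scale via `s`.
#' @param s Sigmoid scale; defaults to the ensemble's stored scale.
#' @return Probabilities in (0, 1).
#' @examples
#' score_to_probability(3.325, s = 1)  # 0.5
#' @export
score_to_probability <- function(score, ensemble = NULL, s = NULL) {
  if (is.null(s)) {
    stopifnot(inherits(ensemble, "burnout_ensemble"))
    s <- ensemble$s
  }
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s <= 0)
    stop("sigmoid scale s must be a single positive number", call. = FALSE)
  stats::plogis((score - PFI_BURNOUT_THRESHOLD) / s)
}

#' Evaluate burnout probability predictions
#'
#' Computes AUROC, AUPRC (average precision) and sensitivity/specificity at a
#' fixed probability operating threshold (by default the Youden threshold the
#' ensemble chose on its calibration split). Percentile bootstrap CIs
#' resample physicians.
#'
#' @param probabilities Predicted burnout probabilities.
#' @param actual Logical burnout flags (score >= 3.325).
#' @param physician_id Ids for the bootstrap resampling unit.
#' @param operating_threshold Probability cutoff for sensitivity/specificity.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return Object of class `evaluation_report`.
#' @export
evaluate_predictions <- function(probabilities, actual, physician_id,
                                 operating_threshold = 0.5, n_boot = 1000L,
                                 seed = 1L, level = 0.95) {
  actual <- as.logical(actual)
  if (all(actual) || !any(actual))
    stop("both outcome classes must be present", call. = FALSE)
  point_roc <- auroc(probabilities, actual)
  point_pr <- auprc(probabilities, actual)
  ss <- sens_spec_at(probabilities, actual, operating_threshold)
  reps <- boot_by_physician(physician_id, n_boot, seed, function(idx) {
    y <- actual[idx]
    if (all(y) || !any(y)) return(c(NA_real_, NA_real_))
    c(auroc(probabilities[idx], y), auprc(probabilities[idx], y))
  })
  structure(list(auroc = point_roc, auroc_ci = percentile_ci(reps[1, ], level),
                 auprc = point_pr, auprc_ci = percentile_ci(reps[2, ], level),
                 sensitivity = unname(ss["sensitivity"]),
                 specificity = unname(ss["specificity"]),
                 operating_threshold = operating_threshold,
                 n = length(actual), n_boot = n_boot, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("AUROC %.3f (95%% CI %.3f-%.3f)\n", x$auroc,
              x$auroc_ci[1], x$auroc_ci[2]))
  cat(sprintf("AUPRC %.3f (95%% CI %.3f-%.3f)\n", x$auprc,
              x$auprc_ci[1], x$auprc_ci[2]))
  cat(sprintf("sensitivity %.0f%%, specificity %.0f%% at threshold %.3f\n",
              100 * x$sensitivity, 100 * x$specificity,
              x$operating_threshold))
  invisible(x)
}

#' @export
print.burnout_ensemble <- function(x, ...) {
  cat("bias-corrected burnout ensemble\n")
  cat("  beta:", paste(sprintf("%s=%.3f", names(x$beta), x$beta),
                       collapse = ", "), "\n")
  cat(sprintf("  sigmoid scale s = %.3f, operating threshold = %.3f\n",
              x$s, x$operating_threshold))
  cat(sprintf("  train/calibration physicians: %d / %d\n",
              length(x$split$train), length(x$split$calibration)))
  invisible(x)
}
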
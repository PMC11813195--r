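# Population-level prevalence: combine observed responder prevalence with
# model-predicted nonresponder prevalence; synthetic response-rate-reduction
# validation via jitter-and-select.

#' Combine observed and predicted burnout prevalence
#'
#' Survey-level combination (default) treats every invitation as one unit:
#' `(sum(observed flags) + sum(predicted probabilities)) / (n_responses +
#' n_nonresponses)`, a convex combination of the observed and predicted
#' components weighted by group size. Physician-level combination first
#' averages within physician (over that physician's observed flags and
#' predicted probabilities together), then averages across physicians.
#'
#' Confidence intervals come from a percentile bootstrap that resamples
#' physicians with replacement; inside each replicate the predicted
#' probabilities are additionally resampled as Bernoulli draws so that
#' prediction uncertainty propagates into the interval.
#'
#' @param observed Logical burnout flags for the observed responses.
#' @param predicted Predicted burnout probabilities for the nonresponses.
#' @param observed_ids,predicted_ids Physician ids aligned with `observed` /
#'   `predicted` (a physician may appear in both, e.g. a partial responder).
#' @param weighting_level `"survey"` (default) or `"physician"`.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return Object of class `prevalence_estimate` with `observed_prevalence`,
#'   `predicted_prevalence` (+ CI), `population_prevalence` (+ CI) and
#'   counts.
#' @export
combine_prevalence <- function(observed, predicted,
                               observed_ids = NULL, predicted_ids = NULL,
                               weighting_level = c("survey", "physician"),
                               n_boot = 1000L, seed = 1L, level = 0.95) {
  weighting_level <- match.arg(weighting_level)
  observed <- as.logical(observed)
  predicted <- as.numeric(predicted)
  n_obs <- length(observed); n_pred <- length(predicted)
  if (n_obs + n_pred == 0L)
    stop("need at least one observed response or one predicted nonresponse",
         call. = FALSE)
  if (n_pred && (anyNA(predicted) || any(predicted < 0 | predicted > 1)))
    stop("predicted probabilities must lie in [0, 1]", call. = FALSE)
  if (is.null(observed_ids)) observed_ids <- paste0("obs", seq_len(n_obs))
  if (is.null(predicted_ids)) predicted_ids <- paste0("prd", seq_len(n_pred))

  point <- function(obs, prd, ids_o, ids_p) {
    if (weighting_level == "survey") {
      obs_prev <- if (length(obs)) mean(obs) else NA_real_
      prd_prev <- if (length(prd)) mean(prd) else NA_real_
      pop <- (sum(obs) + sum(prd)) / (length(obs) + length(prd))
    } else {
      vals <- c(as.numeric(obs), prd)
      ids <- c(ids_o, ids_p)
      per_phys <- tapply(vals, ids, mean)
      pop <- mean(per_phys)
      obs_prev <- if (length(obs)) mean(tapply(as.numeric(obs), ids_o, mean))
                  else NA_real_
      prd_prev <- if (length(prd)) mean(tapply(prd, ids_p, mean))
                  else NA_real_
    }
    c(obs = obs_prev, prd = prd_prev, pop = pop)
  }
  pt <- point(observed, predicted, observed_ids, predicted_ids)

  all_ids <- unique(c(observed_ids, predicted_ids))
  obs_rows <- split(seq_len(n_obs), observed_ids)
  prd_rows <- split(seq_len(n_pred), predicted_ids)
  set.seed(seed)
  reps <- replicate(n_boot, {
    take <- sample(all_ids, length(all_ids), replace = TRUE)
    oi <- unlist(obs_rows[take[take %in% names(obs_rows)]], use.names = FALSE)
    pi_ <- unlist(prd_rows[take[take %in% names(prd_rows)]], use.names = FALSE)
    prd_draw <- if (length(pi_))
      as.numeric(stats::runif(length(pi_)) < predicted[pi_]) else numeric(0)
    point(observed[oi], prd_draw,
          if (length(oi)) observed_ids[oi] else character(0),
          if (length(pi_)) predicted_ids[pi_] else character(0))
  })
  structure(list(
    weighting_level = weighting_level,
    n_responses = n_obs,
    n_nonresponses = n_pred,
    observed_prevalence = unname(pt["obs"]),
    predicted_prevalence = unname(pt["prd"]),
    predicted_ci = if (n_pred) percentile_ci(reps["prd", ], level)
                   else c(NA_real_, NA_real_),
    population_prevalence = unname(pt["pop"]),
    population_ci = percentile_ci(reps["pop", ], level),
    n_boot = n_boot, seed = seed
  ), class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("population burnout prevalence (%s-level combination)\n",
              x$weighting_level))
  cat(sprintf("  observed  (n=%d responses):    %.1f%%\n", x$n_responses,
              100 * x$observed_prevalence))
  if (x$n_nonresponses > 0)
    cat(sprintf("  predicted (n=%d nonresponses): %.1f%% (95%% CI %.1f-%.1f%%)\n",
                x$n_nonresponses, 100 * x$predicted_prevalence,
                100 * x$predicted_ci[1], 100 * x$predicted_ci[2]))
  cat(sprintf("  population:                    %.1f%% (95%% CI %.1f-%.1f%%)\n",
              100 * x$population_prevalence,
              100 * x$population_ci[1], 100 * x$population_ci[2]))
  invisible(x)
}

#' Configuration for the synthetic response-rate reduction
#'
#' Parameters of the jitter-and-select procedure: each cycle adds independent
#' triangular jitter (from `jitter_low` to `jitter_high`, mode
#' `jitter_mode`) to every responding physician's average response
#' propensity and marks the lowest `frac_selected` fraction as candidate
#' synthetic nonresponders; after `n_cycles` cycles, physicians who were
#' candidates in at least `selection_threshold` cycles become final synthetic
#' nonresponders.
#'
#' `frac_selected = 0` is permitted as the exact no-op limit (no candidates,
#' empty selection).
#'
#' @param jitter_low,jitter_mode,jitter_high Triangular jitter parameters
#'   (defaults -0.5, 0, 0.5).
#' @param frac_selected Fraction marked per cycle (default 0.20).
#' @param n_cycles Number of jitter cycles (default 100).
#' @param selection_threshold Minimum candidate count for final selection
#'   (default 50).
#' @param seed Integer seed.
#' @return Object of class `reduction_config`.
#' @export
reduction_config <- function(jitter_low = -0.5, jitter_mode = 0,
                             jitter_high = 0.5, frac_selected = 0.20,
                             n_cycles = 100L, selection_threshold = 50L,
                             seed = 1L) {
  cfg <- list(
    jitter_low = check_number(jitter_low, "jitter_low"),
    jitter_mode = check_number(jitter_mode, "jitter_mode"),
    jitter_high = check_number(jitter_high, "jitter_high"),
    frac_selected = check_number(frac_selected, "frac_selected", 0, 1,
                                 open_upper = TRUE),
    n_cycles = check_count(n_cycles, "n_cycles"),
    selection_threshold = check_count(selection_threshold,
                                      "selection_threshold"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (!(cfg$jitter_low < cfg$jitter_mode && cfg$jitter_mode < cfg$jitter_high))
    stop_config("jitter_mode", "must satisfy jitter_low < mode < jitter_high")
  if (cfg$selection_threshold > cfg$n_cycles)
    stop_config("selection_threshold", "must not exceed n_cycles")
  structure(cfg, class = "reduction_config")
}

#' Select synthetic nonresponders by jitter-and-select
#'
#' See [reduction_config()] for the procedure. The per-physician propensity
#' is the mean of that physician's per-wave propensities; jitter is applied
#' to this average once per cycle, without truncation (candidate ranking is
#' invariant to shifts outside (0,1)).
#'
#' @param propensities Named numeric vector of per-physician average response
#'   propensities, or a data.frame with `physician_id` and `p` (averaged
#'   internally).
#' @param config A [reduction_config()].
#' @return Character vector of selected physician ids (possibly empty).
#' @export
select_synthetic_nonresponders <- function(propensities,
                                           config = reduction_config()) {
  if (!inherits(config, "reduction_config"))
    config <- do.call(reduction_config, config)
  if (is.data.frame(propensities)) {
    propensities <- tapply(propensities$p, propensities$physician_id, mean)
    propensities <- stats::setNames(as.numeric(propensities),
                                    names(propensities) %||%
                                      dimnames(propensities)[[1]])
  }
  if (is.null(names(propensities)))
    stop("propensities must be named by physician id", call. = FALSE)
  n <- length(propensities)
  if (n < 5L)
    stop("need at least 5 responding physicians with propensities",
         call. = FALSE)
  k <- if (config$frac_selected == 0) 0L
       else max(1L, floor(config$frac_selected * n))
  if (k == 0L) return(character(0))
  set.seed(config$seed)
  hits <- stats::setNames(integer(n), names(propensities))
  for (cycle in seq_len(config$n_cycles)) {
    jit <- rtriangular(n, config$jitter_low, config$jitter_mode,
                       config$jitter_high)
    cand <- names(sort(propensities + jit))[seq_len(k)]
    hits[cand] <- hits[cand] + 1L
  }
  names(hits)[hits >= config$selection_threshold]
}
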
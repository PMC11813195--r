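#' Score the 10-item burnout battery for one respondent
#'
#' The burnout score is the mean of the answered items (0-4 Likert) rescaled
#' to 0-10 by multiplying by 2.5. An invitation counts as a survey response
#' when at least 4 of the 10 items are answered; otherwise the score is
#' undefined. Scores at or above 3.325 are flagged as indicative of burnout
#' symptoms.
#'
#' Partially answered batteries (4-9 items) are scored as the mean of the
#' available items: no imputation is performed.
#'
#' @param items Numeric vector of length 10; `NA` marks an unanswered item,
#'   answered items must be integers in 0-4.
#' @return A list of class `burnout_score`: `n_answered`, `is_response`,
#'   `score` (NA unless a response), `burnout` (NA unless a response).
#' @examples
#' score_pfi_burnout(c(2, 2, 1, 1, 1, 1, 1, 1, 1, 2))
#' @export
score_pfi_burnout <- function(items) {
  if (!is.numeric(items) && !all(is.na(items)))
    stop("items must be a numeric vector of length 10", call. = FALSE)
  if (length(items) != PFI_N_ITEMS)
    stop(sprintf("items must have length %d, got %d", PFI_N_ITEMS,
                 length(items)), call. = FALSE)
  answered <- which(!is.na(items))
  bad <- answered[items[answered] < 0 | items[answered] > PFI_ITEM_MAX |
                    items[answered] != floor(items[answered])]
  if (length(bad))
    stop(sprintf("item %d has value %s outside {0,...,4}", bad[1L],
                 format(items[bad[1L]])), call. = FALSE)
  is_response <- length(answered) >= PFI_MIN_ANSWERED
  score <- if (is_response) mean(items[answered]) * PFI_SCALE else NA_real_
  structure(list(
    n_answered = length(answered),
    is_response = is_response,
    score = score,
    burnout = if (is_response) score >= PFI_BURNOUT_THRESHOLD else NA
  ), class = "burnout_score")
}

#' Score every survey record in a cohort
#'
#' Applies [score_pfi_burnout()] to each row of a survey-records table.
#'
#' @param records data.frame with `physician_id`, `wave` and item columns
#'   `item_1` ... `item_10` (as produced by [generate_cohort()] or read with
#'   [read_cohort()]).
#' @return data.frame with `physician_id`, `wave`, `n_answered`,
#'   `is_response`, `score`, `burnout`.
#' @export
score_surveys <- function(records) {
  item_cols <- paste0("item_", seq_len(PFI_N_ITEMS))
  missing_cols <- setdiff(item_cols, names(records))
  if (length(missing_cols))
    stop("records is missing item columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  mat <- as.matrix(records[item_cols])
  out <- lapply(seq_len(nrow(records)),
                function(i) score_pfi_burnout(mat[i, ]))
  data.frame(
    physician_id = records$physician_id,
    wave = records$wave,
    n_answered = vapply(out, `[[`, integer(1), "n_answered"),
    is_response = vapply(out, `[[`, logical(1), "is_response"),
    score = vapply(out, `[[`, numeric(1), "score"),
    burnout = vapply(out, function(s) as.logical(s$burnout), logical(1))
  )
}

#' Categorize one physician's response pattern
#'
#' A physician is a `never` responder with zero responses, an `always`
#' responder when every invitation drew a response (including physicians
#' invited only once), and a `partial` responder when invited twice with
#' exactly one response.
#'
#' @param invited_waves Integer vector of waves the physician was invited in
#'   (length 1 or 2).
#' @param responded_waves Integer vector of waves with a response (subset of
#'   `invited_waves`).
#' @return One of `"never"`, `"partial"`, `"always"`.
#' @examples
#' categorize_responder(c(1, 2), 1)  # partial
#' categorize_responder(1, 1)        # always
#' @export
categorize_responder <- function(invited_waves, responded_waves = integer()) {
  n_inv <- length(invited_waves)
  if (n_inv < 1L || n_inv > 2L)
    stop("a physician must have 1 or 2 invitations, got ", n_inv,
         call. = FALSE)
  if (!all(responded_waves %in% invited_waves))
    stop("responded_waves must be a subset of invited_waves", call. = FALSE)
  n_resp <- length(responded_waves)
  if (n_resp == 0L) "never"
  else if (n_resp == n_inv) "always"
  else "partial"
}

#' Categorize every physician in a scored cohort
#'
#' @param scores data.frame from [score_surveys()].
#' @return data.frame with one row per physician: `physician_id`,
#'   `n_invited`, `n_responses`, `category` (factor never/partial/always).
#' @export
categorize_responders <- function(scores) {
  sp <- split(scores$is_response, scores$physician_id)
  data.frame(
    physician_id = names(sp),
    n_invited = vapply(sp, length, integer(1)),
    n_responses = vapply(sp, sum, integer(1)),
    category = factor(
      vapply(sp, function(r) {
        if (!any(r)) "never" else if (all(r)) "always" else "partial"
      }, character(1)),
      levels = c("never", "partial", "always")),
    row.names = NULL
  )
}

#' @export
print.burnout_score <- function(x, ...) {
  if (x$is_response)
    cat(sprintf("burnout score %.3f (%d/10 items), burnout: %s\n",
                x$score, x$n_answered, x$burnout))
  else
    cat(sprintf("nonresponse (%d/10 items answered)\n", x$n_answered))
  invisible(x)
}
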
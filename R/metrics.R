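#' Area under the ROC curve (midrank convention)
#'
#' Computed from the Mann-Whitney U statistic with midranks, which is
#' equivalent to trapezoidal integration of the ROC curve and handles tied
#' scores by averaging.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Logical (or 0/1) outcome labels; both classes must be
#'   present.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.2, 0.6, 0.4), c(TRUE, FALSE, TRUE, FALSE))
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both outcome classes must be present to compute AUROC",
         call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated (average-precision) area: thresholds sweep the distinct
#' score values from high to low, and tied scores enter as a block. With
#' constant scores the area equals the prevalence of the positive class.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels)
  if (n_pos == 0L || n_pos == length(labels))
    stop("both outcome classes must be present to compute AUPRC",
         call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # cumulative counts at each distinct threshold (tie blocks collapse)
  block_end <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[block_end]
  n_at <- block_end
  precision <- tp / n_at
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Youden-optimal operating threshold
#'
#' Returns the threshold (among the observed scores) maximizing
#' sensitivity + specificity - 1 for the rule "positive if score >=
#' threshold". Ties are broken toward the highest threshold.
#'
#' @inheritParams auroc
#' @return A single threshold value.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  cand <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both outcome classes must be present", call. = FALSE)
  j <- vapply(cand, function(t) {
    sens <- sum(labels & scores >= t) / n_pos
    spec <- sum(!labels & scores < t) / n_neg
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

sens_spec_at <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  pred <- scores >= threshold
  c(sensitivity = sum(pred & labels) / sum(labels),
    specificity = sum(!pred & !labels) / sum(!labels))
}

# Physician-level percentile bootstrap of an arbitrary statistic.
# stat_fn receives the row indices of the resampled physicians.
boot_by_physician <- function(physician_id, n_boot, seed, stat_fn) {
  set.seed(seed)
  uid <- unique(physician_id)
  rows_of <- split(seq_along(physician_id), physician_id)
  replicate(n_boot, {
    take <- sample(uid, length(uid), replace = TRUE)
    idx <- unlist(rows_of[as.character(take)], use.names = FALSE)
    stat_fn(idx)
  })
}
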
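# Internal helpers shared across modules.

# Burnout battery constants: 10 items scored 0-4, mean rescaled to 0-10 by
# x2.5; scores >= 3.325 flag burnout symptoms; >= 4 answered items define a
# survey response.
PFI_N_ITEMS <- 10L
PFI_ITEM_MAX <- 4L
PFI_SCALE <- 2.5
PFI_BURNOUT_THRESHOLD <- 3.325
PFI_MIN_ANSWERED <- 4L

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop_config(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok) {
    lb <- if (open_lower) "(" else "["
    ub <- if (open_upper) ")" else "]"
    stop_config(field, sprintf("must be a single number in %s%g, %g%s",
                               lb, lower, upper, ub))
  }
  as.numeric(x)
}

# Draws from a triangular distribution on [low, high] with mode `mode`
# by inverse-CDF transform of uniforms.
rtriangular <- function(n, low = -0.5, mode = 0, high = 0.5) {
  stopifnot(low < mode, mode < high)
  u <- stats::runif(n)
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

# Assign units (e.g. physicians) to k folds, balanced, in seeded random order.
grouped_folds <- function(ids, k, seed) {
  uid <- unique(ids)
  if (length(uid) < k) k <- length(uid)
  set.seed(seed)
  shuffled <- sample(uid)
  fold_of <- rep(seq_len(k), length.out = length(uid))
  names(fold_of) <- shuffled
  unname(fold_of[as.character(ids)])
}

# Percentile interval from a vector of bootstrap replicates.
percentile_ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  unname(stats::quantile(x, c(a, 1 - a), na.rm = TRUE, names = FALSE, type = 7))
}
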
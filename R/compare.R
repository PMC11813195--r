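#' Compare responder groups on features and demographics
#'
#' Produces a descriptive comparison table across responder categories
#' (never / partial / always): continuous measures are summarized as
#' median (IQR) and tested with the Kruskal-Wallis test; categorical measures
#' as n (%) with the Fisher exact test. Following the convention of reporting
#' the window before the most recent survey, each physician contributes the
#' feature row of their most recent invited wave.
#'
#' Fisher's test is exact for tables up to 2x3; larger tables fall back to a
#' Monte Carlo p-value with a fixed internal seed. No multiple-testing
#' correction is applied. Measures that are constant across all groups are
#' flagged degenerate with an undefined p-value.
#'
#' @param features Feature table (`physician_id`, `wave`, measure columns).
#' @param categories Output of [categorize_responders()].
#' @return data.frame of class `comparison_table`: one row per measure with
#'   per-group summaries, `test`, `p_value` and a `flag` column
#'   (`""` or `"degenerate"`).
#' @export
compare_groups <- function(features, categories) {
  stopifnot(is.data.frame(features), is.data.frame(categories))
  # most recent invited wave per physician
  ord <- order(features$physician_id, -features$wave)
  latest <- features[ord, ][!duplicated(features$physician_id[ord]), ]
  df <- merge(latest, categories[c("physician_id", "category")],
              by = "physician_id")
  df$category <- droplevels(factor(df$category))
  counts <- table(df$category)
  if (any(counts == 0L)) {
    warning("dropping empty group(s): ",
            paste(names(counts)[counts == 0L], collapse = ", "))
    df$category <- droplevels(df$category)
  }
  groups <- levels(df$category)
  if (length(groups) < 2L)
    stop("need at least 2 nonempty groups to compare", call. = FALSE)

  measures <- setdiff(names(features), c("physician_id", "wave"))
  rows <- lapply(measures, function(mname) {
    v <- df[[mname]]
    if (is.numeric(v)) {
      summ <- vapply(groups, function(g) {
        x <- v[df$category == g]
        sprintf("%.1f (%.1f-%.1f)", stats::median(x, na.rm = TRUE),
                stats::quantile(x, 0.25, na.rm = TRUE, names = FALSE),
                stats::quantile(x, 0.75, na.rm = TRUE, names = FALSE))
      }, character(1))
      if (length(unique(v[!is.na(v)])) < 2L) {
        p <- NA_real_; flag <- "degenerate"
      } else {
        p <- stats::kruskal.test(v, df$category)$p.value; flag <- ""
      }
      test <- "kruskal_wallis"
    } else {
      v <- factor(v)
      # reference level = modal category
      v <- stats::relevel(v, ref = names(which.max(table(v))))
      tab <- table(v, df$category)
      summ <- vapply(groups, function(g) {
        n <- sum(df$category == g)
        top <- tab[levels(v)[length(levels(v))], g]
        sprintf("%d (%.0f%%)", top, 100 * top / max(n, 1L))
      }, character(1))
      if (nrow(tab) < 2L) {
        p <- NA_real_; flag <- "degenerate"; test <- "fisher"
      } else {
        test <- "fisher"
        if (nrow(tab) <= 2L && ncol(tab) <= 3L) {
          p <- stats::fisher.test(tab)$p.value
        } else {
          has_seed <- exists(".Random.seed", envir = globalenv())
          old <- if (has_seed) get(".Random.seed", envir = globalenv())
          set.seed(20260101L)
          p <- stats::fisher.test(tab, simulate.p.value = TRUE, B = 1e4)$p.value
          if (has_seed) assign(".Random.seed", old, envir = globalenv())
        }
        flag <- ""
      }
    }
    out <- data.frame(measure = mname, t(summ), test = test, p_value = p,
                      flag = flag, check.names = FALSE)
    names(out)[2:(1 + length(groups))] <- groups
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("comparison_table", class(res))
  res
}

#' Paired comparison of response vs nonresponse years
#'
#' For partial responders, compares each measure between the wave they
#' responded in and the wave they did not, with the Wilcoxon signed-rank test
#' on within-physician differences (zero differences dropped, per the
#' classical procedure). Rows with all-zero differences are flagged
#' degenerate.
#'
#' @param response_year data.frame of measures in each physician's response
#'   year (one row per physician).
#' @param nonresponse_year data.frame of the same measures, same physicians,
#'   same row order, in the nonresponse year.
#' @return data.frame of class `comparison_table` with per-arm
#'   median (IQR) summaries, `test = "wilcoxon_signed_rank"`, `p_value`,
#'   `flag`.
#' @export
compare_paired_years <- function(response_year, nonresponse_year) {
  stopifnot(is.data.frame(response_year), is.data.frame(nonresponse_year))
  if (nrow(response_year) != nrow(nonresponse_year))
    stop("paired tables must have the same number of rows", call. = FALSE)
  if (nrow(response_year) < 2L)
    stop("need at least 2 pairs", call. = FALSE)
  measures <- intersect(names(response_year), names(nonresponse_year))
  measures <- measures[vapply(response_year[measures], is.numeric, logical(1))]
  rows <- lapply(measures, function(mname) {
    x <- nonresponse_year[[mname]]
    y <- response_year[[mname]]
    keep <- !is.na(x) & !is.na(y)
    d <- y[keep] - x[keep]
    d <- d[d != 0]
    summ <- function(v) sprintf("%.1f (%.1f-%.1f)",
                                stats::median(v, na.rm = TRUE),
                                stats::quantile(v, 0.25, na.rm = TRUE, names = FALSE),
                                stats::quantile(v, 0.75, na.rm = TRUE, names = FALSE))
    if (length(d) == 0L) {
      p <- NA_real_; flag <- "degenerate"
    } else {
      p <- signed_rank_test(d)
      flag <- ""
    }
    data.frame(measure = mname, nonresponse_year = summ(x[keep]),
               response_year = summ(y[keep]), test = "wilcoxon_signed_rank",
               p_value = p, flag = flag)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("comparison_table", class(res))
  res
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided signed-rank test of symmetry about zero. Zero differences are
#' dropped by the caller; ties among the absolute differences take midranks.
#' For up to 16 nonzero differences the p-value is exact, by enumeration of
#' all sign assignments (`P(|W - mu| >= |w - mu|)` under the symmetric null);
#' beyond that a normal approximation with tie correction is used.
#'
#' @param d Numeric vector of nonzero paired differences.
#' @return Two-sided p-value.
#' @export
signed_rank_test <- function(d) {
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L) return(NA_real_)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= 16L) {
    # all 2^n sign assignments: W = sum of ranks with positive sign
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wdist <- as.numeric(signs %*% r)
    mean(abs(wdist - mu) >= abs(w - mu) - 1e-9)
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z <- (w - mu) / sigma
    2 * stats::pnorm(-abs(z))
  }
}

#' @export
print.comparison_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$p_value <- ifelse(is.na(df$p_value), "-",
                       formatC(df$p_value, format = "g", digits = 3))
  print(df, row.names = FALSE)
  invisible(x)
}
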
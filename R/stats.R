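# Group statistics: per-timepoint two-sample t tests with a sustained
# recovery-time rule, one-way ANOVA, and the Holm-Sidak step-down
# multiple-comparison procedure.

#' Two-sample t test with degenerate-variance conventions
#'
#' Wraps [stats::t.test()] with the conventions needed for quantized
#' small-sample data: when both groups have zero variance, `p = 1` if the
#' means are equal and `p = 0` (flagged as degenerate) if they differ.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @param var.equal Classic equal-variance t test (default) or Welch.
#' @return One-row tibble: `estimate` (mean of `x` minus mean of `y`),
#'   `statistic`, `df`, `p.value`, `degenerate`.
#' @export
ttest2 <- function(x, y, var.equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) abort("need >= 2 observations per group.")
  if (var(x) == 0 && var(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble(estimate = mean(x) - mean(y),
                  statistic = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                  df = length(x) + length(y) - 2,
                  p.value = if (eq) 1 else 0, degenerate = TRUE))
  }
  tt <- t.test(x, y, var.equal = var.equal)
  tibble(estimate = unname(diff(rev(tt$estimate))),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p.value = tt$p.value, degenerate = FALSE)
}

#' Per-timepoint two-sample t tests
#'
#' Compares two conditions at every shared timepoint, as done when testing
#' EP against control normalized diameters frame by frame.
#'
#' @param data Tidy data frame with columns `condition` (exactly two
#'   levels), `replicate`, `time_s`, `value`.
#' @param var.equal Equal-variance t (default) or Welch.
#' @return Tibble with one row per shared timepoint: `time_s`, `estimate`,
#'   `statistic`, `df`, `p.value`, `degenerate`.
#' @export
timepoint_ttest <- function(data, var.equal = TRUE) {
  data <- as_tibble(data)
  conds <- unique(data$condition)
  if (length(conds) != 2) abort("`data` must contain exactly two conditions.")
  shared <- intersect(data$time_s[data$condition == conds[1]],
                      data$time_s[data$condition == conds[2]])
  purrr::map_dfr(sort(shared), function(tt) {
    a <- data$value[data$condition == conds[1] & data$time_s == tt]
    b <- data$value[data$condition == conds[2] & data$time_s == tt]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble(time_s = tt, estimate = NA_real_, statistic = NA_real_,
                    df = NA_real_, p.value = NA_real_, degenerate = NA))
    }
    mutate(ttest2(a, b, var.equal = var.equal), time_s = tt, .before = 1)
  })
}

#' Recovery time from a per-timepoint p-value series
#'
#' The first post-EP grid time at which the comparison is non-significant
#' (`p >= alpha`) and stays non-significant at every later grid time
#' (sustained-recovery rule); a single non-significant dip followed by
#' renewed significance does not count as recovery.
#'
#' @param pvalues Data frame with columns `time_s` and `p.value` (e.g. from
#'   [timepoint_ttest()]), or a numeric p-value vector with times in
#'   `time_s`.
#' @param alpha Significance level.
#' @param after Only grid times strictly greater than this enter the rule
#'   (default 0 = post-EP).
#' @param time_s Grid times when `pvalues` is a bare vector.
#' @return Recovery time in seconds, or `NA` ("none") when significance
#'   persists through the grid.
#' @export
recovery_time <- function(pvalues, alpha = 0.05, after = 0, time_s = NULL) {
  if (is.data.frame(pvalues)) {
    time_s <- pvalues$time_s
    p <- pvalues$p.value
  } else {
    p <- pvalues
  }
  if (length(p) == 0 || is.null(time_s)) abort("empty p-value grid.")
  ord <- order(time_s)
  time_s <- time_s[ord]; p <- p[ord]
  keep <- time_s > after & !is.na(p)
  time_s <- time_s[keep]; p <- p[keep]
  if (length(p) == 0) abort("no usable post-EP timepoints.")
  ok <- p >= alpha
  sustained <- rev(cumprod(rev(ok))) > 0
  if (!any(sustained)) return(NA_real_)
  time_s[which(sustained)[1]]
}

#' One-way ANOVA
#'
#' Classic one-way fixed-effects ANOVA via [stats::oneway.test()] with equal
#' variances, plus the conventions for degenerate inputs: all observations
#' identical gives `F = 0, p = 1`; zero within-group variance with differing
#' means gives `F = Inf, p = 0` (flagged).
#'
#' @param groups A list of numeric samples, or a data frame with columns
#'   `value` and `group`.
#' @return One-row tibble: `statistic` (F), `df1`, `df2`, `p.value`,
#'   `degenerate`.
#' @export
oneway_anova <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 2) abort("need at least two groups.")
  if (any(lengths(groups) < 2)) abort("every group needs >= 2 observations.")
  k <- length(groups); n <- sum(lengths(groups))
  within0 <- all(map_dbl(groups, var) == 0)
  if (within0) {
    means <- map_dbl(groups, mean)
    eq <- max(means) - min(means) <= sqrt(.Machine$double.eps)
    return(tibble(statistic = if (eq) 0 else Inf, df1 = k - 1, df2 = n - k,
                  p.value = if (eq) 1 else 0, degenerate = TRUE))
  }
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  ow <- oneway.test(value ~ grp, var.equal = TRUE)
  tibble(statistic = unname(ow$statistic), df1 = unname(ow$parameter[1]),
         df2 = unname(ow$parameter[2]), p.value = ow$p.value,
         degenerate = FALSE)
}

#' Holm-Sidak step-down multiple-comparison procedure
#'
#' Sorts the p-values ascending; at step `i` among `m` hypotheses the
#' Sidak-adjusted threshold is `1 - (1 - alpha)^(1/(m - i + 1))`; rejection
#' proceeds while `p_(i)` is at or below its threshold and stops at the
#' first failure. Adjusted p-values are
#' `max_(j <= i) [1 - (1 - p_(j))^(m - j + 1)]`, clamped to `[0, 1]` and
#' monotone non-decreasing in the sorted order; results are mapped back to
#' the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error level.
#' @return Tibble in input order: `p.value`, `p.adjusted`, `reject`,
#'   `threshold` (the per-step Sidak threshold each hypothesis was compared
#'   against).
#' @export
holm_sidak <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  steps <- seq_len(m)
  thresh <- 1 - (1 - alpha)^(1 / (m - steps + 1))
  adj <- cummax(1 - (1 - ps)^(m - steps + 1))
  adj <- pmin(adj, 1)
  below <- ps <= thresh
  reject_sorted <- cumprod(below) > 0       # stop at first failure
  pos <- match(seq_len(m), ord)             # sorted position of each input
  tibble(p.value = p, p.adjusted = adj[pos], reject = reject_sorted[pos],
         threshold = thresh[pos])
}
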
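#' Absolute percentage test-retest difference
#'
#' `T-RT% = 200 |test - retest| / (test + retest)`: the absolute difference
#' as a percentage of the pair mean. Symmetric in its arguments, invariant
#' to a common positive scale factor, and bounded in `[0, 200)` for
#' positive inputs.
#'
#' @param test,retest outcome values (vectorized); each pair must have a
#'   positive sum.
#' @return Percentages, same length as the inputs.
#' @export
trt_percent <- function(test, retest) {
  s <- test + retest
  if (any(!is.finite(s)) || any(s <= 0))
    stop("trt_percent requires finite pairs with positive sum")
  200 * abs(test - retest) / s
}

# mean squares of the two-way subjects x sessions layout
.icc_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Two-way intraclass correlation coefficient
#'
#' Single-measure ICC from the two-way subjects-by-sessions mean-squares
#' decomposition. The default is the two-way random-effects,
#' absolute-agreement form ICC(A,1), which charges systematic
#' session differences against reliability; the consistency form ICC(C,1)
#' is available via `type`. Confidence intervals use the standard F-based
#' formulas (Satterthwaite degrees of freedom for absolute agreement).
#'
#' @param test,retest paired outcome vectors (same subjects, two sessions),
#'   or `test` may be an n x k matrix with `retest` missing.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @param conf_level confidence level for the interval. Default 0.95.
#' @return An object of class `icc_result`: `icc`, `ci` (length 2),
#'   `band` (reliability label, see [icc_band()]), `type`, `n`, `k`, the
#'   mean squares, and `undefined` (TRUE when the total variance is zero,
#'   in which case `icc` is `NA`).
#' @export
icc_two_way <- function(test, retest = NULL,
                        type = c("agreement", "consistency"),
                        conf_level = 0.95) {
  type <- match.arg(type)
  m <- if (is.matrix(test)) test else cbind(test, retest)
  if (any(!is.finite(m))) stop("ICC requires finite complete pairs")
  if (nrow(m) < 3L) stop("ICC requires at least 3 complete pairs")
  ms <- .icc_ms(m)
  n <- ms$n; k <- ms$k
  if (max(abs(m - mean(m))) < 1e-12 * max(1, abs(mean(m)))) {
    return(structure(list(icc = NA_real_, ci = c(NA_real_, NA_real_),
                          band = NA_character_, type = type, n = n, k = k,
                          msr = ms$msr, msc = ms$msc, mse = ms$mse,
                          undefined = TRUE), class = "icc_result"))
  }
  alpha <- 1 - conf_level
  if (type == "consistency") {
    icc <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    f <- ms$msr / ms$mse
    fl <- f / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    icc <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
    # McGraw & Wong F-based interval with Satterthwaite df
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (ms$msr - f1 * ms$mse) /
      (f1 * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    hi <- n * (f2 * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * f2 * ms$msr)
    ci <- c(lo, hi)
  }
  structure(list(icc = icc, ci = pmin(ci, 1), band = icc_band(icc),
                 type = type, n = n, k = k,
                 msr = ms$msr, msc = ms$msc, mse = ms$mse,
                 undefined = FALSE), class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("ICC (%s, single): undefined (zero total variance, n = %d)\n",
                x$type, x$n))
  } else {
    cat(sprintf("ICC (%s, single) = %.3f  [%.3f, %.3f]  (%s; n = %d)\n",
                x$type, x$icc, x$ci[1], x$ci[2], x$band, x$n))
  }
  invisible(x)
}

#' Reliability band for an ICC value
#'
#' Conventional interpretation bands: below 0.5 poor, 0.5 to 0.75 moderate,
#' 0.75 to 0.9 good, above 0.9 excellent. Values landing exactly on a
#' boundary are assigned to the higher band (deterministic convention).
#'
#' @param icc ICC estimate(s), at most 1.
#' @return Character vector of band labels.
#' @export
icc_band <- function(icc) {
  if (any(icc > 1 + 1e-12, na.rm = TRUE)) stop("ICC cannot exceed 1")
  out <- ifelse(icc < 0.5, "poor",
         ifelse(icc < 0.75, "moderate",
         ifelse(icc < 0.9, "good", "excellent")))
  out[is.na(icc)] <- NA_character_
  out
}

#' Bland-Altman bias and limits of agreement
#'
#' Bias is `mean(test - retest)`; the limits of agreement are
#' `bias +/- 1.96 sd(differences)`. Supply pooled vectors across regions to
#' obtain the pooled-across-regions variant.
#'
#' @param test,retest paired outcome vectors (>= 2 pairs).
#' @return A list with `bias`, `sd_diff`, `loa` (lower, upper), `means`
#'   and `diffs` (per-pair plotting coordinates), and `n`.
#' @export
bland_altman <- function(test, retest) {
  if (length(test) != length(retest) || length(test) < 2L)
    stop("Bland-Altman requires >= 2 complete pairs")
  d <- test - retest
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd_diff = s, loa = c(bias - 1.96 * s, bias + 1.96 * s),
       means = (test + retest) / 2, diffs = d, n = length(d))
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of the paired differences. Zero differences
#' are dropped; the exact null distribution is used whenever there are no
#' tied absolute differences (otherwise the usual normal approximation with
#' continuity correction applies, flagged in the result).
#'
#' @param test,retest paired outcome vectors.
#' @return A list with `p_value`, `statistic` (V), `n_used` (nonzero
#'   differences), `exact` (logical), and `degenerate` (TRUE when all
#'   differences are zero; `p_value` is then `NA`).
#' @export
paired_wilcoxon <- function(test, retest) {
  d <- test - retest
  d <- d[d != 0]
  if (length(d) == 0L)
    return(list(p_value = NA_real_, statistic = NA_real_, n_used = 0L,
                exact = NA, degenerate = TRUE))
  ties <- any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = !ties, correct = TRUE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       n_used = length(d), exact = !ties, degenerate = FALSE)
}

#' Rank statistics: Spearman correlation and Kruskal-Wallis
#'
#' `rank_association` returns Spearman's rho with midranks for ties
#' (constant input yields an `NA` rho, flagged); `group_difference` is the
#' Kruskal-Wallis rank-sum test across groups.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return `rank_association`: list with `rho` and `p_value`.
#' @export
rank_association <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("rank_association requires >= 3 paired points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, constant_input = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       constant_input = FALSE)
}

#' @rdname rank_association
#' @param values numeric outcome vector.
#' @param groups group labels, same length as `values` (>= 2 groups).
#' @return `group_difference`: list with `statistic`, `df`, `p_value`.
#' @export
group_difference <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop("group_difference requires >= 2 groups")
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}
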
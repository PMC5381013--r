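#' Pearson correlation with test
#'
#' Thin wrapper around [stats::cor.test()] with the input checks the
#' pipeline relies on (paired, non-constant, length >= 3).
#'
#' @param x,y Paired numeric vectors.
#' @return List with `r`, `p`, `n`, `df`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       df = unname(ct$parameter))
}

#' Variance-ratio F-test on two standard deviations
#'
#' Compares two SDs via `F = (sd_a/sd_b)^2` referred to an F distribution
#' with `(n_a - 1, n_b - 1)` degrees of freedom.  The two-sided p-value is
#' `2 * min(upper tail, lower tail)`, capped at 1.  The groups are treated
#' as independent samples; for corrected-vs-uncorrected values measured on
#' the same subjects a paired alternative is available in
#' [pitman_morgan()].
#'
#' @param sd_a,sd_b Standard deviations (> 0).
#' @param n_a,n_b Sample sizes (>= 2).
#' @return A `t1_variance_comparison`: `sd_a`, `sd_b`, `n_a`, `n_b`,
#'   `f_statistic`, `df`, `p_two_sided`, and
#'   `percent_reduction = 100 * (1 - sd_b/sd_a)`.
#' @examples
#' f_test_sd(42.6, 200, 36.6, 200)$p_two_sided  # ~0.03
#' @export
f_test_sd <- function(sd_a, n_a, sd_b, n_b) {
  if (sd_a <= 0 || sd_b <= 0) stop("SDs must be > 0", call. = FALSE)
  if (n_a < 2 || n_b < 2) stop("need n >= 2 in both groups", call. = FALSE)
  f <- (sd_a / sd_b)^2
  upper <- stats::pf(f, n_a - 1, n_b - 1, lower.tail = FALSE)
  lower <- stats::pf(f, n_a - 1, n_b - 1, lower.tail = TRUE)
  out <- list(sd_a = sd_a, sd_b = sd_b, n_a = n_a, n_b = n_b,
              f_statistic = f, df = c(n_a - 1, n_b - 1),
              p_two_sided = min(1, 2 * min(upper, lower)),
              percent_reduction = 100 * (1 - sd_b / sd_a))
  class(out) <- "t1_variance_comparison"
  out
}

#' @export
print.t1_variance_comparison <- function(x, ...) {
  cat(sprintf("F-test of SDs: %.2f ms (n=%d) vs %.2f ms (n=%d)\n",
              x$sd_a, x$n_a, x$sd_b, x$n_b))
  cat(sprintf("  F = %.4f on (%d, %d) df, two-sided p = %s; SD reduction %.1f%%\n",
              x$f_statistic, x$df[1], x$df[2], format_p(x$p_two_sided),
              x$percent_reduction))
  invisible(x)
}

#' Pitman-Morgan paired variance test
#'
#' Opt-in paired alternative to [f_test_sd()] for variances measured on the
#' same subjects (e.g. corrected vs uncorrected T1): tests the correlation
#' between sums and differences of the pairs.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `t_statistic`, `df`, `p_two_sided`, `sd_x`, `sd_y`.
#' @export
pitman_morgan <- function(x, y) {
  if (length(x) != length(y))
    stop("paired test needs equal lengths", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  s <- x + y; d <- x - y
  if (stats::sd(s) == 0 || stats::sd(d) == 0)
    return(list(t_statistic = 0, df = n - 2, p_two_sided = 1,
                sd_x = stats::sd(x), sd_y = stats::sd(y)))
  r <- stats::cor(s, d)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(t_statistic = tstat, df = n - 2,
       p_two_sided = 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE),
       sd_x = stats::sd(x), sd_y = stats::sd(y))
}

#' Compare group means
#'
#' `mode = "unpaired"` uses the two-sample t-test (pooled variance by
#' default, Welch via `var_equal = FALSE`); `mode = "paired"` the
#' within-subject difference t-test; `mode = "mann_whitney"` the
#' Mann-Whitney U-test, computed exactly for small untied samples
#' (`n_a + n_b <= 20`) and by the tie-corrected normal approximation
#' otherwise.
#'
#' @param x,y Numeric vectors (equal length in paired mode).
#' @param mode One of `"unpaired"`, `"paired"`, `"mann_whitney"`.
#' @param var_equal Pooled (TRUE, default) or Welch (FALSE) unpaired t.
#' @return List with `statistic`, `p`, `df` (NA for Mann-Whitney),
#'   `method`, and group summaries `mean_x`, `mean_y`, `sd_x`, `sd_y`.
#' @export
compare_means <- function(x, y, mode = c("unpaired", "paired", "mann_whitney"),
                          var_equal = TRUE) {
  mode <- match.arg(mode)
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 observations per group", call. = FALSE)
  summ <- list(mean_x = mean(x), mean_y = mean(y),
               sd_x = stats::sd(x), sd_y = stats::sd(y))
  if (mode == "paired") {
    if (length(x) != length(y))
      stop("paired mode requires equal lengths", call. = FALSE)
    d <- x - y
    if (stats::sd(d) == 0) {
      # degenerate but well-defined: identical pairs give t = 0, p = 1
      res <- list(statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                  p = if (mean(d) == 0) 1 else 0,
                  df = length(d) - 1, method = "paired t")
      return(c(res, summ))
    }
    tt <- stats::t.test(x, y, paired = TRUE)
    return(c(list(statistic = unname(tt$statistic), p = tt$p.value,
                  df = unname(tt$parameter), method = "paired t"), summ))
  }
  if (mode == "unpaired") {
    tt <- stats::t.test(x, y, var.equal = var_equal)
    return(c(list(statistic = unname(tt$statistic), p = tt$p.value,
                  df = unname(tt$parameter),
                  method = if (var_equal) "pooled t" else "Welch t"), summ))
  }
  # Mann-Whitney
  exact <- (length(x) + length(y)) <= 20 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  c(list(statistic = unname(wt$statistic), p = wt$p.value, df = NA_real_,
         method = if (exact) "Mann-Whitney U (exact)"
                  else "Mann-Whitney U (normal approx.)"), summ)
}

#' Sample size for detecting a difference in means
#'
#' Normal-approximation per-group size for a two-sided two-sample
#' comparison: `n = 2 * (z_{1-alpha/2} + z_power)^2 * sd^2 / delta^2`,
#' rounded up.
#'
#' @param delta Detectable difference (ms).
#' @param sd Common SD (ms).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return A `t1_sample_size`: `delta`, `sd`, `alpha`, `power`,
#'   `n_per_group_exact` (unrounded), `n_per_group`, `n_total`.
#' @examples
#' sample_size_two_means(50, 45.2)$n_total  # 26
#' sample_size_two_means(50, 39.3)$n_total  # 20
#' @export
sample_size_two_means <- function(delta, sd, alpha = 0.05, power = 0.80) {
  if (delta <= 0 || sd <= 0) stop("`delta` and `sd` must be > 0",
                                  call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("`alpha` and `power` must lie in (0, 1)", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n_exact <- 2 * z^2 * sd^2 / delta^2
  n_per <- max(2L, as.integer(ceiling(n_exact)))
  out <- list(delta = delta, sd = sd, alpha = alpha, power = power,
              n_per_group_exact = n_exact, n_per_group = n_per,
              n_total = 2L * n_per)
  class(out) <- "t1_sample_size"
  out
}

#' @export
print.t1_sample_size <- function(x, ...) {
  cat(sprintf(
    "sample size: delta = %g ms, sd = %g ms, alpha = %g, power = %g -> %d per group (%d total)\n",
    x$delta, x$sd, x$alpha, x$power, x$n_per_group, x$n_total))
  invisible(x)
}

#' Compare extreme quartiles of a cohort
#'
#' Forms the bottom and top quartile subgroups of a stratifying variable
#' (25th/75th percentile cut points, linear interpolation between order
#' statistics) and compares a response between them with the unpaired
#' t-test.
#'
#' @param cohort A `t1_cohort` (>= 8 subjects).
#' @param stratify_by Column to stratify on, e.g. `"hematocrit"` or
#'   `"wall_thickness"`.
#' @param response Response values: either a column name (e.g. `"t1_myo"`)
#'   or a numeric vector of length `nrow(cohort)` (e.g. corrected T1).
#' @param var_equal Passed to [compare_means()].
#' @return List with `cut_points` (named: lower, upper), per-group `n`,
#'   `mean`, `sd`, and the unpaired-t `statistic` and `p`.
#' @export
quartile_compare <- function(cohort, stratify_by = "hematocrit",
                             response = "t1_myo", var_equal = TRUE) {
  if (nrow(cohort) < 8)
    stop("need at least 8 subjects for quartile comparison", call. = FALSE)
  s <- cohort[[stratify_by]]
  if (is.null(s)) stop("no such column: ", stratify_by, call. = FALSE)
  if (stats::sd(s) == 0)
    stop("stratifier `", stratify_by, "` is constant", call. = FALSE)
  y <- if (is.character(response) && length(response) == 1) {
    if (is.null(cohort[[response]]))
      stop("no such column: ", response, call. = FALSE)
    cohort[[response]]
  } else {
    if (length(response) != nrow(cohort))
      stop("`response` vector must match cohort size", call. = FALSE)
    as.numeric(response)
  }
  q <- stats::quantile(s, c(0.25, 0.75), type = 7, names = FALSE)
  lo <- y[s <= q[1]]
  hi <- y[s >= q[2]]
  cm <- compare_means(hi, lo, mode = "unpaired", var_equal = var_equal)
  list(cut_points = c(lower = q[1], upper = q[2]),
       n = c(bottom = length(lo), top = length(hi)),
       mean = c(bottom = mean(lo), top = mean(hi)),
       sd = c(bottom = stats::sd(lo), top = stats::sd(hi)),
       statistic = cm$statistic, p = cm$p)
}

#' Percent reduction in range
#'
#' `100 * (1 - (max(after) - min(after)) / (max(before) - min(before)))`.
#'
#' @param before,after Numeric vectors (before must not be constant).
#' @return Percent reduction (negative if the range widened).
#' @examples
#' range_reduction(c(908, 1183), c(941, 1146))  # ~25
#' @export
range_reduction <- function(before, after) {
  if (!length(before) || !length(after))
    stop("both inputs must be nonempty", call. = FALSE)
  rb <- diff(range(before))
  if (rb == 0) stop("`before` values are constant: range undefined",
                    call. = FALSE)
  100 * (1 - diff(range(after)) / rb)
}

# display convention: 2 significant figures below 0.1, else 2 decimals
format_p <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 0.001) return("<0.001")
  if (p < 0.1) return(formatC(signif(p, 2), format = "fg"))
  formatC(p, digits = 2, format = "f")
}
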
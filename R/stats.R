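# The inferential layer: independent two-sample t tests (pooled by
# default, Welch available), Pearson correlations with two-tailed p and a
# Fisher-transform 95% CI, and the pre/post delta-delta correlation. The
# pooled test is implemented from summary statistics so that printed
# group summaries (mean, SD, n) can be tested without raw data; raw
# samples are reduced to the same summaries first, making the two routes
# exactly equal.

summarize_sample <- function(x, name) {
  if (is.list(x)) {
    if (!all(c("mean", "sd", "n") %in% names(x)))
      stop_arg("summary input `%s` needs elements mean, sd, n", name)
    if (x$n < 2) stop_arg("`%s` must have n >= 2", name)
    return(list(mean = x$mean, sd = x$sd, n = x$n))
  }
  x <- as.numeric(x)
  if (length(x) < 2L) stop_arg("sample `%s` must have >= 2 values", name)
  if (!all(is.finite(x))) stop_data("sample `%s` contains non-finite values", name)
  list(mean = mean(x), sd = stats::sd(x), n = length(x))
}

#' Independent two-sample t test
#'
#' Student's pooled-variance t test (default) or Welch's test, two-tailed.
#' Samples may be given as raw numeric vectors or as summary lists
#' `list(mean=, sd=, n=)`; both routes give identical results.
#'
#' @param a,b Samples (numeric vectors or summary lists).
#' @param method `"pooled"` (Student, df = n1+n2-2) or `"welch"`.
#' @return An object of class `group_comparison` with the group summaries,
#'   `t`, `df` and two-tailed `p`.
#' @export
#' @examples
#' two_sample_t(list(mean = 33.22, sd = 9.87, n = 100),
#'              list(mean = 31.24, sd = 10.59, n = 100))
two_sample_t <- function(a, b, method = c("pooled", "welch")) {
  method <- match.arg(method)
  sa <- summarize_sample(a, "a")
  sb <- summarize_sample(b, "b")
  diff <- sa$mean - sb$mean
  if (method == "pooled") {
    df <- sa$n + sb$n - 2
    sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / df
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
  } else {
    va <- sa$sd^2 / sa$n
    vb <- sb$sd^2 / sb$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
  }
  if (se == 0) {
    if (diff == 0) {
      t_stat <- 0
    } else {
      stop_data("zero variance in both samples with unequal means")
    }
  } else {
    t_stat <- diff / se
  }
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(list(n = c(sa$n, sb$n), means = c(sa$mean, sb$mean),
                 sds = c(sa$sd, sb$sd), t = t_stat, df = df, p = p,
                 method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Two-sample t test (%s): t(%.4g) = %.3f, p = %.4g\n",
              x$method, x$df, x$t, x$p))
  cat(sprintf("  group 1: %.3f +/- %.3f (n = %d); group 2: %.3f +/- %.3f (n = %d)\n",
              x$means[1], x$sds[1], x$n[1], x$means[2], x$sds[2], x$n[2]))
  invisible(x)
}

#' Pearson correlation with two-tailed p and Fisher 95% CI
#'
#' r, the t-based two-tailed p (`t = r sqrt((n-2)/(1-r^2))`), and a 95%
#' confidence interval from `atanh(r) +/- 1.96 / sqrt(n - 3)`
#' back-transformed. At |r| = 1 the p value is reported as 0 (below the
#' machine floor).
#'
#' @param x,y Paired numeric vectors, n >= 3, both non-constant.
#' @return An object of class `correlation_result` with `n`, `r`, `p`,
#'   `ci` (length 2).
#' @export
pearson_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_arg("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop_arg("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_data("inputs contain non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_data("correlation undefined for constant input")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), n - 2)
  }
  ci <- if (n > 3) tanh(atanh(min(max(r, -1 + 1e-15), 1 - 1e-15)) +
                          c(-1, 1) * 1.96 / sqrt(n - 3))
        else c(-1, 1)
  structure(list(n = n, r = r, p = p, ci = ci),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.3f, p = %.4g, 95%% CI [%.3f, %.3f], n = %d\n",
              x$r, x$p, x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' Correlation between pre/post changes in FC and changes in FS14
#'
#' The delta-delta statistic: `pearson_test(post_fc - pre_fc,
#' fs14_post - fs14_pre)` over paired subjects.
#'
#' @param pre_fc,post_fc Per-subject FC scalars (e.g. masked means).
#' @param fs14_pre,fs14_post Per-subject fatigue scores.
#' @return A `correlation_result`.
#' @export
delta_correlation <- function(pre_fc, post_fc, fs14_pre, fs14_post) {
  ns <- c(length(pre_fc), length(post_fc), length(fs14_pre), length(fs14_post))
  if (length(unique(ns)) != 1L) stop_arg("all four vectors must be paired")
  pearson_test(as.numeric(post_fc) - as.numeric(pre_fc),
               as.numeric(fs14_post) - as.numeric(fs14_pre))
}
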
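#' Cohort-level hypothesis tests
#'
#' The three tests used to compare conventional and sMRI-modified plans,
#' implemented from closed forms so every statistic is verifiable by hand:
#' a one-sided paired t test (volume and recurrence-coverage comparisons),
#' a one-sided one-sample t test against a population mean of 1.0 (Dice
#' indices), and one-way ANOVA (target coverage, brainstem dose). The
#' direction of a one-sided test is always an explicit argument, never
#' inferred from the data. No multiple-testing correction is applied; this
#' is recorded in the result metadata.
#'
#' @param x,y Numeric vectors (paired, equal length for the paired test).
#' @param direction `"greater"` (mean difference / mean above the null),
#'   `"less"`, or `"two.sided"`.
#' @return A `smrirt_test` object with fields `statistic`, `df`, `p_value`,
#'   `method`, `alternative`, `n`, `estimate`. Use [generics::tidy()] /
#'   [generics::glance()] for tibble forms.
#' @name cohort_tests
NULL

new_test_result <- function(statistic, df, p_value, method, alternative,
                            n, estimate) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method, alternative = alternative, n = n,
                 estimate = estimate,
                 multiple_testing = "none"),
            class = "smrirt_test")
}

t_tail_p <- function(t, df, direction) {
  switch(direction,
         greater = stats::pt(t, df, lower.tail = FALSE),
         less = stats::pt(t, df, lower.tail = TRUE),
         two.sided = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' @rdname cohort_tests
#' @export
paired_t_one_sided <- function(x, y,
                               direction = c("greater", "less", "two.sided")) {
  direction <- match.arg(direction)
  if (length(x) != length(y)) stop("paired test requires equal lengths")
  n <- length(x)
  if (n < 2) stop("paired test requires n >= 2")
  d <- x - y
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd == 0)
    stop("zero-variance differences: paired t statistic is undefined")
  t <- mean(d) / (sdd / sqrt(n))
  new_test_result(t, n - 1, t_tail_p(t, n - 1, direction),
                  "paired t test", direction, n, mean(d))
}

#' @rdname cohort_tests
#' @param mu Null population mean (default 1.0, the perfect-overlap Dice
#'   reference).
#' @export
one_sample_t_vs_unity <- function(x, direction = c("less", "greater",
                                                   "two.sided"),
                                  mu = 1.0) {
  direction <- match.arg(direction)
  n <- length(x)
  if (n < 2) stop("one-sample test requires n >= 2")
  sdx <- stats::sd(x)
  if (!is.finite(sdx) || sdx == 0)
    stop("zero variance: one-sample t statistic is undefined")
  t <- (mean(x) - mu) / (sdx / sqrt(n))
  new_test_result(t, n - 1, t_tail_p(t, n - 1, direction),
                  sprintf("one-sample t test vs %g", mu), direction, n,
                  mean(x))
}

#' @rdname cohort_tests
#' @param groups A list of numeric vectors, one per group (>= 2 groups,
#'   each with n >= 2).
#' @export
one_way_anova <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("ANOVA requires at least 2 groups")
  ns <- vapply(groups, length, 1L)
  if (any(ns < 2)) stop("every group needs n >= 2")
  N <- sum(ns)
  means <- vapply(groups, mean, 1.0)
  grand <- sum(ns * means) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1.0))
  if (ss_within == 0)
    stop("zero within-group variance: F statistic is undefined")
  ms_between <- ss_between / (k - 1)
  ms_within <- ss_within / (N - k)
  f <- ms_between / ms_within
  p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  new_test_result(f, c(k - 1, N - k), p, "one-way ANOVA", "two.sided", N,
                  grand)
}

#' @export
print.smrirt_test <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.4f, df = %s, p = %.4g, n = %d\n",
              x$method, x$alternative, x$statistic,
              paste(x$df, collapse = ", "), x$p_value, x$n))
  invisible(x)
}

#' Tidy a test result
#'
#' @param x A `smrirt_test`.
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `df1`, `df2`, `p.value`,
#'   `estimate`, `method`, `alternative`, `n`.
#' @export
tidy.smrirt_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    df1 = x$df[1],
    df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
    p.value = x$p_value,
    estimate = x$estimate,
    method = x$method,
    alternative = x$alternative,
    n = x$n
  )
}

#' @rdname tidy.smrirt_test
#' @export
glance.smrirt_test <- function(x, ...) tidy.smrirt_test(x, ...)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
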
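# Pooled-variance t-test and coefficient of variation, the two remaining
# summary statistics of the study's reporting conventions.

#' Unpaired Student's t-test (pooled variance)
#'
#' Classic two-sample t with the pooled variance estimate and
#' `df = n1 + n2 - 2`, two-sided. This is the parametric comparison used for
#' group means (spine densities, exploration times); it is deliberately the
#' pooled variant, not Welch's.
#'
#' @param a,b numeric samples with at least 2 values each.
#' @return `t_test_result`: `mean_a`, `mean_b`, `t`, `df`, `p`.
#' @examples
#' t_test_two_sample(c(1, 2, 3), c(4, 5, 6))
#' @export
t_test_two_sample <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop_invalid("t_test_two_sample(): need at least 2 values per group")
  }
  if (anyNA(a) || anyNA(b)) stop_invalid("t_test_two_sample(): NA values not allowed")
  n1 <- length(a); n2 <- length(b)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  if (sp2 <= 0) stop_invalid("t_test_two_sample(): zero pooled variance")
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(
    list(mean_a = mean(a), mean_b = mean(b), t = tstat, df = df, p = p),
    class = "t_test_result"
  )
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("Pooled t-test: t = %.4g, df = %d, p = %.3g (means %.4g vs %.4g)\n",
              x$t, x$df, x$p, x$mean_a, x$mean_b))
  invisible(x)
}

#' Coefficient of variation in percent
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation; the precision
#' measure used for replicate LC-MS quantifications.
#'
#' @param values numeric vector, n >= 2, nonzero mean.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(9, 10, 11))  # 10
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop_invalid("coefficient_of_variation(): need n >= 2")
  m <- mean(values)
  if (m == 0) stop_invalid("coefficient_of_variation(): zero mean")
  100 * stats::sd(values) / m
}
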
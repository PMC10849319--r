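#' Regression through the origin
#'
#' Least-squares fit of `y = slope * x` with the intercept fixed at zero,
#' the standard way of comparing per-population X-chromosomal sharing
#' proportions to autosomal ones (a population with no sharing on the
#' autosomes is expected to have none on the X). The slope is
#' `sum(x * y) / sum(x^2)`; the coefficient of determination is the
#' uncentered `R^2 = 1 - RSS / sum(y^2)`; the p-value is the two-sided t
#' test of zero slope on `n - 1` degrees of freedom. These are exactly the
#' no-intercept outputs of [stats::lm()], which does the fitting.
#'
#' @param x,y Equal-length numeric vectors (at least two points; `x` not
#'   identically zero).
#' @param conf_level Confidence level for the slope interval (default 0.95).
#' @return List with `slope`, `se`, `r_squared`, `p_value`, `df`, and
#'   `conf_int` (two-sided confidence interval for the slope).
#' @examples
#' zero_intercept_regression(1:5, 2 * (1:5))$slope # exactly 2
#' @export
zero_intercept_regression <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  if (length(x) < 2) stop("need at least two points", call. = FALSE)
  if (all(x == 0)) stop("`x` is identically zero; slope undefined",
                        call. = FALSE)
  fit <- lm(y ~ x + 0)
  s <- summary(fit)
  slope <- unname(coef(fit)[1])
  se <- s$coefficients[1, 2]
  df <- fit$df.residual
  tq <- qt(1 - (1 - conf_level) / 2, df)
  list(slope = slope,
       se = se,
       r_squared = s$r.squared,
       p_value = s$coefficients[1, 4],
       df = df,
       conf_int = c(slope - tq * se, slope + tq * se))
}
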
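#' Linear width trend with significance test
#'
#' Ordinary least squares of width on calendar year (years may be unevenly
#' spaced; the regressor is real time, so the slope is in metres per year)
#' with the classical two-sided t test of the slope. Series whose p-value
#' exceeds `alpha` are deemed to have no linear trend. The reported total
#' change is the endpoint difference (last minus first observed width), and
#' the annual percent rate divides it by the initial width and the span; the
#' fitted-line change (`slope * span`) is also exposed.
#'
#' @param series data.frame with columns `year` and `amw_m` (>= 3 distinct
#'   years, strictly increasing).
#' @param alpha significance level for the slope test.
#' @return list of class `trend_result`: `slope` (m/yr), `slope_se`,
#'   `intercept`, `p_value`, `significant`, `total_change` (m, endpoint
#'   difference), `fitted_change` (m, slope x span), `percent_rate` (%/yr),
#'   `n`, `span`.
#' @export
fit_width_trend <- function(series, alpha = 0.05) {
  if (!all(c("year", "amw_m") %in% names(series)))
    stop("series must have columns year, amw_m")
  series <- series[order(series$year), , drop = FALSE]
  yrs <- series$year
  if (length(unique(yrs)) < 3L)
    stop("insufficient-data error: need >= 3 distinct years")
  if (any(diff(yrs) <= 0))
    stop("insufficient-data error: years must be strictly increasing")
  fit <- stats::lm(amw_m ~ year, data = series)
  sm <- suppressWarnings(summary(fit))$coefficients
  p <- sm["year", "Pr(>|t|)"]
  if (is.nan(p)) {
    # exactly collinear series: zero residual variance
    p <- if (abs(stats::coef(fit)["year"]) > 0) 0 else 1
  }
  span <- yrs[length(yrs)] - yrs[1]
  total <- series$amw_m[length(yrs)] - series$amw_m[1]
  structure(list(
    slope = unname(stats::coef(fit)["year"]),
    slope_se = unname(sm["year", "Std. Error"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    p_value = unname(p),
    significant = p < alpha,
    total_change = total,
    fitted_change = unname(stats::coef(fit)["year"]) * span,
    percent_rate = annual_percent_rate(series$amw_m[1], total, span),
    n = length(yrs), span = span
  ), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "trend: slope %.3f m/yr (p = %.4g%s), change %.2f m over %d yr (%.3f %%/yr)\n",
    x$slope, x$p_value, if (x$significant) ", significant" else "",
    x$total_change, x$span, x$percent_rate))
  invisible(x)
}

#' Annual percent change rate
#'
#' `(total_change / initial) / span * 100`, percent per year relative to the
#' initial value.
#'
#' @param initial initial width (m), > 0.
#' @param total_change change over the span (m).
#' @param span_years span in years, > 0.
#' @return percent per year.
#' @export
annual_percent_rate <- function(initial, total_change, span_years) {
  if (any(initial <= 0)) stop("domain error: initial value must be > 0")
  if (any(span_years <= 0)) stop("domain error: span must be > 0")
  (total_change / initial) / span_years * 100
}

#' Single-factor dynamic change rate
#'
#' `K = (Ub - Ua) / Ua * (1 / T) * 100`, the annual percent change of any
#' attribute (width, index, ...) between two epochs.
#'
#' @param ua,ub attribute value at the initial and final epoch (`ua` > 0).
#' @param span_years duration `T` between epochs, > 0.
#' @return `K` in percent per year.
#' @export
dynamic_change <- function(ua, ub, span_years) {
  if (any(ua <= 0)) stop("domain error: initial value must be > 0")
  if (any(span_years <= 0)) stop("domain error: span must be > 0")
  (ub - ua) / ua / span_years * 100
}
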
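# Present-value valuation of income streams.
#
# Real (inflation-free) incomes grow at g per year and are discounted at r,
# i.e. a payment t years after the base year is scaled by the net factor
# ((1+g)/(1+r))^t. Growth is applied to the real stream and discounting to
# the grown stream; the base year has exponent 0 (end-of-period convention).
# Present values are finally inflated to reporting-year dollars with a
# single CPI factor.

#' Present value of an annual income stream
#'
#' `PV = sum_t stream(t) * (1+g)^(t - base) / (1+r)^(t - base)`, with `g` the
#' wage growth rate and `r` the discount rate. With `g == r` the PV equals
#' the plain sum of the real stream.
#'
#' @param stream named numeric vector (names = calendar years), or a
#'   two-column data frame `year`, `income`.
#' @param params [economic_params()].
#' @return present value at the base year, in the stream's currency.
#' @export
#' @examples
#' p <- economic_params(wage_growth = 0.01, discount_rate = 0.03, base_year = 2003)
#' present_value(c("2003" = 100, "2004" = 100, "2005" = 100), p)  # 294.2125
present_value <- function(stream, params = economic_params()) {
  if (is.data.frame(stream)) {
    years <- stream$year
    values <- stream$income
  } else {
    years <- as.numeric(names(stream))
    values <- as.numeric(stream)
  }
  if (length(values) == 0) return(0)
  if (anyNA(years)) config_error("income stream must be keyed by calendar year")
  if (any(years < params$base_year)) {
    config_error("income stream contains years before the base year")
  }
  t <- years - params$base_year
  sum(values * ((1 + params$wage_growth) / (1 + params$discount_rate))^t)
}

#' Inflate a base-year value to reporting-year dollars
#'
#' @param value currency amount at base-year prices.
#' @param cpi_factor positive CPI multiplier (e.g. the consumer price index
#'   ratio between the reporting year and the income base year).
#' @return `value * cpi_factor`.
#' @export
inflate_to_reporting <- function(value, cpi_factor) {
  if (!is.numeric(cpi_factor) || any(cpi_factor <= 0)) {
    config_error("cpi_factor must be positive")
  }
  value * cpi_factor
}
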
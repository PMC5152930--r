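# Counterfactual life-course accumulation.
#
# Given a decedent and the matched panel trajectory, three outcome streams
# are accumulated from the death year to the projection horizon: years of
# life lost (to the matched person's simulated death or the horizon),
# full-time-equivalent working years (accumulated weekly hours divided by the
# standard working year), and the annual real income stream that feeds the
# present-value calculation.
#
# Conventions (documented, configurable where meaningful): the death year
# itself contributes a full counterfactual year of potential work and income
# (matching happens at the start of the year); the counterfactual death year
# contributes nothing (death at the start of that year).

#' Economic parameters of the costing
#'
#' @param wage_growth annual real income growth applied in valuation
#'   (default 0.01, i.e. 1% above inflation).
#' @param discount_rate annual discount rate (default 0.03).
#' @param base_year present-value base year (default 2003, the mortality
#'   year).
#' @param horizon last projected calendar year (default 2030).
#' @param standard_annual_hours hours in a standard full-time working year
#'   (default 1976 = 38 h/week x 52 weeks).
#' @param weeks_per_year weeks worked per year used to annualise weekly hours
#'   (default 52).
#' @param cpi_factor multiplier taking base-year dollars to reporting-year
#'   dollars (default 1; supply the CPI ratio for a different reporting
#'   year).
#' @return object of class `economic_params`.
#' @export
economic_params <- function(wage_growth = 0.01,
                            discount_rate = 0.03,
                            base_year = 2003,
                            horizon = 2030,
                            standard_annual_hours = 1976,
                            weeks_per_year = 52,
                            cpi_factor = 1) {
  if (discount_rate <= -1 || wage_growth <= -1) {
    config_error("rates must exceed -100%")
  }
  if (standard_annual_hours <= 0) config_error("standard_annual_hours must be positive")
  if (horizon < base_year) config_error("horizon must be >= base_year")
  if (cpi_factor <= 0) config_error("cpi_factor must be positive")
  structure(
    list(wage_growth = wage_growth, discount_rate = discount_rate,
         base_year = as.integer(base_year), horizon = as.integer(horizon),
         standard_annual_hours = standard_annual_hours,
         weeks_per_year = weeks_per_year, cpi_factor = cpi_factor),
    class = "economic_params"
  )
}

# First year in which a trajectory's alive flag is 0 (Inf if none): the
# counterfactual death year.
cf_death_year <- function(traj) {
  dead <- traj$year[traj$alive == 0]
  if (length(dead)) min(dead) else Inf
}

#' Counterfactual years of life lost for one decedent
#'
#' YLL = min(counterfactual death year, horizon) - death year, where the
#' counterfactual death year is the first year the matched trajectory's
#' alive flag is false; survivors to the horizon contribute
#' horizon - death year.
#'
#' @param death_year calendar year of the actual death.
#' @param traj one person's trajectory (rows of the panel tibble).
#' @param horizon last projected year.
#' @return years of life lost (nonnegative).
#' @export
counterfactual_yll <- function(death_year, traj, horizon) {
  if (!death_year %in% traj$year) {
    data_error("matched trajectory does not cover the death year")
  }
  max(0, min(cf_death_year(traj), horizon) - death_year)
}

#' Full-time-equivalent working years over an interval
#'
#' Accumulated weekly hours x weeks per year / standard annual hours, over
#' the years from `from_year` to the earlier of the year before the
#' counterfactual death and the horizon.
#'
#' @inheritParams counterfactual_yll
#' @param from_year first counted year (the death year).
#' @param params [economic_params()] supplying `standard_annual_hours` and
#'   `weeks_per_year`.
#' @return FTE working years.
#' @export
working_years <- function(traj, from_year, horizon, params = economic_params()) {
  last <- min(cf_death_year(traj) - 1, horizon)
  sel <- traj$year >= from_year & traj$year <= last
  sum(traj$weekly_hours[sel]) * params$weeks_per_year / params$standard_annual_hours
}

#' Annual real income stream of a counterfactual lifespan
#'
#' Yearly real incomes from `from_year` to the horizon, zero in and after the
#' counterfactual death year.
#'
#' @inheritParams working_years
#' @return named numeric vector (names = calendar years).
#' @export
income_stream <- function(traj, from_year, horizon) {
  sel <- traj$year >= from_year & traj$year <= horizon
  y <- traj$year[sel]
  inc <- traj$annual_income_real[sel]
  inc[y >= cf_death_year(traj)] <- 0
  setNames(inc, y)[order(y)]
}

#' Accumulate outcomes for all decedents and replicates
#'
#' Vectorised equivalent of applying [counterfactual_yll()],
#' [working_years()], [income_stream()] and [present_value()] to every
#' matched pair in every replicate. All decedents must share one death year
#' (the design analyses a single mortality year), which is also taken as the
#' accumulation start.
#'
#' @param deaths premature cancer death records.
#' @param panel long person-year tibble covering death year to horizon.
#' @param assignments list of [match_replicate()] results.
#' @param params [economic_params()].
#' @return tibble with one row per (replicate, decedent): `replicate`,
#'   `death_id`, `site`, `age_band`, `sex`, `ses_quintile`, `yll`,
#'   `working_years`, `pvli` (present value at the base year, uninflated).
#' @export
accumulate_outcomes <- function(deaths, panel, assignments, params = economic_params()) {
  if (length(unique(deaths$year)) > 1) {
    data_error("all deaths must share one mortality year")
  }
  from_year <- deaths$year[1]
  if (from_year < params$base_year) {
    config_error("death year precedes the present-value base year")
  }

  # Per-person summaries over [from_year, horizon]; panel hours/income are 0
  # in and after the simulated death year by construction.
  sub <- panel[panel$year >= from_year & panel$year <= params$horizon, , drop = FALSE]
  f <- (1 + params$wage_growth) / (1 + params$discount_rate)
  disc <- f^(sub$year - params$base_year)
  first_dead <- tapply(ifelse(sub$alive == 0, sub$year, Inf), sub$person_id, min)
  wy <- tapply(sub$weekly_hours, sub$person_id,
               sum) * params$weeks_per_year / params$standard_annual_hours
  pv <- tapply(sub$annual_income_real * disc, sub$person_id, sum)

  per_person <- tibble::tibble(
    person_id = names(wy),
    cf_year = as.numeric(first_dead[names(wy)]),
    wy = as.numeric(wy),
    pv = as.numeric(pv)
  )

  meta <- tibble::tibble(
    death_id = deaths$id,
    site = deaths$site,
    age_band = reporting_age_band_of(deaths$age),
    sex = deaths$sex,
    ses_quintile = deaths$ses_quintile
  )

  out <- lapply(assignments, function(a) {
    idx <- match(a$pairs$person_id, per_person$person_id)
    if (anyNA(idx)) data_error("assignment references persons absent from the panel")
    tibble::tibble(
      replicate = a$replicate_index,
      meta[match(a$pairs$death_id, meta$death_id), ],
      yll = pmax(0, pmin(per_person$cf_year[idx], params$horizon) - from_year),
      working_years = per_person$wy[idx],
      pvli = per_person$pv[idx]
    )
  })
  dplyr::bind_rows(out)
}
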
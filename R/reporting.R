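# Replicate aggregation and report rendering.
#
# Aggregation order is fixed: outcomes are summed within each replicate and
# stratum first, then summarised across replicates as the mean with a
# percentile confidence interval (2.5th/97.5th percentile at the default 95%
# level, linear-interpolation convention, stats::quantile type 7). Display
# rounding is half-up and applied only when rendering; all internals stay
# unrounded.

#' @importFrom dplyr group_by summarise across all_of bind_rows n %>%
NULL

#' Percentile confidence interval across replicates
#'
#' @param x numeric vector of replicate-level statistics.
#' @param level confidence level in percent (default 95).
#' @return named vector `ci_low`, `ci_high`: the (100-level)/2 and
#'   100-(100-level)/2 percentiles, linear interpolation (type 7).
#' @export
percentile_ci <- function(x, level = 95) {
  if (level <= 0 || level >= 100) config_error("ci level must be in (0, 100)")
  alpha <- (100 - level) / 200
  q <- quantile(x, c(alpha, 1 - alpha), type = 7, names = FALSE)
  c(ci_low = q[1], ci_high = q[2])
}

#' Aggregate per-person outcomes across replicates
#'
#' For each stratum the replicate-level total of each outcome (deaths, YLL,
#' working years, PVLI) is computed first; the mean and the percentile
#' interval are then taken across replicates. PVLI is inflated to
#' reporting-year dollars with `params$cpi_factor`.
#'
#' @param outcomes tibble from [accumulate_outcomes()].
#' @param by character vector of stratum columns (any of `"age_band"`,
#'   `"sex"`, `"site"`, `"ses_quintile"`); empty for the grand total.
#' @param params [economic_params()] (for the CPI factor).
#' @param level confidence level in percent.
#' @return tibble with the stratum columns plus `measure` (`deaths`, `yll`,
#'   `working_years`, `pvli`), `mean`, `ci_low`, `ci_high`, `n_replicates`.
#' @export
aggregate_outcomes <- function(outcomes, by = character(), params = economic_params(),
                               level = 95) {
  bad <- setdiff(by, c("age_band", "sex", "site", "ses_quintile"))
  if (length(bad)) {
    config_error(paste("unknown stratum key(s):", paste(bad, collapse = ", ")))
  }
  if (nrow(outcomes) == 0) {
    return(tibble::tibble(measure = character(), mean = numeric(),
                          ci_low = numeric(), ci_high = numeric(),
                          n_replicates = integer()))
  }
  rep_totals <- outcomes %>%
    group_by(across(all_of(c(by, "replicate")))) %>%
    summarise(
      deaths = dplyr::n(),
      yll = sum(.data$yll),
      working_years = sum(.data$working_years),
      pvli = sum(.data$pvli) * params$cpi_factor,
      .groups = "drop"
    )
  # A stratum absent from some replicate contributes zero there.
  if (length(by)) {
    rep_totals <- tidyr::complete(
      rep_totals,
      !!!rlang_syms(by), .data$replicate,
      fill = list(deaths = 0L, yll = 0, working_years = 0, pvli = 0)
    )
  }
  long <- tidyr::pivot_longer(rep_totals, c("deaths", "yll", "working_years", "pvli"),
                              names_to = "measure", values_to = "value")
  long %>%
    group_by(across(all_of(c(by, "measure")))) %>%
    summarise(
      mean = mean(.data$value),
      ci_low = percentile_ci(.data$value, level)[["ci_low"]],
      ci_high = percentile_ci(.data$value, level)[["ci_high"]],
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}

# tidyr::complete needs symbols; avoid importing rlang wholesale.
rlang_syms <- function(chr) lapply(chr, as.symbol)

#' Share of a total, in percent
#'
#' Returns the unrounded percentage; round for display with
#' [round_half_up()].
#'
#' @param part,total nonnegative quantities; `total` must be positive.
#' @return `100 * part / total`.
#' @export
#' @examples
#' share_of_total(15051, 25733)  # 58.49...
share_of_total <- function(part, total) {
  if (any(total <= 0)) data_error("share_of_total requires a positive total")
  100 * part / total
}

#' Average cost per death
#'
#' @param total_pvli total PVLI for the stratum.
#' @param n_deaths number of deaths in the stratum (> 0).
#' @param scale divisor converting to the display unit (e.g. input in
#'   $ millions with `scale = 1e-3` reports thousands of dollars per death).
#' @return `total_pvli / n_deaths / scale`.
#' @export
#' @examples
#' per_death_cost(4200, 25733, scale = 1e-3)  # ~163 ($000 per death)
per_death_cost <- function(total_pvli, n_deaths, scale = 1) {
  if (any(n_deaths <= 0)) data_error("per_death_cost requires n_deaths > 0")
  total_pvli / n_deaths / scale
}

#' Savings from a sustained proportional mortality reduction
#'
#' A sustained reduction of a site's mortality by fraction `p` saves
#' `p x site_total_pvli` per annum; because each year adds a new persisting
#' annual stream, savings over `T` years compound to
#' `annual x T(T+1)/2`.
#'
#' @param site_total_pvli the site's total PVLI loss (any currency unit).
#' @param reduction fraction in `[0, 1]`.
#' @param horizon_years number of years `T` over which savings accumulate.
#' @return list with `annual` and `cumulative` savings in the input unit.
#' @export
#' @examples
#' scenario_savings(765, 0.02, 10)  # annual 15.3, cumulative 841.5 ($M)
scenario_savings <- function(site_total_pvli, reduction, horizon_years = 10) {
  if (reduction < 0 || reduction > 1) config_error("reduction must be in [0, 1]")
  if (horizon_years < 0) config_error("horizon_years must be >= 0")
  annual <- reduction * site_total_pvli
  list(annual = annual,
       cumulative = annual * horizon_years * (horizon_years + 1) / 2)
}

#' Render stratified report tables to CSV
#'
#' Writes three tables -- deaths and YLL by age band and sex, PVLI by age
#' band and sex with percent of total, and the site-level table with working
#' years, PVLI, percent of total, deaths and per-death cost -- each preceded
#' by `#` metadata lines recording economic parameters, seeds and fallback
#' counts. Rounding is display-only: percentages to integers (half-up), PVLI
#' to whole millions, per-death cost to whole thousands. Re-running on the
#' same inputs gives byte-identical files.
#'
#' @param result a `prodloss_run` from [run_analysis()].
#' @param dir output directory (created if needed).
#' @param currency_scale divisor taking PVLI to display millions (default
#'   1e6: outcomes in dollars, tables in $ millions).
#' @return invisibly, the paths written.
#' @export
render_tables <- function(result, dir, currency_scale = 1e6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  outcomes <- result$outcomes
  params <- result$params
  empty <- nrow(outcomes) == 0
  if (empty) {
    warning("empty outcome set: rendering tables of zeros")
  }
  meta <- c(
    sprintf("# wage_growth: %g", params$wage_growth),
    sprintf("# discount_rate: %g", params$discount_rate),
    sprintf("# base_year: %d", params$base_year),
    sprintf("# horizon: %d", params$horizon),
    sprintf("# standard_annual_hours: %g", params$standard_annual_hours),
    sprintf("# weeks_per_year: %g", params$weeks_per_year),
    sprintf("# cpi_factor: %g", params$cpi_factor),
    sprintf("# n_replicates: %d", length(result$assignments)),
    sprintf("# base_seed: %d", result$base_seed),
    sprintf("# fallback_matches: %d",
            sum(vapply(result$assignments, function(a) nrow(a$fallback_log), 1L)))
  )
  write_with_meta <- function(df, file) {
    path <- file.path(dir, file)
    con <- file(path, "w")
    writeLines(meta, con)
    write.csv(df, con, row.names = FALSE, quote = FALSE)
    close(con)
    path
  }

  if (empty) {
    zero <- function(cols) {
      as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    }
    p1 <- write_with_meta(zero(c("age_band", "sex", "deaths", "yll")),
                          "deaths_yll_by_age_sex.csv")
    p2 <- write_with_meta(zero(c("age_band", "sex", "pvli_m", "pct_of_total")),
                          "pvli_by_age_sex.csv")
    p3 <- write_with_meta(
      zero(c("site", "working_years", "pvli_m", "pct_of_total_pvli",
             "deaths", "pvli_per_death_000")),
      "pvli_by_site.csv"
    )
    return(invisible(c(p1, p2, p3)))
  }

  agg_as <- aggregate_outcomes(outcomes, c("age_band", "sex"), params)
  t_deaths <- tidyr::pivot_wider(
    agg_as[agg_as$measure %in% c("deaths", "yll"), ],
    id_cols = c("age_band", "sex"), names_from = "measure",
    values_from = c("mean", "ci_low", "ci_high")
  )
  p1 <- write_with_meta(rounded_cols(t_deaths), "deaths_yll_by_age_sex.csv")

  pv <- agg_as[agg_as$measure == "pvli", ]
  total_pv <- sum(pv$mean)
  t_pvli <- tibble::tibble(
    age_band = pv$age_band, sex = pv$sex,
    pvli_m = round_half_up(pv$mean / currency_scale),
    ci_low_m = round_half_up(pv$ci_low / currency_scale),
    ci_high_m = round_half_up(pv$ci_high / currency_scale),
    pct_of_total = if (total_pv > 0) {
      round_half_up(share_of_total(pv$mean, total_pv))
    } else {
      rep(0, nrow(pv))
    }
  )
  p2 <- write_with_meta(t_pvli, "pvli_by_age_sex.csv")

  agg_site <- aggregate_outcomes(outcomes, "site", params)
  t_site <- tidyr::pivot_wider(agg_site, id_cols = "site",
                               names_from = "measure", values_from = "mean")
  if (nrow(t_site)) {
    t_site <- tibble::tibble(
      site = t_site$site,
      working_years = round_half_up(t_site$working_years),
      pvli_m = round_half_up(t_site$pvli / currency_scale),
      pct_of_total_pvli = if (sum(t_site$pvli) > 0) {
        round_half_up(share_of_total(t_site$pvli, sum(t_site$pvli)))
      } else {
        rep(0, nrow(t_site))
      },
      deaths = round_half_up(t_site$deaths),
      pvli_per_death_000 = round_half_up(
        per_death_cost(t_site$pvli, pmax(t_site$deaths, 1), scale = 1000)
      )
    )
  }
  p3 <- write_with_meta(t_site, "pvli_by_site.csv")

  invisible(c(p1, p2, p3))
}

rounded_cols <- function(df) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round_half_up)
  df
}
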
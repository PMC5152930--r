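# Shared fixtures: tiny hand-built trajectories and small generator specs.

# One person's trajectory with given survival/hours/income vectors.
make_traj <- function(years, alive, hours = rep(0, length(years)),
                      income = rep(0, length(years)), person_id = "P1") {
  tibble::tibble(
    person_id = person_id, year = years, age = years - min(years) + 30L,
    sex = "M", ses_quintile = 3L, alive = as.integer(alive),
    weekly_hours = hours, annual_income_real = income
  )
}

# A panel in which every exact matching cell is populated: one person per
# (starting age 0..79, sex, SES quintile) combination, survival fixed,
# constant hours/income.
make_dense_panel <- function(start = 2003, end = 2030,
                             hours = 38, income = 50000) {
  years <- start:end
  combos <- expand.grid(age0 = 0:79, sex = c("M", "F"), ses = 1:5,
                        stringsAsFactors = FALSE)
  grid <- tibble::tibble(
    person_id = sprintf("P%06d", seq_len(nrow(combos))),
    age0 = combos$age0,
    sex = combos$sex,
    ses = combos$ses
  )
  long <- tidyr::crossing(grid, year = years)
  tibble::tibble(
    person_id = long$person_id,
    year = long$year,
    age = as.integer(long$age0 + (long$year - start)),
    sex = long$sex,
    ses_quintile = as.integer(long$ses),
    alive = 1L,
    weekly_hours = hours,
    annual_income_real = income
  )
}

# Deaths spread over all cells.
make_deaths <- function(n = 50, year = 2003, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    id = sprintf("D%04d", seq_len(n)),
    year = year,
    age = sample(0:79, n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE),
    ses_quintile = sample(1:5, n, replace = TRUE),
    icd10 = sample(c("C34", "C18", "C50", "C61", "C71"), n, replace = TRUE)
  )) |>
    (\(d) {
      d$site <- classify_site(d$icd10)
      d
    })()
}
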
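# Synthetic mortality dataset generator.
#
# Emulates an individual-level national mortality registry extract: one row
# per death with year, age, sex, area-based socioeconomic quintile and the
# ICD-10 underlying cause. Default marginals reproduce the Australian 2003
# premature-cancer-death distribution by age band, sex and site.

#' Specify a synthetic mortality dataset
#'
#' @param n_deaths number of death records to generate.
#' @param year calendar year of death stamped on every record.
#' @param age_sex_weights tibble with columns `age_band`, `lo`, `hi`, `sex`,
#'   `weight`: a probability table over (age band x sex) cells, summing to 1.
#'   Default: proportional to the Australian 2003 premature cancer death
#'   counts ([aus_cancer_deaths_2003()]).
#' @param site_weights tibble with columns `site`, `weight` over the labels of
#'   `site_map`; default proportional to the 2003 site death counts.
#' @param ses_distribution probabilities over socioeconomic quintiles 1-5
#'   (default uniform: the quintiles are population fifths by construction).
#' @param site_map site map used to attach a concrete ICD-10 category to each
#'   sampled site.
#' @param seed integer seed; generation is fully deterministic given the spec.
#' @return an object of class `mortality_spec`.
#' @export
mortality_spec <- function(n_deaths = 25733,
                           year = 2003,
                           age_sex_weights = NULL,
                           site_weights = NULL,
                           ses_distribution = rep(0.2, 5),
                           site_map = default_site_map(),
                           seed = 1L) {
  if (is.null(age_sex_weights)) {
    ref <- aus_cancer_deaths_2003()
    bands <- reporting_age_bands()
    age_sex_weights <- tibble::tibble(
      age_band = as.character(ref$age_band),
      lo = bands$lo[match(as.character(ref$age_band), bands$label)],
      hi = bands$hi[match(as.character(ref$age_band), bands$label)],
      sex = ref$sex,
      weight = ref$deaths / sum(ref$deaths)
    )
  }
  if (is.null(site_weights)) {
    ref <- aus_cancer_sites_2003()
    site_weights <- tibble::tibble(site = ref$site, weight = ref$deaths / sum(ref$deaths))
  }
  if (!is.numeric(n_deaths) || length(n_deaths) != 1 || n_deaths < 0) {
    config_error("n_deaths must be a single nonnegative count")
  }
  check_prob_table(age_sex_weights$weight, "age_sex_weights")
  check_prob_table(site_weights$weight, "site_weights")
  check_prob_table(ses_distribution, "ses_distribution")
  if (length(ses_distribution) != 5) {
    config_error("ses_distribution must have 5 quintile probabilities")
  }
  known <- site_labels(site_map)
  if (!all(site_weights$site %in% known)) {
    config_error("site_weights contains labels absent from the site map")
  }
  structure(
    list(
      n_deaths = as.integer(n_deaths), year = as.integer(year),
      age_sex_weights = age_sex_weights, site_weights = site_weights,
      ses_distribution = ses_distribution, site_map = validate_if_needed(site_map),
      seed = as.integer(seed)
    ),
    class = "mortality_spec"
  )
}

#' Generate a synthetic mortality dataset
#'
#' Samples (age band x sex) cells multinomially from the spec's weight table,
#' draws an integer age uniformly within the band, a socioeconomic quintile,
#' a cancer site, and a concrete ICD-10 category uniformly from the site's
#' code ranges. Identical spec (including seed) gives identical output.
#'
#' @param spec a [mortality_spec()].
#' @return tibble of death records: `id`, `year`, `age`, `sex`,
#'   `ses_quintile`, `icd10`, `site`.
#' @export
generate_mortality_dataset <- function(spec) {
  stopifnot(inherits(spec, "mortality_spec"))
  n <- spec$n_deaths
  w <- spec$age_sex_weights
  empty <- tibble::tibble(
    id = character(), year = integer(), age = integer(), sex = character(),
    ses_quintile = integer(), icd10 = character(), site = character()
  )
  if (n == 0L) return(empty)
  cats_by_site <- site_categories(spec$site_map)
  with_seed(spec$seed, {
    cell <- sample.int(nrow(w), n, replace = TRUE, prob = w$weight)
    age <- w$lo[cell] + floor(runif(n) * (w$hi[cell] - w$lo[cell] + 1L))
    ses <- sample.int(5L, n, replace = TRUE, prob = spec$ses_distribution)
    site <- spec$site_weights$site[
      sample.int(nrow(spec$site_weights), n, replace = TRUE, prob = spec$site_weights$weight)
    ]
    icd10 <- vapply(cats_by_site[site], function(codes) {
      codes[sample.int(length(codes), 1L)]
    }, "")
    tibble::tibble(
      id = sprintf("D%06d", seq_len(n)),
      year = spec$year,
      age = as.integer(age),
      sex = w$sex[cell],
      ses_quintile = as.integer(ses),
      icd10 = unname(icd10),
      site = site
    )
  })
}

#' Write / read a mortality dataset CSV
#'
#' Column layout: `id, year, age, sex, ses_quintile, icd10` (the derived
#' `site` column is re-attached on read from the supplied map).
#'
#' @param records tibble from [generate_mortality_dataset()].
#' @param path file path.
#' @export
write_mortality_csv <- function(records, path) {
  write.csv(records[c("id", "year", "age", "sex", "ses_quintile", "icd10")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mortality_csv
#' @param site_map map used to classify `icd10` into sites on read.
#' @export
read_mortality_csv <- function(path, site_map = default_site_map()) {
  rec <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  rec$site <- classify_site(rec$icd10, site_map)
  rec
}
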
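# Reference summary tables for premature (< age 80) cancer mortality in
# Australia in 2003. These published national summary statistics serve two
# purposes: they are the default marginals of the synthetic mortality
# generator, and they are ready-made inputs for the reporting operations
# (shares of total, per-death costs, reduction scenarios), which act on
# aggregate tables regardless of where those tables came from.

#' Premature cancer deaths and years of life lost, Australia 2003
#'
#' Counts of premature (< 80 years) cancer deaths in 2003 and the associated
#' counterfactual years of life lost (YLL) projected to 2030, by reporting
#' age band and sex.
#'
#' @return tibble with columns `age_band` (ordered factor `<15` ... `65-80`),
#'   `sex` (`"M"`/`"F"`), `deaths`, `yll`.
#' @export
aus_cancer_deaths_2003 <- function() {
  bands <- reporting_age_bands()$label
  tibble::tibble(
    age_band = factor(rep(bands, 2L), levels = bands, ordered = TRUE),
    sex = rep(c("M", "F"), each = length(bands)),
    deaths = c(
      54, 57, 121, 422, 1338, 3385, 9674,
      35, 42, 153, 524, 1376, 2497, 6055
    ),
    yll = c(
      1261, 1345, 2791, 9783, 31069, 73828, 141598,
      804, 980, 3568, 12396, 32928, 56708, 100115
    )
  )
}

#' PVLI forgone by age band and sex, Australia 2003
#'
#' Present value of lifetime income (PVLI) forgone due to premature cancer
#' deaths in 2003, projected 2003-2030, in millions of 2016 Australian
#' dollars, by reporting age band and sex.
#'
#' @return tibble with columns `age_band`, `sex`, `pvli_m` ($ millions).
#' @export
aus_cancer_pvli_2003 <- function() {
  bands <- reporting_age_bands()$label
  tibble::tibble(
    age_band = factor(rep(bands, 2L), levels = bands, ordered = TRUE),
    sex = rep(c("M", "F"), each = length(bands)),
    pvli_m = c(
      14, 45, 142, 505, 1084, 950, 388,
      17, 22, 79, 233, 382, 269, 68
    )
  )
}

#' Site-level burden of premature cancer mortality, Australia 2003
#'
#' Working years lost, PVLI forgone (millions of 2016 AUD) and number of
#' premature deaths by cancer site, projected 2003-2030. Site labels match
#' [default_site_map()].
#'
#' @return tibble with columns `site`, `working_years`, `pvli_m`, `deaths`.
#' @export
aus_cancer_sites_2003 <- function() {
  rows <- list(
    list("Lung cancer", 15943, 765, 5746),
    list("Colorectal cancer", 10332, 497, 3253),
    list("Brain cancer", 6571, 326, 1003),
    list("Breast cancer", 7519, 307, 2171),
    list("Melanoma", 4897, 249, 867),
    list("Lymphoma", 4263, 209, 1101),
    list("Leukaemia", 4180, 201, 990),
    list("Pancreatic cancer", 4083, 197, 1398),
    list("Oesophageal cancer", 3134, 156, 849),
    list("Stomach cancer", 3113, 154, 830),
    list("Liver cancer (excluding hepatitis B and C related)", 2929, 150, 720),
    list("Mouth and oropharynx cancers", 2805, 142, 566),
    list("Prostate cancer", 2605, 125, 1547),
    list("Kidney cancer", 2414, 121, 656),
    list("Bone and connective tissue cancer", 1890, 88, 240),
    list("Ovarian cancer", 1505, 61, 632),
    list("Multiple myeloma", 1205, 58, 488),
    list("Bladder cancer", 1029, 50, 480),
    list("Cervical cancer", 967, 39, 213),
    list("Laryngeal cancer", 718, 36, 186),
    list("Non-melanoma skin cancers", 639, 32, 197),
    list("Gallbladder cancer", 544, 26, 192),
    list("Corpus uteri cancer", 354, 14, 183),
    list("Testicular cancer", 237, 13, 16),
    list("Eye cancer", 126, 7, 24),
    list("Thyroid cancer", 96, 4, 54),
    list("Other malignant neoplasms", 3554, 171, 1131)
  )
  tibble::tibble(
    site = vapply(rows, function(r) r[[1]], ""),
    working_years = vapply(rows, function(r) r[[2]], 1),
    pvli_m = vapply(rows, function(r) r[[3]], 1),
    deaths = vapply(rows, function(r) r[[4]], 1)
  )
}

#' Published grand totals, Australia 2003
#'
#' The published cohort-level totals. Stratified rows carry independent
#' display rounding, so they can under- or over-sum these by a unit; ratio
#' calculations against the total therefore use these values, not row sums.
#'
#' @return list with `deaths`, `yll`, `working_years`, `pvli_m` (total PVLI,
#'   $ millions), `pvli_m_male` (male total PVLI, $ millions).
#' @export
aus_cancer_totals_2003 <- function() {
  list(deaths = 25733, yll = 469174, working_years = 87653,
       pvli_m = 4200, pvli_m_male = 3128)
}

#' Reporting age bands
#'
#' The seven age bands used in stratified outputs. The open-ended top band is
#' labelled `65-80` and covers integer ages 65-79: all deaths in scope are
#' premature, i.e. before the 80th birthday.
#'
#' @return tibble with columns `label`, `lo`, `hi` (inclusive integer ages).
#' @export
reporting_age_bands <- function() {
  tibble::tibble(
    label = c("<15", "15-24", "25-34", "35-44", "45-54", "55-64", "65-80"),
    lo = c(0L, 15L, 25L, 35L, 45L, 55L, 65L),
    hi = c(14L, 24L, 34L, 44L, 54L, 64L, 79L)
  )
}

# Assign each integer age to a reporting band label (ordered factor).
reporting_age_band_of <- function(age) {
  bands <- reporting_age_bands()
  idx <- findInterval(age, bands$lo)
  if (any(age < 0 | age > max(bands$hi))) {
    data_error("age outside 0-79 cannot be assigned a reporting band")
  }
  factor(bands$label[idx], levels = bands$label, ordered = TRUE)
}
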
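test_that("premature filter keeps deaths strictly before age 80", {
  recs <- tibble::tibble(id = 1:5, age = c(0, 45, 79, 80, 95))
  expect_equal(filter_premature(recs)$age, c(0, 45, 79))
  expect_equal(nrow(filter_premature(recs[0, ])), 0)
  expect_error(filter_premature(tibble::tibble(id = 1, age = -2)),
               class = "prodloss_data_error")
})

test_that("cell index partitions the alive population at the matching year", {
  panel <- make_dense_panel()
  # one person dead at 2003 must be excluded
  panel$alive[panel$person_id == "P000001"] <- 0L
  cells <- build_cells(panel)
  n_alive <- length(unique(panel$person_id[panel$year == 2003 & panel$alive == 1]))
  expect_equal(nrow(cells$persons), n_alive)
  expect_false(anyNA(cells$persons$band_i))
  # single-person cell: a unique (band, sex, ses) combination maps to itself
  keys <- paste(cells$persons$band_i, cells$persons$sex, cells$persons$ses)
  expect_true(all(table(keys) >= 1))
})

test_that("a one-candidate cell is a forced choice and seeds determine matches", {
  years <- 2003:2030
  mk <- function(pid, age0, sex, ses) {
    tibble::tibble(person_id = pid, year = years, age = age0 + years - 2003L,
                   sex = sex, ses_quintile = ses, alive = 1L,
                   weekly_hours = 0, annual_income_real = 0)
  }
  # exactly one person shares the decedent's cell (30-34, F, 2)
  panel <- dplyr::bind_rows(mk("P1", 33L, "F", 2L), mk("P2", 33L, "M", 2L),
                            mk("P3", 52L, "F", 2L))
  cells <- build_cells(panel)
  death <- tibble::tibble(id = "D1", year = 2003, age = 33L, sex = "F",
                          ses_quintile = 2L, icd10 = "C50", site = "Breast cancer")
  for (s in c(1, 77, 1234)) {
    a <- match_replicate(death, cells, seed = s)
    expect_equal(a$pairs$person_id, "P1")
    expect_equal(a$pairs$fallback_level, 0L)
  }
  dense <- build_cells(make_dense_panel())
  deaths <- make_deaths(n = 80)
  a1 <- match_replicate(deaths, dense, seed = 42)
  a2 <- match_replicate(deaths, dense, seed = 42)
  expect_identical(a1$pairs, a2$pairs)
})

test_that("non-fallback pairs share age band, sex and SES with their decedent", {
  panel <- make_dense_panel()
  cells <- build_cells(panel)
  deaths <- make_deaths(n = 120, seed = 4)
  a <- match_replicate(deaths, cells, seed = 9)
  expect_equal(nrow(a$pairs), nrow(deaths))          # completeness
  expect_equal(nrow(a$fallback_log), 0)              # dense panel: no fallback
  pp <- cells$persons[match(a$pairs$person_id, cells$persons$person_id), ]
  expect_equal(pp$sex, deaths$sex)
  expect_equal(pp$ses, as.integer(deaths$ses_quintile))
  expect_equal(pp$band_i, band_index_of(deaths$age, cells$banding))
})

test_that("the fallback ladder relaxes SES, then age, and logs every relaxation", {
  # panel with candidates only in quintile 1, male, single band (ages 30-34)
  years <- 2003:2030
  panel <- tibble::tibble(
    person_id = rep(c("A", "B"), each = length(years)),
    year = rep(years, 2),
    age = rep(30L + years - 2003L, 2),
    sex = "M", ses_quintile = rep(c(1L, 2L), each = length(years)),
    alive = 1L, weekly_hours = 0, annual_income_real = 0
  )
  cells <- build_cells(panel)
  # decedent in quintile 3: no exact cell, adjacent quintile 2 works (level 1)
  d1 <- tibble::tibble(id = "D1", year = 2003, age = 31L, sex = "M",
                       ses_quintile = 3L)
  a1 <- match_replicate(d1, cells, seed = 1)
  expect_equal(a1$pairs$fallback_level, 1L)
  expect_equal(a1$pairs$person_id, "B")
  expect_equal(a1$fallback_log$death_id, "D1")
  # decedent aged 36, quintile 5: needs widened band AND dropped SES (level 3)
  d2 <- tibble::tibble(id = "D2", year = 2003, age = 36L, sex = "M",
                       ses_quintile = 5L)
  a2 <- match_replicate(d2, cells, seed = 1)
  expect_equal(a2$pairs$fallback_level, 3L)
  # no candidate of the right sex anywhere: hard error naming the decedent
  d3 <- tibble::tibble(id = "D3", year = 2003, age = 31L, sex = "F",
                       ses_quintile = 1L)
  expect_error(match_replicate(d3, cells, seed = 1), "D3",
               class = "prodloss_data_error")
})

test_that("replicate runs derive seeds by XOR and reproduce exactly", {
  panel <- make_dense_panel()
  cells <- build_cells(panel)
  deaths <- make_deaths(n = 60, seed = 2)
  reps <- run_replicates(deaths, cells, n_replicates = 5, base_seed = 101)
  expect_length(reps, 5)
  for (r in seq_along(reps)) {
    expect_equal(reps[[r]]$seed, replicate_seed(101, r - 1))
    expect_equal(nrow(reps[[r]]$pairs), nrow(deaths))
  }
  # replicate 0 must equal a direct single match at the derived seed
  solo <- match_replicate(deaths, cells, seed = replicate_seed(101, 0))
  expect_identical(reps[[1]]$pairs, solo$pairs)
  reps2 <- run_replicates(deaths, cells, n_replicates = 5, base_seed = 101)
  expect_identical(lapply(reps, `[[`, "pairs"), lapply(reps2, `[[`, "pairs"))
  expect_error(run_replicates(deaths, cells, n_replicates = 0, base_seed = 1),
               class = "prodloss_config_error")
})

test_that("within-cell draws are uniform over candidates (chi-square)", {
  # 4 candidates in one cell; 10,000 seeded draws via a cohort of identical keys
  years <- 2003:2030
  panel <- dplyr::bind_rows(lapply(sprintf("P%d", 1:4), function(pid) {
    tibble::tibble(person_id = pid, year = years, age = 40L + years - 2003L,
                   sex = "F", ses_quintile = 3L, alive = 1L,
                   weekly_hours = 0, annual_income_real = 0)
  }))
  cells <- build_cells(panel)
  deaths <- tibble::tibble(id = sprintf("D%05d", 1:10000), year = 2003,
                           age = 42L, sex = "F", ses_quintile = 3L)
  a <- match_replicate(deaths, cells, seed = 314)
  counts <- table(factor(a$pairs$person_id, levels = sprintf("P%d", 1:4)))
  expect_equal(sum(counts), 10000)
  p <- stats::chisq.test(as.vector(counts), p = rep(0.25, 4))$p.value
  expect_gt(p, 0.001)
})
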
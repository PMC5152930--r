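# Replicate matching of decedents to panel persons.
#
# Each premature cancer decedent is assigned a counterfactual life trajectory
# by drawing, uniformly at random and with replacement, a panel person from
# the cell sharing the decedent's age category, sex and socioeconomic
# quintile in the matching year. Sampling with replacement is required
# because a national decedent cohort can exceed a cell's candidate count in a
# one-percent population sample. The whole procedure is replicated R times
# with seeds derived as base_seed XOR replicate_index, so runs reproduce
# exactly across machines.

#' Matching age bands
#'
#' Five-year bands 0-4, 5-9, ..., 75-79 by default: finer than the reporting
#' bands, coarse enough to keep cells populated at one-percent-sample
#' densities.
#'
#' @param width band width in years (default 5).
#' @param max_age top age covered (default 79; matching applies to premature
#'   deaths only).
#' @return tibble with columns `lo`, `hi`, `label`.
#' @export
matching_age_bands <- function(width = 5L, max_age = 79L) {
  lo <- seq(0L, max_age, by = width)
  hi <- pmin(lo + width - 1L, max_age)
  tibble::tibble(lo = lo, hi = hi, label = sprintf("%d-%d", lo, hi))
}

band_index_of <- function(age, banding) {
  idx <- findInterval(age, banding$lo)
  idx[age < 0 | age > max(banding$hi)] <- NA_integer_
  idx
}

#' Keep premature deaths only
#'
#' A premature death occurs before the 80th birthday (close to life
#' expectancy); only these are costed.
#'
#' @param records death-record tibble with an `age` column.
#' @return the subset with `age < 80`.
#' @export
#' @examples
#' filter_premature(tibble::tibble(id = 1:3, age = c(79, 80, 95)))
filter_premature <- function(records) {
  if (any(!is.finite(records$age) | records$age < 0)) {
    data_error("death records contain invalid ages")
  }
  records[records$age < 80, , drop = FALSE]
}

#' Index panel persons into matching cells
#'
#' Builds the candidate index used by [match_replicate()]: every panel person
#' alive in the matching year is placed in exactly one (age band x sex x SES
#' quintile) cell, keyed on their age in that year.
#'
#' @param panel long person-year tibble (see [generate_population_panel()]).
#' @param banding age banding from [matching_age_bands()].
#' @param match_year calendar year at which candidates are indexed (default:
#'   first panel year).
#' @return an object of class `match_cells`.
#' @export
build_cells <- function(panel, banding = matching_age_bands(),
                        match_year = min(panel$year)) {
  # Open-ended top band so every alive person lands in exactly one cell;
  # no decedent key ever maps there, but the age-widening fallback of the
  # youngest-old band may draw from it.
  top <- max(banding$hi)
  banding <- rbind(
    banding,
    tibble::tibble(lo = top + 1L, hi = 200L, label = sprintf("%d+", top + 1L))
  )
  at <- panel[panel$year == match_year & panel$alive == 1, , drop = FALSE]
  band_i <- band_index_of(at$age, banding)
  persons <- tibble::tibble(
    person_id = at$person_id,
    band_i = band_i,
    sex = at$sex,
    ses = as.integer(at$ses_quintile)
  )
  structure(
    list(banding = banding, match_year = match_year, persons = persons),
    class = "match_cells"
  )
}

cell_key_string <- function(banding, band_i, sex, ses) {
  paste(banding$label[band_i], sex, ses, sep = "|")
}

# Candidate person ids for one decedent key at a given relaxation level.
# Levels escalate cumulatively: 0 exact cell; 1 adjacent SES quintiles
# merged; 2 age band additionally widened by one band either side; 3 SES
# dropped entirely (widened band, same sex).
candidates_at_level <- function(persons, band_i, sex, ses, level, n_bands) {
  bands <- if (level >= 2) max(1L, band_i - 1L):min(n_bands, band_i + 1L) else band_i
  sel <- persons$band_i %in% bands & persons$sex == sex
  if (level == 0) {
    sel <- sel & persons$ses == ses
  } else if (level < 3) {
    sel <- sel & abs(persons$ses - ses) <= 1L
  }
  persons$person_id[sel]
}

#' Match one replicate of decedents to panel persons
#'
#' Each decedent draws one candidate uniformly at random, with replacement,
#' from its (age band x sex x SES) cell. When a cell is empty a fallback
#' ladder is climbed -- merge adjacent SES quintiles, then widen the age band
#' by one band either side, then drop SES -- and every relaxed match is
#' logged. Deterministic given `seed`.
#'
#' @param deaths premature cancer death records (tibble with `id`, `age`,
#'   `sex`, `ses_quintile`).
#' @param cells candidate index from [build_cells()].
#' @param seed integer seed for this replicate.
#' @param replicate_index replicate number recorded in the output (default 0).
#' @return an object of class `match_assignment`: list with
#'   `replicate_index`, `seed`, `pairs` (tibble `death_id`, `person_id`,
#'   `cell_key`, `fallback_level`) and `fallback_log`.
#' @export
match_replicate <- function(deaths, cells, seed, replicate_index = 0L) {
  stopifnot(inherits(cells, "match_cells"))
  banding <- cells$banding
  persons <- cells$persons
  n_bands <- nrow(banding)
  band_i <- band_index_of(deaths$age, banding)
  if (any(is.na(band_i))) {
    data_error("decedent age outside the matching banding; filter premature deaths first")
  }
  key <- cell_key_string(banding, band_i, deaths$sex, deaths$ses_quintile)

  person_out <- character(nrow(deaths))
  level_out <- integer(nrow(deaths))
  key_out <- character(nrow(deaths))

  with_seed(seed, {
    for (k in sort(unique(key))) {
      rows <- which(key == k)
      b <- band_i[rows[1L]]
      sx <- deaths$sex[rows[1L]]
      q <- as.integer(deaths$ses_quintile[rows[1L]])
      level <- 0L
      cand <- candidates_at_level(persons, b, sx, q, 0L, n_bands)
      while (length(cand) == 0L && level < 3L) {
        level <- level + 1L
        cand <- candidates_at_level(persons, b, sx, q, level, n_bands)
      }
      if (length(cand) == 0L) {
        stop(errorCondition(
          sprintf("no match candidates for decedent(s) %s (cell %s) even after full relaxation",
                  paste(deaths$id[rows], collapse = ", "), k),
          class = c("prodloss_data_error", "error")
        ))
      }
      person_out[rows] <- cand[sample.int(length(cand), length(rows), replace = TRUE)]
      level_out[rows] <- level
      key_out[rows] <- if (level == 0L) k else paste0(k, "~relaxed", level)
    }
  })

  pairs <- tibble::tibble(
    death_id = deaths$id,
    person_id = person_out,
    cell_key = key_out,
    fallback_level = level_out
  )
  fallback_log <- pairs[pairs$fallback_level > 0L, c("death_id", "fallback_level")]
  structure(
    list(replicate_index = as.integer(replicate_index), seed = as.integer(seed),
         pairs = pairs, fallback_log = fallback_log),
    class = "match_assignment"
  )
}

#' Derive the seed of one replicate
#'
#' Replicate r (0-based) uses `base_seed XOR r`. This derivation is part of
#' the public contract so replicated runs reproduce across machines.
#'
#' @param base_seed integer base seed.
#' @param replicate_index 0-based replicate number.
#' @return integer seed.
#' @export
replicate_seed <- function(base_seed, replicate_index) {
  bitwXor(as.integer(base_seed), as.integer(replicate_index))
}

#' Run R matching replicates
#'
#' @inheritParams match_replicate
#' @param n_replicates number of replicates R (>= 1).
#' @param base_seed integer; replicate r uses seed [replicate_seed()]
#'   `(base_seed, r)`.
#' @return list of `n_replicates` [match_replicate()] results.
#' @export
run_replicates <- function(deaths, cells, n_replicates = 100L, base_seed = 1L) {
  if (n_replicates < 1) config_error("n_replicates must be >= 1")
  lapply(seq_len(n_replicates) - 1L, function(r) {
    match_replicate(deaths, cells, seed = replicate_seed(base_seed, r),
                    replicate_index = r)
  })
}

#' Write matching assignments to CSV
#'
#' One row per (replicate, decedent) pair with the cell key actually used and
#' the fallback level (0 = exact cell).
#'
#' @param assignments list of [match_replicate()] results.
#' @param path file path.
#' @export
write_assignments_csv <- function(assignments, path) {
  rows <- do.call(rbind, lapply(assignments, function(a) {
    cbind(replicate = a$replicate_index, a$pairs)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
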
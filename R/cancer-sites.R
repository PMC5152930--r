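# Cancer site classification from ICD-10 underlying-cause codes.
#
# A death is a cancer death when its three-character ICD-10 category lies in
# C00-C97 (malignant neoplasms). Cancer codes are grouped into 26 named sites
# plus a catch-all "Other malignant neoplasms"; the named ranges follow
# standard WHO ICD-10 category groupings and can be overridden with a
# user-supplied mapping file.

# Parse an ICD-10-shaped token into its chapter letter and a numeric position
# category*100 + subcode (subcode 0 when absent), e.g. "C34.1" -> 3401.
# Range endpoints without a subcode cover the whole category (C34 ends 3499).
parse_icd10 <- function(code, what = "code") {
  code <- toupper(trimws(as.character(code)))
  m <- regmatches(code, regexec("^([A-Z])([0-9]{2})(?:\\.([0-9]{1,2}))?$", code))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    data_error(sprintf(
      "malformed ICD-10 %s: %s", what,
      paste(sQuote(code[bad]), collapse = ", ")
    ))
  }
  letter <- vapply(m, `[`, "", 2L)
  category <- as.integer(vapply(m, `[`, "", 3L))
  sub <- vapply(m, `[`, "", 4L)
  pos <- category * 100L + ifelse(sub == "", 0L, as.integer(sub))
  list(letter = letter, category = category, pos = pos)
}

#' Is an ICD-10 code a cancer (malignant neoplasm) death?
#'
#' A code counts as cancer when its three-character category lies in C00-C97;
#' subcode digits (e.g. the ".1" in "C34.1") are ignored for this decision.
#'
#' @param code character vector of ICD-10 codes (letter, two digits, optional
#'   decimal subcode), e.g. `"C50"`, `"C34.1"`, `"I21"`.
#' @return logical vector, `TRUE` where the code is in C00-C97.
#' @export
#' @examples
#' is_cancer_death(c("C50", "I21", "C97", "C98"))
is_cancer_death <- function(code) {
  p <- parse_icd10(code)
  p$letter == "C" & p$category <= 97L
}

#' Default cancer site map
#'
#' The shipped grouping of ICD-10 categories C00-C97 into 26 named cancer
#' sites plus the catch-all "Other malignant neoplasms". Named ranges follow
#' standard WHO ICD-10 category groupings; any C00-C97 code not covered by a
#' named site falls through to the catch-all, so the map partitions the
#' malignant-neoplasm chapter. Liver cancer is plain C22: a hepatitis-related
#' exclusion cannot be derived from the cause-of-death code alone.
#'
#' @return A tibble with columns `site_label`, `code_start`, `code_end`
#'   (inclusive ICD-10 category ranges; a site may span several rows). The
#'   final row is the catch-all, flagged by `code_start == "C00"` and
#'   `code_end == "C97"` ordered last.
#' @seealso [classify_site()], [read_site_map()]
#' @export
default_site_map <- function() {
  tribble_rows <- list(
    c("Lung cancer", "C33", "C34"),
    c("Colorectal cancer", "C18", "C21"),
    c("Brain cancer", "C70", "C72"),
    c("Breast cancer", "C50", "C50"),
    c("Melanoma", "C43", "C43"),
    c("Lymphoma", "C81", "C85"),
    c("Leukaemia", "C91", "C95"),
    c("Pancreatic cancer", "C25", "C25"),
    c("Oesophageal cancer", "C15", "C15"),
    c("Stomach cancer", "C16", "C16"),
    c("Liver cancer (excluding hepatitis B and C related)", "C22", "C22"),
    c("Mouth and oropharynx cancers", "C00", "C14"),
    c("Prostate cancer", "C61", "C61"),
    c("Kidney cancer", "C64", "C65"),
    c("Bone and connective tissue cancer", "C40", "C41"),
    c("Bone and connective tissue cancer", "C47", "C49"),
    c("Ovarian cancer", "C56", "C56"),
    c("Multiple myeloma", "C90", "C90"),
    c("Bladder cancer", "C67", "C67"),
    c("Cervical cancer", "C53", "C53"),
    c("Laryngeal cancer", "C32", "C32"),
    c("Non-melanoma skin cancers", "C44", "C44"),
    c("Gallbladder cancer", "C23", "C24"),
    c("Corpus uteri cancer", "C54", "C55"),
    c("Testicular cancer", "C62", "C62"),
    c("Eye cancer", "C69", "C69"),
    c("Thyroid cancer", "C73", "C73"),
    c("Other malignant neoplasms", "C00", "C97")
  )
  map <- tibble::tibble(
    site_label = vapply(tribble_rows, `[`, "", 1L),
    code_start = vapply(tribble_rows, `[`, "", 2L),
    code_end   = vapply(tribble_rows, `[`, "", 3L)
  )
  validate_site_map(map)
}

#' Read a site map from a CSV file
#'
#' The file must have columns `site_label`, `code_start`, `code_end`; a site
#' may repeat over several rows (one per range). The last listed site acts as
#' the catch-all for otherwise-unmapped C00-C97 codes.
#'
#' @param path path to the CSV mapping file.
#' @return validated site-map tibble (see [default_site_map()]).
#' @export
read_site_map <- function(path) {
  map <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  needed <- c("site_label", "code_start", "code_end")
  if (!all(needed %in% names(map))) {
    config_error(sprintf(
      "site map file must have columns %s", paste(needed, collapse = ", ")
    ))
  }
  validate_site_map(map[needed])
}

validate_site_map <- function(map) {
  s <- parse_icd10(map$code_start, "site-map range start")
  e <- parse_icd10(map$code_end, "site-map range end")
  if (any(s$letter != "C") || any(e$letter != "C") ||
      any(s$category > 97L) || any(e$category > 97L)) {
    config_error("site map ranges must lie within C00-C97")
  }
  # An endpoint given at category level covers the whole category.
  start_pos <- s$pos
  end_pos <- ifelse(grepl("\\.", map$code_end), e$pos, e$category * 100L + 99L)
  if (any(end_pos < start_pos)) {
    config_error("site map has ranges with end before start")
  }
  map$.start_pos <- start_pos
  map$.end_pos <- end_pos
  # Named sites (all but the last label) must not overlap one another.
  labels <- unique(map$site_label)
  named <- map[map$site_label != labels[length(labels)], ]
  if (nrow(named) > 1) {
    o <- order(named$.start_pos)
    a <- named[o, ]
    if (any(a$.start_pos[-1] <= a$.end_pos[-nrow(a)])) {
      config_error("site map named ranges overlap")
    }
  }
  attr(map, "site_labels") <- labels
  class(map) <- c("prodloss_site_map", class(map))
  map
}

#' Classify a cancer ICD-10 code into a reported site
#'
#' Subcodes classify by their three-character category unless a range in the
#' map is itself defined at subcode level. Codes in C00-C97 matched by no
#' named range receive the map's final (catch-all) label.
#'
#' @param code character vector of ICD-10 codes; all must satisfy
#'   [is_cancer_death()].
#' @param map a site map from [default_site_map()] or [read_site_map()].
#' @return character vector of site labels.
#' @export
#' @examples
#' classify_site(c("C34.1", "C61", "C26"))
classify_site <- function(code, map = default_site_map()) {
  if (!inherits(map, "prodloss_site_map")) map <- validate_site_map(map)
  p <- parse_icd10(code)
  cancer <- p$letter == "C" & p$category <= 97L
  if (any(!cancer)) {
    data_error(sprintf(
      "non-cancer code(s) passed to classify_site: %s",
      paste(sQuote(code[!cancer]), collapse = ", ")
    ))
  }
  labels <- attr(map, "site_labels")
  catchall <- labels[length(labels)]
  named <- map[map$site_label != catchall, ]
  out <- rep(catchall, length(code))
  for (i in seq_len(nrow(named))) {
    hit <- p$pos >= named$.start_pos[i] & p$pos <= named$.end_pos[i]
    out[hit] <- named$site_label[i]
  }
  out
}

#' All site labels of a map, catch-all last
#' @param map a site map.
#' @return character vector of unique site labels in map order.
#' @export
site_labels <- function(map = default_site_map()) {
  attr(validate_if_needed(map), "site_labels")
}

validate_if_needed <- function(map) {
  if (inherits(map, "prodloss_site_map")) map else validate_site_map(map)
}

# All three-character categories C00..C97 belonging to a given site label,
# used by the synthetic generator to draw a concrete code for a site.
site_categories <- function(map = default_site_map()) {
  map <- validate_if_needed(map)
  codes <- sprintf("C%02d", 0:97)
  split(codes, classify_site(codes, map))
}
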
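# Internal helpers shared across modules.

#' @importFrom stats quantile rbinom runif setNames
#' @importFrom utils write.csv read.csv
NULL

# Evaluate `code` with a locally seeded Mersenne-Twister stream, restoring the
# caller's RNG state afterwards so package functions never disturb user code.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Round half away from zero
#'
#' Display rounding used in rendered tables: 0.5 always rounds up in
#' magnitude (so 81.5% renders as 82%), unlike [round()]'s round-half-even.
#' Internals are never rounded; this is applied at display time only.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half-up to `digits` places.
#' @export
#' @examples
#' round_half_up(81.5)   # 82
#' round_half_up(0.5)    # 1
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Configuration-error helper: consistent condition class for bad specs.
config_error <- function(msg) {
  stop(errorCondition(msg, class = c("prodloss_config_error", "error")))
}

data_error <- function(msg) {
  stop(errorCondition(msg, class = c("prodloss_data_error", "error")))
}

check_prob_table <- function(p, name, sum_to_one = TRUE, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0)) {
    config_error(sprintf("probability table '%s' has negative or non-finite entries", name))
  }
  if (sum_to_one && abs(sum(p) - 1) > tol) {
    config_error(sprintf("probability table '%s' must sum to 1 (got %.12f)", name, sum(p)))
  }
  invisible(p)
}
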
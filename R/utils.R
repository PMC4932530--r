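#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going up (0.05 -> 0.1), the
#' convention used for all reported percentages. Base `round()` rounds
#' half to even, which would turn e.g. 76.25 into 76.2.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # guard against values like 54.6 stored as 54.599999... after division
  z <- signif(x * p, 12)
  floor(z + 0.5) / p
}

# Deterministic derived seed, kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483629L)
}

# Evaluate `expr` under a temporary RNG state so callers' streams are not
# disturbed; always seeds first.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

abort_bryoclim <- function(msg, class = "bryoclim_error") {
  rlang::abort(msg, class = class)
}
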
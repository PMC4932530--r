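#' Define a virtual species
#'
#' A virtual species responds to each named climate variable with a Gaussian
#' (bell-shaped) curve; its true suitability at a cell is the product of the
#' per-variable responses, rescaled so the maximum over valid land cells is 1.
#'
#' @param name species identifier.
#' @param responses named list; each element is `c(optimum, breadth)` with
#'   `breadth > 0` (the standard deviation of the bell curve), named after a
#'   landscape variable.
#' @param prevalence_target optional fraction in (0, 1); informational field
#'   describing the intended occupancy of the species.
#' @return a `virtual_species` list.
#' @export
virtual_species <- function(name, responses, prevalence_target = NULL) {
  if (length(responses) == 0L || is.null(names(responses))) {
    abort_bryoclim("`responses` must be a named list with at least one variable.")
  }
  for (v in names(responses)) {
    if (length(responses[[v]]) != 2L || responses[[v]][2] <= 0) {
      abort_bryoclim(sprintf("response for '%s' must be c(optimum, breadth) with breadth > 0.", v))
    }
  }
  if (!is.null(prevalence_target) &&
      (prevalence_target <= 0 || prevalence_target >= 1)) {
    abort_bryoclim("`prevalence_target` must lie in (0, 1).")
  }
  structure(
    list(name = name, responses = responses, prevalence_target = prevalence_target),
    class = "virtual_species"
  )
}

#' True suitability surface of a virtual species
#'
#' @param species a [virtual_species()].
#' @param stack a [climate_stack()].
#' @return numeric matrix in \[0, 1\] with `NA` on invalid cells; the maximum
#'   over valid cells is 1.
#' @export
true_suitability <- function(species, stack) {
  missing_vars <- setdiff(names(species$responses), names(stack$variables))
  if (length(missing_vars) > 0L) {
    abort_bryoclim(sprintf("species '%s' responds to variable(s) absent from the landscape: %s",
                           species$name, paste(missing_vars, collapse = ", ")))
  }
  s <- matrix(1, stack$n_rows, stack$n_cols)
  for (v in names(species$responses)) {
    opt <- species$responses[[v]][1]
    br <- species$responses[[v]][2]
    s <- s * exp(-((stack$variables[[v]] - opt)^2) / (2 * br^2))
  }
  s[!stack$valid_mask] <- NA_real_
  mx <- max(s, na.rm = TRUE)
  if (mx == 0) abort_bryoclim(sprintf("species '%s' has zero suitability everywhere on land.", species$name))
  s / mx
}

#' Sample presence-only occurrences of a virtual species
#'
#' Presences are drawn without replacement from land cells with probability
#' proportional to true suitability — a presence-only sampling model with no
#' detection component, emulating herbarium/field records.
#'
#' @param species a [virtual_species()].
#' @param stack a [climate_stack()].
#' @param n number of occurrences (>= 1).
#' @param seed integer seed.
#' @param mask optional [region_mask()]; when supplied, sampling is restricted
#'   to island cells (the endemic's range). Without it all valid cells are
#'   eligible.
#' @param effort optional named vector of per-archipelago sampling-effort
#'   multipliers (default: uniform effort).
#' @return tibble with columns `species`, `row`, `col`, `lon`, `lat` and
#'   attribute `n_raw = n`; one row per sampled cell.
#' @export
sample_occurrences <- function(species, stack, n, seed, mask = NULL,
                               effort = NULL) {
  if (n < 1) abort_bryoclim("`n` must be >= 1.")
  suit <- true_suitability(species, stack)
  eligible <- stack$valid_mask
  if (!is.null(mask)) eligible <- eligible & mask$island_id > 0
  w <- ifelse(eligible, suit, NA_real_)
  if (!is.null(effort)) {
    if (is.null(mask)) abort_bryoclim("`effort` requires a region_mask.")
    for (arch in names(effort)) {
      sel <- !is.na(mask$archipelago) & mask$archipelago == arch
      w[sel] <- w[sel] * effort[[arch]]
    }
  }
  idx <- which(!is.na(w) & w > 0)
  if (length(idx) < n) {
    abort_bryoclim(sprintf(
      "requested %d occurrences but only %d cells have positive suitability.",
      n, length(idx)))
  }
  cells <- with_seed(seed, sample(idx, n, replace = FALSE, prob = w[idx]))
  row <- ((cells - 1L) %% stack$n_rows) + 1L
  col <- ((cells - 1L) %/% stack$n_rows) + 1L
  ll <- cell_to_lonlat(row, col, stack$west, stack$north, stack$cell_size)
  out <- tibble::tibble(species = species$name, row = as.integer(row),
                        col = as.integer(col), lon = ll$lon, lat = ll$lat)
  attr(out, "n_raw") <- n
  out
}
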
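#' Project an ensemble over a climate stack
#'
#' Predicts the weighted ensemble suitability for every valid cell.
#'
#' @param ensemble an `sdm_ensemble` from [build_consensus()] (or any model
#'   honouring [predict_suitability()]).
#' @param stack a [climate_stack()] carrying all training variables.
#' @param species,scenario optional provenance labels stored on the surface.
#' @return a `suitability_surface`: list with `grid` (matrix in \[0, 1\],
#'   `NA` on invalid cells), `species`, `scenario`.
#' @export
predict_surface <- function(ensemble, stack, species = NA_character_,
                            scenario = "present") {
  cells <- valid_cells(stack)
  env <- env_at_cells(stack, cells, ensemble$vars)
  pred <- predict_suitability(ensemble, env)
  grid <- matrix(NA_real_, stack$n_rows, stack$n_cols)
  grid[cbind(cells$row, cells$col)] <- pred
  structure(list(grid = grid, species = species, scenario = scenario),
            class = "suitability_surface")
}

#' Multivariate environmental similarity surface (MESS)
#'
#' For each valid cell and each variable, with reference minimum `min`,
#' maximum `max` and `f` the percentage of reference values strictly below the
#' cell value: `f = 0 -> s = 100 (v - min)/(max - min)`; `0 < f <= 50 ->
#' s = 2 f`; `50 < f < 100 -> s = 2 (100 - f)`; `f = 100 ->
#' s = 100 (max - v)/(max - min)`. The MESS value is the minimum of `s` over
#' variables; a positive value means every variable lies within the reference
#' range, a negative value flags non-analog climate. A degenerate reference
#' variable (max = min) scores 100 at that value and a large negative
#' sentinel elsewhere.
#'
#' @param reference_env matrix of reference environments (>= 2 rows, named
#'   columns) — typically the calibration presence cells.
#' @param stack a [climate_stack()] to score.
#' @return a `mess_surface`: list with `grid` (matrix, `NA` on invalid cells)
#'   and `n_reference`.
#' @export
compute_mess <- function(reference_env, stack) {
  if (nrow(reference_env) < 2L) abort_bryoclim("reference needs at least 2 points.")
  vars <- colnames(reference_env)
  miss <- setdiff(vars, names(stack$variables))
  if (length(miss) > 0L) {
    abort_bryoclim(sprintf("stack lacks reference variable(s): %s",
                           paste(miss, collapse = ", ")))
  }
  cells <- valid_cells(stack)
  env <- env_at_cells(stack, cells, vars)
  n_ref <- nrow(reference_env)
  s_all <- matrix(NA_real_, nrow(env), length(vars))
  for (j in seq_along(vars)) {
    ref <- sort(reference_env[, vars[j]])
    lo <- ref[1]; hi <- ref[n_ref]
    v <- env[, j]
    if (hi == lo) {
      message(sprintf("compute_mess: reference range of '%s' is degenerate.", vars[j]))
      s_all[, j] <- ifelse(v == lo, 100, -1e6)
      next
    }
    f <- 100 * findInterval(v, ref, left.open = TRUE) / n_ref
    s <- numeric(length(v))
    s[f == 0] <- 100 * (v[f == 0] - lo) / (hi - lo)
    mid_lo <- f > 0 & f <= 50
    s[mid_lo] <- 2 * f[mid_lo]
    mid_hi <- f > 50 & f < 100
    s[mid_hi] <- 2 * (100 - f[mid_hi])
    s[f == 100] <- 100 * (hi - v[f == 100]) / (hi - lo)
    s_all[, j] <- s
  }
  m <- apply(s_all, 1, min)
  grid <- matrix(NA_real_, stack$n_rows, stack$n_cols)
  grid[cbind(cells$row, cells$col)] <- m
  structure(list(grid = grid, n_reference = n_ref), class = "mess_surface")
}

#' Sensitivity-based binarization threshold
#'
#' Lower empirical quantile of the calibration-presence suitability scores:
#' the largest score such that at most `error_rate` of the presences fall
#' strictly below it, so at least `1 - error_rate` of presences are predicted
#' present. With the default 5% this is the "5% error adjustment" used to
#' turn the continuous index into presence/absence.
#'
#' @param surface_at_presences suitability scores at calibration presences.
#' @param error_rate tolerated omission on presences (default 0.05).
#' @return list with `threshold` and `omission` (achieved fraction of
#'   presences scoring strictly below the threshold).
#' @export
select_threshold <- function(surface_at_presences, error_rate = 0.05) {
  n <- length(surface_at_presences)
  if (n < 1L) abort_bryoclim("need at least one presence score.")
  s <- sort(surface_at_presences)
  k <- floor(error_rate * n)
  threshold <- s[k + 1L]
  list(threshold = threshold,
       omission = sum(surface_at_presences < threshold) / n)
}

#' Threshold a suitability surface and mask non-analog climate
#'
#' A cell is in the binary range iff it is valid, its suitability is at least
#' the threshold, and (when a MESS surface is supplied) its MESS value is
#' positive. Masking can only remove cells, never add them.
#'
#' @param surface a `suitability_surface` from [predict_surface()].
#' @param threshold binarization threshold (see [select_threshold()]).
#' @param mess optional `mess_surface` from [compute_mess()].
#' @return a `binary_range`: list with logical `grid` (`NA`-free; `FALSE` on
#'   invalid cells), `threshold`, `species`, `scenario`.
#' @export
binarize_and_mask <- function(surface, threshold, mess = NULL) {
  g <- surface$grid
  if (!is.null(mess) && !identical(dim(mess$grid), dim(g))) {
    abort_bryoclim("suitability and MESS grids are not aligned.")
  }
  range_grid <- !is.na(g) & g >= threshold
  if (!is.null(mess)) {
    range_grid <- range_grid & !is.na(mess$grid) & mess$grid > 0
  }
  structure(
    list(grid = range_grid, threshold = threshold,
         species = surface$species, scenario = surface$scenario),
    class = "binary_range"
  )
}

#' @export
print.suitability_surface <- function(x, ...) {
  cat(sprintf("<suitability_surface> %s / %s; %d valid cells, mean %.3f\n",
              x$species, x$scenario, sum(!is.na(x$grid)),
              mean(x$grid, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.binary_range <- function(x, ...) {
  cat(sprintf("<binary_range> %s / %s; %d suitable cells (threshold %.4f)\n",
              x$species, x$scenario, sum(x$grid), x$threshold))
  invisible(x)
}
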
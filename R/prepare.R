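#' Snap occurrence records to the grid and thin to one per cell
#'
#' Records separated by less than one grid cell collapse to a single
#' occurrence — the standard sampling-bias control of gridding presence
#' records at the resolution of the climate data. Records falling on invalid
#' cells (sea / missing data) are dropped with a message.
#'
#' @param records data frame with columns `lon`, `lat` and optionally
#'   `species` (a single species per call).
#' @param stack a [climate_stack()].
#' @return tibble with columns `species`, `row`, `col`, `lon`, `lat` (cell
#'   centres), at most one row per grid cell; attribute `n_raw` holds the
#'   input record count and `n_dropped_invalid` the number discarded on
#'   invalid cells. Thinning is idempotent.
#' @export
snap_and_thin <- function(records, stack) {
  if (nrow(records) == 0L) abort_bryoclim("no occurrence records supplied.")
  species <- if ("species" %in% names(records)) records$species[1] else NA_character_
  east <- stack$west + stack$n_cols * stack$cell_size
  south <- stack$north - stack$n_rows * stack$cell_size
  inb <- records$lon >= stack$west & records$lon <= east &
    records$lat >= south & records$lat <= north_of(stack)
  records <- records[inb, , drop = FALSE]
  if (nrow(records) == 0L) {
    abort_bryoclim("all occurrence records fall outside the grid bounds.")
  }
  cells <- lonlat_to_cell(records$lon, records$lat, stack$west, stack$north,
                          stack$cell_size, stack$n_rows, stack$n_cols)
  valid <- stack$valid_mask[cbind(cells$row, cells$col)]
  n_dropped <- sum(!valid)
  if (n_dropped > 0L) {
    message(sprintf("snap_and_thin: dropped %d record(s) on invalid cells.", n_dropped))
  }
  cells <- cells[valid, , drop = FALSE]
  if (nrow(cells) == 0L) {
    abort_bryoclim("all occurrence records fall on invalid cells.")
  }
  cells <- dplyr::distinct(cells, .data$row, .data$col)
  ll <- cell_to_lonlat(cells$row, cells$col, stack$west, stack$north, stack$cell_size)
  out <- tibble::tibble(species = species, row = cells$row, col = cells$col,
                        lon = ll$lon, lat = ll$lat)
  attr(out, "n_raw") <- nrow(records) + n_dropped
  attr(out, "n_dropped_invalid") <- n_dropped
  out
}

north_of <- function(stack) stack$north

#' Minimum-records rule
#'
#' A species qualifies for modelling when its thinned occurrence set has at
#' least `min_records` distinct cells. The default of 11 reads "more than ten
#' records" strictly; published guidance places the workable minimum between
#' 3 and 13 depending on range size, hence the parameter.
#'
#' @param occ thinned occurrence tibble from [snap_and_thin()].
#' @param min_records minimum number of occupied cells (default 11).
#' @return logical scalar.
#' @export
passes_min_records <- function(occ, min_records = 11) {
  nrow(occ) >= min_records
}

#' Screen predictors for collinearity
#'
#' Pearson correlations are computed on a random sample of valid cells
#' (`n_sample` points, drawn with replacement when fewer valid cells exist).
#' Pairs with |r| above `r_max` are resolved greedily: the pair with the
#' largest |r| is found and its member lower in `priority_order` is dropped,
#' until no retained pair offends.
#'
#' @param stack a [climate_stack()].
#' @param candidate_vars variable names to screen.
#' @param priority_order variables to keep preferentially, most-preferred
#'   first; candidates not listed rank below all listed ones, in input order.
#' @param r_max correlation threshold (default 0.8).
#' @param n_sample number of screening sample cells (default 10000).
#' @param seed integer seed for the screening sample.
#' @return a `variable_screen` list: `retained` (ordered names), `dropped`
#'   (tibble of dropped/kept_instead/correlation), `sample_cells`, `seed`,
#'   and `cor_matrix` (screening-sample correlations).
#' @export
screen_collinearity <- function(stack, candidate_vars,
                                priority_order = candidate_vars,
                                r_max = 0.8, n_sample = 10000, seed = 1L) {
  if (length(candidate_vars) < 2L) {
    abort_bryoclim("need at least two candidate variables.")
  }
  missing_vars <- setdiff(candidate_vars, names(stack$variables))
  if (length(missing_vars) > 0L) {
    abort_bryoclim(sprintf("candidate(s) absent from the stack: %s",
                           paste(missing_vars, collapse = ", ")))
  }
  idx <- which(stack$valid_mask)
  if (length(idx) < 2L) abort_bryoclim("not enough valid cells to sample.")
  replace <- length(idx) < n_sample
  cells_i <- with_seed(seed, sample(idx, n_sample, replace = replace))
  row <- ((cells_i - 1L) %% stack$n_rows) + 1L
  col <- ((cells_i - 1L) %/% stack$n_rows) + 1L
  env <- env_at_cells(stack, tibble::tibble(row = row, col = col), candidate_vars)
  cm <- stats::cor(env)

  rank_of <- function(v) {
    r <- match(v, priority_order)
    ifelse(is.na(r), length(priority_order) + match(v, candidate_vars), r)
  }
  retained <- candidate_vars
  dropped <- tibble::tibble(dropped = character(), kept_instead = character(),
                            correlation = numeric())
  repeat {
    sub <- cm[retained, retained, drop = FALSE]
    diag(sub) <- 0
    if (all(abs(sub) <= r_max, na.rm = TRUE)) break
    worst <- which(abs(sub) == max(abs(sub), na.rm = TRUE), arr.ind = TRUE)[1, ]
    a <- retained[worst[1]]; b <- retained[worst[2]]
    loser <- if (rank_of(a) > rank_of(b)) a else b
    keeper <- setdiff(c(a, b), loser)
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      dropped = loser, kept_instead = keeper,
      correlation = sub[worst[1], worst[2]]
    ))
    retained <- setdiff(retained, loser)
  }
  structure(
    list(retained = retained, dropped = dropped,
         sample_cells = n_sample, seed = seed, r_max = r_max, cor_matrix = cm),
    class = "variable_screen"
  )
}

#' @export
print.variable_screen <- function(x, ...) {
  cat(sprintf("<variable_screen> retained: %s | dropped: %d (|r| > %g on %d sample cells)\n",
              paste(x$retained, collapse = ", "), nrow(x$dropped), x$r_max,
              x$sample_cells))
  invisible(x)
}

#' Draw pseudo-absence (background) cells
#'
#' Samples `n` distinct valid cells uniformly over the geographic background,
#' never reusing presence cells.
#'
#' @param stack a [climate_stack()].
#' @param n number of background cells.
#' @param seed integer seed.
#' @param exclude occurrence tibble whose `row`/`col` cells are ineligible.
#' @return tibble with columns `row`, `col`.
#' @export
sample_background <- function(stack, n, seed, exclude = NULL) {
  idx <- which(stack$valid_mask)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    excl <- (exclude$col - 1L) * stack$n_rows + exclude$row
    idx <- setdiff(idx, excl)
  }
  if (length(idx) < n) {
    abort_bryoclim(sprintf("requested %d background cells but only %d are eligible.",
                           n, length(idx)))
  }
  cells <- with_seed(seed, sample(idx, n, replace = FALSE))
  tibble::tibble(row = as.integer(((cells - 1L) %% stack$n_rows) + 1L),
                 col = as.integer(((cells - 1L) %/% stack$n_rows) + 1L))
}
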
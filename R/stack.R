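#' Co-registered climate and elevation grids
#'
#' A `climate_stack` bundles named climate grids, an elevation grid, a shared
#' geotransform and a validity mask. All grids are numeric matrices with row 1
#' at the northern edge; cells are addressed as (row, col) everywhere in the
#' package, and only [lonlat_to_cell()] / [cell_to_lonlat()] translate between
#' geographic coordinates and cell indices.
#'
#' @param variables named list of numeric matrices, one per climate variable.
#' @param elevation numeric matrix of elevation (m), same shape.
#' @param west,north longitude of the western edge and latitude of the
#'   northern edge of the grid (degrees).
#' @param cell_size cell size in decimal degrees (> 0); the default 0.0083
#'   matches a 30 arc-second (~1 km) grid.
#' @param valid_mask logical matrix; `FALSE` marks cells excluded from all
#'   modelling, projection and counting (e.g. sea or missing data). Defaults
#'   to all cells valid. Cells where any variable or the elevation is `NA`
#'   are forced invalid.
#' @return an object of class `climate_stack`.
#' @export
climate_stack <- function(variables, elevation, west, north,
                          cell_size = 0.0083, valid_mask = NULL) {
  if (!is.list(variables) || length(variables) == 0L ||
      is.null(names(variables)) || anyDuplicated(names(variables))) {
    abort_bryoclim("`variables` must be a non-empty list with unique names.")
  }
  dims <- dim(elevation)
  for (nm in names(variables)) {
    if (!identical(dim(variables[[nm]]), dims)) {
      abort_bryoclim(sprintf("grid '%s' does not match the elevation grid shape.", nm))
    }
  }
  if (!is.numeric(cell_size) || cell_size <= 0) {
    abort_bryoclim("`cell_size` must be a positive number of degrees.")
  }
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, dims[1], dims[2])
  if (!identical(dim(valid_mask), dims)) {
    abort_bryoclim("`valid_mask` does not match the grid shape.")
  }
  missing_any <- Reduce(`|`, lapply(variables, is.na), is.na(elevation))
  valid_mask <- valid_mask & !missing_any
  structure(
    list(
      variables = variables,
      elevation = elevation,
      west = west, north = north,
      cell_size = cell_size,
      n_rows = dims[1], n_cols = dims[2],
      valid_mask = valid_mask
    ),
    class = "climate_stack"
  )
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf(
    "<climate_stack> %d x %d cells @ %g deg, %d variables (%s), %d valid cells\n",
    x$n_rows, x$n_cols, x$cell_size, length(x$variables),
    paste(names(x$variables), collapse = ", "), sum(x$valid_mask)
  ))
  invisible(x)
}

#' Region labels for a gridded landscape
#'
#' Per-cell island / archipelago / continent labels on the same grid as a
#' [climate_stack()]. Island ids are positive integers (0 = not an island);
#' every island belongs to an archipelago.
#'
#' @param island_id integer matrix, 0 where the cell is not part of an island.
#' @param archipelago character matrix (`NA` off-island) naming the
#'   archipelago of each island cell.
#' @param continent logical matrix flagging continental land cells.
#' @return an object of class `region_mask`.
#' @export
region_mask <- function(island_id, archipelago, continent) {
  dims <- dim(island_id)
  if (!identical(dim(archipelago), dims) || !identical(dim(continent), dims)) {
    abort_bryoclim("region grids must share one shape.")
  }
  if (any(island_id > 0 & is.na(archipelago))) {
    abort_bryoclim("every island cell must carry an archipelago label.")
  }
  structure(
    list(
      island_id = island_id,
      archipelago = archipelago,
      continent = continent,
      n_islands = length(setdiff(unique(as.vector(island_id)), 0L))
    ),
    class = "region_mask"
  )
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf(
    "<region_mask> %d islands in %d archipelagos; %d island cells, %d continent cells\n",
    x$n_islands, length(unique(stats::na.omit(as.vector(x$archipelago)))),
    sum(x$island_id > 0), sum(x$continent)
  ))
  invisible(x)
}

#' Extract environmental values at cells
#'
#' Builds the environment matrix used by the modelling techniques: one row per
#' cell, one column per requested variable.
#'
#' @param stack a [climate_stack()].
#' @param cells data frame with integer columns `row` and `col`.
#' @param vars variable names to extract (default: all).
#' @return numeric matrix, `nrow(cells)` x `length(vars)`.
#' @export
env_at_cells <- function(stack, cells, vars = names(stack$variables)) {
  missing_vars <- setdiff(vars, names(stack$variables))
  if (length(missing_vars) > 0L) {
    abort_bryoclim(sprintf("variable(s) not in stack: %s",
                           paste(missing_vars, collapse = ", ")))
  }
  idx <- cbind(cells$row, cells$col)
  out <- vapply(vars, function(v) stack$variables[[v]][idx], numeric(nrow(idx)))
  out <- matrix(out, nrow = nrow(idx), dimnames = list(NULL, vars))
  out
}

#' All valid cells of a stack as a tibble
#'
#' @param stack a [climate_stack()].
#' @return tibble with columns `row`, `col`.
#' @export
valid_cells <- function(stack) {
  idx <- which(stack$valid_mask, arr.ind = TRUE)
  tibble::tibble(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]))
}
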
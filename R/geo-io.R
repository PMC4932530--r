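#' Convert longitude/latitude to grid cell indices
#'
#' Cells are addressed as (row, col) with row 1 at the northern edge. A point
#' on an edge shared by two cells belongs to the cell to its west (vertical
#' edges) or north (horizontal edges); the grid's own west and north outer
#' edges belong to the first column and row, so the origin corner maps to
#' cell (1, 1).
#'
#' @param lon,lat numeric vectors of coordinates (degrees), recycled to a
#'   common length.
#' @param west,north,cell_size geotransform of the grid (see
#'   [climate_stack()]).
#' @param n_rows,n_cols grid extent, used for bounds checking.
#' @return tibble with integer columns `row`, `col`.
#' @export
lonlat_to_cell <- function(lon, lat, west, north, cell_size, n_rows, n_cols) {
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  east <- west + n_cols * cell_size
  south <- north - n_rows * cell_size
  bad <- lon < west | lon > east | lat < south | lat > north
  if (any(bad)) {
    abort_bryoclim(sprintf("%d point(s) outside the grid bounds.", sum(bad)))
  }
  col <- pmax(1L, as.integer(ceiling((lon - west) / cell_size)))
  row <- pmax(1L, as.integer(ceiling((north - lat) / cell_size)))
  tibble::tibble(row = pmin(row, n_rows), col = pmin(col, n_cols))
}

#' Convert cell indices to cell-centre coordinates
#'
#' @param row,col integer vectors of cell indices.
#' @inheritParams lonlat_to_cell
#' @return tibble with columns `lon`, `lat` at cell centres.
#' @export
cell_to_lonlat <- function(row, col, west, north, cell_size) {
  tibble::tibble(
    lon = west + (col - 0.5) * cell_size,
    lat = north - (row - 0.5) * cell_size
  )
}

#' Write a grid as an ESRI ASCII raster
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces doubles bit-exactly. `NA` cells are written as the NODATA code.
#'
#' @param grid numeric matrix (row 1 = north).
#' @param path output file path (conventionally `.asc`).
#' @param west,north,cell_size geotransform.
#' @param nodata NODATA code (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, west, north, cell_size, nodata = -9999) {
  n_rows <- nrow(grid); n_cols <- ncol(grid)
  header <- c(
    sprintf("ncols %d", n_cols),
    sprintf("nrows %d", n_rows),
    sprintf("xllcorner %.17g", west),
    sprintf("yllcorner %.17g", north - n_rows * cell_size),
    sprintf("cellsize %.17g", cell_size),
    sprintf("NODATA_value %.17g", nodata)
  )
  vals <- grid
  vals[is.na(vals)] <- nodata
  body <- apply(vals, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file path.
#' @return list with `grid` (numeric matrix, NODATA folded to `NA`), `west`,
#'   `north`, `cell_size`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  needed <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(needed %in% names(hdr))) {
    abort_bryoclim(sprintf("'%s' is not an ESRI ASCII grid (incomplete header).", path))
  }
  n_rows <- as.integer(hdr$nrows); n_cols <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != n_rows * n_cols) {
    abort_bryoclim(sprintf("'%s': expected %d values, found %d.",
                           path, n_rows * n_cols, length(vals)))
  }
  grid <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) grid[grid == hdr$nodata_value] <- NA_real_
  list(
    grid = grid,
    west = hdr$xllcorner,
    north = hdr$yllcorner + n_rows * hdr$cellsize,
    cell_size = hdr$cellsize
  )
}

#' Load co-registered rasters into a climate stack
#'
#' All rasters must share shape and geotransform (within `tol` degrees);
#' cells missing in any layer are excluded via the validity mask.
#'
#' @param variable_paths named character vector of raster paths, one per
#'   climate variable.
#' @param elevation_path path of the elevation raster.
#' @param tol geotransform agreement tolerance in degrees.
#' @return a [climate_stack()].
#' @export
load_stack <- function(variable_paths, elevation_path, tol = 1e-9) {
  if (is.null(names(variable_paths)) || any(names(variable_paths) == "")) {
    abort_bryoclim("`variable_paths` must be a fully named vector.")
  }
  ref <- read_ascii_grid(elevation_path)
  layers <- lapply(variable_paths, read_ascii_grid)
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!identical(dim(l$grid), dim(ref$grid))) {
      abort_bryoclim(sprintf("layer '%s' shape differs from the elevation grid.", nm))
    }
    if (abs(l$west - ref$west) > tol || abs(l$north - ref$north) > tol ||
        abs(l$cell_size - ref$cell_size) > tol) {
      abort_bryoclim(sprintf("layer '%s' geotransform differs from the elevation grid.", nm))
    }
  }
  climate_stack(
    variables = lapply(layers, `[[`, "grid"),
    elevation = ref$grid,
    west = ref$west, north = ref$north, cell_size = ref$cell_size
  )
}

#' Read and write occurrence tables
#'
#' Occurrence CSVs must carry a `species`, `lon`, `lat` header.
#'
#' @param path CSV file path.
#' @return `read_occurrences()`: tibble with columns `species`, `lon`, `lat`.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "lon", "lat") %in% names(df))) {
    abort_bryoclim(sprintf("'%s' must have columns species, lon, lat.", path))
  }
  tibble::as_tibble(df[, c("species", "lon", "lat")])
}

#' @rdname read_occurrences
#' @param records data frame with columns `species`, `lon`, `lat`.
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read and write protected-area polygons as GeoJSON
#'
#' @param pa a `protected_areas` object (see [generate_protected_areas()]).
#' @param path GeoJSON file path.
#' @return `read_protected_areas()`: a `protected_areas` object.
#' @export
write_protected_areas <- function(pa, path) {
  features <- lapply(pa$polygons, function(p) {
    ring <- rbind(p$coords, p$coords[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(id = p$id),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(i) unname(ring[i, ])))
      )
    )
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protected_areas
#' @export
read_protected_areas <- function(path) {
  gj <- jsonlite::read_json(path)
  polygons <- lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], function(pt) {
      c(lon = pt[[1]], lat = pt[[2]])
    }))
    # drop the closing vertex duplicated by the GeoJSON ring convention
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ])) {
      ring <- ring[-nrow(ring), , drop = FALSE]
    }
    list(id = f$properties$id, coords = ring)
  })
  structure(list(polygons = polygons), class = "protected_areas")
}
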
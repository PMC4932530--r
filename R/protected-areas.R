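#' Test points against a polygon
#'
#' Even-odd (ray casting) point-in-polygon test, vectorized over points.
#' Points exactly on an edge may fall on either side; all package uses go
#' through area fractions, where edge cases are immaterial.
#'
#' @param px,py point coordinates.
#' @param coords two-column matrix of polygon vertices (unclosed ring).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, coords) {
  n <- nrow(coords)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- coords[i, 1]; yi <- coords[i, 2]
    xj <- coords[j, 1]; yj <- coords[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Sub-grid sample points (subdiv x subdiv per cell) for the given cells;
# returns list(px, py, cell_index).
cell_subpoints <- function(cells, stack, subdiv) {
  u <- (seq_len(subdiv) - 0.5) / subdiv
  offx <- rep(u, times = subdiv)
  offy <- rep(u, each = subdiv)
  k <- subdiv^2
  n <- nrow(cells)
  cw <- stack$cell_size
  west_edge <- stack$west + (cells$col - 1) * cw
  north_edge <- stack$north - (cells$row - 1) * cw
  list(
    px = rep(west_edge, each = k) + rep(offx, times = n) * cw,
    py = rep(north_edge, each = k) - rep(offy, times = n) * cw,
    cell = rep(seq_len(n), each = k)
  )
}

#' Fraction of each cell covered by protected-area polygons
#'
#' Coverage of the union of polygons is estimated per cell from a regular
#' `subdiv` x `subdiv` grid of sample points, giving a resolution of
#' `1/subdiv^2` in the covered fraction.
#'
#' @param pa a `protected_areas` object.
#' @param stack a [climate_stack()] supplying the geotransform.
#' @param cells tibble with `row`, `col` of the cells to evaluate.
#' @param subdiv sub-sampling density per cell side (default 10).
#' @return numeric vector of covered fractions in \[0, 1\], one per cell.
#' @export
protected_fraction <- function(pa, stack, cells, subdiv = 10) {
  if (nrow(cells) == 0L) return(numeric(0))
  sp <- cell_subpoints(cells, stack, subdiv)
  covered <- rep(FALSE, length(sp$px))
  for (p in pa$polygons) {
    bb <- apply(p$coords, 2, range)
    cand <- which(!covered &
                    sp$px >= bb[1, 1] & sp$px <= bb[2, 1] &
                    sp$py >= bb[1, 2] & sp$py <= bb[2, 2])
    if (length(cand) == 0L) next
    covered[cand] <- point_in_polygon(sp$px[cand], sp$py[cand], p$coords)
  }
  as.numeric(tapply(covered, sp$cell, mean))
}

#' Generate synthetic protected-area polygons
#'
#' Places random axis-aligned rectangular reserves centred on island cells
#' until the union covers approximately the requested fraction of island land
#' area. Requests of 0.95 or more are capped: each island is wrapped in a
#' single bounding-box reserve, saturating coverage.
#'
#' @param mask a [region_mask()] with at least one island.
#' @param stack the matching [climate_stack()].
#' @param fraction target covered fraction of island land area, in (0, 1).
#' @param seed integer seed; identical seeds give identical polygons.
#' @param subdiv sub-sampling density used to track covered area during
#'   generation.
#' @return a `protected_areas` object: list of polygons, each with an `id`
#'   and an unclosed ring `coords` (lon/lat matrix).
#' @export
generate_protected_areas <- function(mask, stack, fraction, seed, subdiv = 5) {
  if (fraction <= 0 || fraction >= 1) {
    abort_bryoclim("`fraction` must lie strictly between 0 and 1.")
  }
  island_cells <- which(mask$island_id > 0, arr.ind = TRUE)
  if (nrow(island_cells) == 0L) abort_bryoclim("the landscape has no islands.")
  cells <- tibble::tibble(row = island_cells[, 1], col = island_cells[, 2])
  cw <- stack$cell_size

  make_pa <- function(polys) {
    structure(list(polygons = polys), class = "protected_areas")
  }

  if (fraction >= 0.95) {
    polys <- lapply(sort(setdiff(unique(as.vector(mask$island_id)), 0L)), function(i) {
      idx <- which(mask$island_id == i, arr.ind = TRUE)
      rmin <- min(idx[, 1]); rmax <- max(idx[, 1])
      cmin <- min(idx[, 2]); cmax <- max(idx[, 2])
      w <- stack$west + (cmin - 1) * cw
      e <- stack$west + cmax * cw
      n <- stack$north - (rmin - 1) * cw
      s <- stack$north - rmax * cw
      list(id = sprintf("pa_island_%d", i),
           coords = cbind(lon = c(w, e, e, w), lat = c(s, s, n, n)))
    })
    return(make_pa(polys))
  }

  sp <- cell_subpoints(cells, stack, subdiv)
  covered <- rep(FALSE, length(sp$px))
  polys <- list()
  with_seed(seed, {
    iter <- 0L
    while (mean(covered) < fraction && iter < 5000L) {
      iter <- iter + 1L
      i <- sample.int(nrow(cells), 1L)
      cx <- stack$west + (cells$col[i] - 0.5) * cw
      cy <- stack$north - (cells$row[i] - 0.5) * cw
      hw <- stats::runif(1, 1, 4) * cw
      hh <- stats::runif(1, 1, 4) * cw
      coords <- cbind(lon = c(cx - hw, cx + hw, cx + hw, cx - hw),
                      lat = c(cy - hh, cy - hh, cy + hh, cy + hh))
      polys[[length(polys) + 1L]] <- list(id = sprintf("pa_%d", length(polys) + 1L),
                                          coords = coords)
      hit <- sp$px >= cx - hw & sp$px <= cx + hw &
        sp$py >= cy - hh & sp$py <= cy + hh
      covered <- covered | hit
    }
  })
  make_pa(polys)
}

#' @export
print.protected_areas <- function(x, ...) {
  cat(sprintf("<protected_areas> %d polygons\n", length(x$polygons)))
  invisible(x)
}

#' Tidy a protected-area set into a vertex table
#'
#' @param x a `protected_areas` object.
#' @param ... unused.
#' @return tibble with columns `id`, `lon`, `lat`, one row per vertex.
#' @export
tidy.protected_areas <- function(x, ...) {
  purrr::map_dfr(x$polygons, function(p) {
    tibble::tibble(id = p$id, lon = p$coords[, 1], lat = p$coords[, 2])
  })
}
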
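test_that("generate_landscape honours the spec geometry", {
  ls <- small_landscape()
  stack <- ls$stack; mask <- ls$mask

  expect_s3_class(stack, "climate_stack")
  expect_identical(stack$n_rows, 120L)
  expect_identical(stack$n_cols, 120L)
  expect_identical(sort(names(stack$variables)),
                   sort(c("bio5", "bio6", "bio13", "bio14", "bio18")))

  # exactly the requested island count, clustered into the requested groups
  expect_identical(mask$n_islands, 4L)
  expect_identical(sort(unique(stats::na.omit(as.vector(mask$archipelago)))),
                   c("archipelago_A", "archipelago_B"))
  # continent occupies the easternmost 20 columns and nothing else
  expect_true(all(mask$continent[, 101:120]))
  expect_false(any(mask$continent[, 1:100]))
  # island and continent cells are disjoint and together are the land mask
  expect_false(any(mask$island_id > 0 & mask$continent))
  expect_identical(unname(stack$valid_mask),
                   unname(mask$island_id > 0 | mask$continent))
})

test_that("each labelled island is 4-connected and separated from the others", {
  ls <- small_landscape()
  mask <- ls$mask
  # relabel from scratch with an independent two-pass union-find style check:
  # every pair of 4-adjacent island cells must share an id, and every id's
  # cells must be reachable from one another (checked via our own BFS)
  ids <- sort(setdiff(unique(as.vector(mask$island_id)), 0L))
  nr <- nrow(mask$island_id); nc <- ncol(mask$island_id)
  for (id in ids) {
    cells <- which(mask$island_id == id)
    # BFS from the first cell over the island's own cells
    seen <- logical(nr * nc)
    queue <- cells[1]; seen[cells[1]] <- TRUE
    memb <- logical(nr * nc); memb[cells] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1) %% nr + 1; c <- (cur - 1) %/% nr + 1
      for (d in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))) {
        if (d[1] < 1 || d[1] > nr || d[2] < 1 || d[2] > nc) next
        i <- (d[2] - 1) * nr + d[1]
        if (memb[i] && !seen[i]) { seen[i] <- TRUE; queue <- c(queue, i) }
      }
    }
    expect_true(all(seen[cells]))
  }
  # no two different islands touch (4-adjacency)
  ii <- mask$island_id
  horiz <- ii[, -1] > 0 & ii[, -nc] > 0 & ii[, -1] != ii[, -nc]
  vert <- ii[-1, ] > 0 & ii[-nr, ] > 0 & ii[-1, ] != ii[-nr, ]
  expect_false(any(horiz) || any(vert))
})

test_that("climate variables follow the declared lapse rates", {
  ls <- noise_free_landscape()  # zero noise: exact linear functions
  stack <- ls$stack
  elev <- stack$elevation
  expect_equal(stack$variables$bio5, 26.5 - 0.006 * elev)
  expect_equal(stack$variables$bio13, 90 + 0.08 * elev)
})

test_that("autocorrelated noise fields are standardized and autocorrelated", {
  f <- withr::with_seed(5, bryoclim:::autocorrelated_field(150, 150, 6))
  expect_equal(mean(f), 0, tolerance = 1e-12)
  expect_equal(stats::sd(as.vector(f)), 1, tolerance = 1e-12)
  # lag-1 correlation along rows far exceeds lag-20
  lag_cor <- function(k) stats::cor(as.vector(f[, 1:(150 - k)]),
                                    as.vector(f[, (1 + k):150]))
  expect_gt(lag_cor(1), 0.8)
  expect_lt(abs(lag_cor(20)), 0.4)
  expect_gt(lag_cor(1), lag_cor(20) + 0.3)
})

test_that("landscape generation is a pure function of the spec", {
  spec <- landscape_spec(seed = 13, n_rows = 80, n_cols = 80,
                         n_islands = 3, n_archipelagos = 2)
  a <- generate_landscape(spec)
  b <- generate_landscape(spec)
  expect_identical(a$stack$variables, b$stack$variables)
  expect_identical(a$stack$elevation, b$stack$elevation)
  expect_identical(a$mask$island_id, b$mask$island_id)
  # and does not disturb the caller's RNG stream
  withr::with_seed(99, {
    before <- runif(1)
  })
  withr::with_seed(99, {
    invisible(generate_landscape(spec))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("landscape_spec validates its inputs", {
  expect_error(landscape_spec(max_elevation = 40, sea_level = 50), "max_elevation")
  expect_error(landscape_spec(cell_size = 0), "cell_size")
  expect_error(
    landscape_spec(variable_defs = list(variable_def("a", 1), variable_def("a", 2))),
    "unique")
  expect_error(variable_def("x", 0, autocorrelation_range = 0.5),
               "autocorrelation_range")
})

test_that("scenarios transform exactly the named variables", {
  ls <- small_landscape()
  stack <- ls$stack
  delta <- scenario_delta("warmdry",
                          offsets = c(bio5 = 2),
                          factors = c(bio13 = 0.8))
  out <- apply_scenario(stack, delta)
  expect_equal(out$variables$bio5, stack$variables$bio5 + 2)
  expect_equal(out$variables$bio13, stack$variables$bio13 * 0.8)
  # untouched variables, elevation, mask and geotransform are preserved
  expect_identical(out$variables$bio6, stack$variables$bio6)
  expect_identical(out$elevation, stack$elevation)
  expect_identical(out$valid_mask, stack$valid_mask)
  expect_identical(out$west, stack$west)

  # identity scenario is a no-op
  ident <- apply_scenario(stack, scenario_delta("none"))
  expect_identical(ident$variables, stack$variables)

  # factor and offset combine as value * factor + offset
  both <- apply_scenario(stack, scenario_delta("b", offsets = c(bio5 = 1),
                                               factors = c(bio5 = 1.1)))
  expect_equal(both$variables$bio5, stack$variables$bio5 * 1.1 + 1)

  expect_error(apply_scenario(stack, scenario_delta("x", offsets = c(zzz = 1))),
               "zzz")
  expect_error(scenario_delta("x", factors = c(bio5 = -1)), "> 0")
})

test_that("per-archipelago offsets apply only inside the archipelago", {
  ls <- small_landscape()
  delta <- scenario_delta("regional",
                          region_offsets = list(archipelago_A = c(bio5 = 3)))
  expect_error(apply_scenario(ls$stack, delta), "region_mask")
  out <- apply_scenario(ls$stack, delta, ls$mask)
  in_a <- !is.na(ls$mask$archipelago) & ls$mask$archipelago == "archipelago_A"
  expect_equal(out$variables$bio5[in_a], ls$stack$variables$bio5[in_a] + 3)
  expect_identical(out$variables$bio5[!in_a], ls$stack$variables$bio5[!in_a])
})

test_that("true_suitability peaks at the optimum and rescales to max 1", {
  stack <- tiny_stack()
  sp <- virtual_species("v", list(tmax = c(23.5, 0.5)))
  s <- true_suitability(sp, stack)
  expect_equal(max(s, na.rm = TRUE), 1)
  # suitability decreases with distance from the optimum in tmax
  ord <- order(abs(as.vector(stack$variables$tmax) - 23.5))
  expect_true(all(diff(s[ord]) <= 1e-12))
  # multi-variable responses multiply
  sp2 <- virtual_species("v2", list(tmax = c(23.5, 0.5), pwet = c(80, 10)))
  s2_raw <- exp(-((stack$variables$tmax - 23.5)^2) / (2 * 0.5^2)) *
    exp(-((stack$variables$pwet - 80)^2) / (2 * 10^2))
  expect_equal(true_suitability(sp2, stack), s2_raw / max(s2_raw))
  expect_error(true_suitability(virtual_species("v3", list(nope = c(1, 1))), stack),
               "nope")
  expect_error(virtual_species("v4", list(tmax = c(1, 0))), "breadth")
})

test_that("sample_occurrences draws suitability-weighted, deterministic samples", {
  ls <- small_landscape()
  sp <- virtual_species("sp", list(bio5 = c(22, 1.5)))
  occ1 <- sample_occurrences(sp, ls$stack, 150, seed = 3, mask = ls$mask)
  occ2 <- sample_occurrences(sp, ls$stack, 150, seed = 3, mask = ls$mask)
  expect_identical(occ1, occ2)
  expect_identical(nrow(occ1), 150L)
  expect_equal(attr(occ1, "n_raw"), 150)
  # no duplicate cells (sampling is without replacement)
  expect_identical(nrow(dplyr::distinct(occ1, row, col)), 150L)
  # every draw is on an island
  expect_true(all(ls$mask$island_id[cbind(occ1$row, occ1$col)] > 0))
  # occurrences sit in better-than-average habitat
  s <- true_suitability(sp, ls$stack)
  island_mean <- mean(s[ls$mask$island_id > 0], na.rm = TRUE)
  expect_gt(mean(s[cbind(occ1$row, occ1$col)]), island_mean)
  # asking for more occurrences than suitable cells errors
  narrow <- virtual_species("n", list(bio5 = c(-500, 0.01)))
  expect_error(sample_occurrences(narrow, ls$stack, 10, seed = 1),
               "zero suitability|positive suitability")
})
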
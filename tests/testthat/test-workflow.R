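# A reduced configuration keeps the end-to-end tests fast while exercising
# every pipeline stage.
small_config <- function(seed = 5) {
  cfg <- default_config(seed = seed)
  cfg$landscape <- list(n_rows = 120, n_cols = 120, cell_size = 0.0083,
                        n_islands = 4, n_archipelagos = 2, sea_level = 50,
                        continent_cols = 20)
  cfg$n_occurrences <- 120
  cfg$n_background <- 400
  cfg$n_trees <- 150
  cfg$reps <- 5
  cfg$screen_sample <- 4000
  cfg
}

small_run <- function() {
  cached("small_run", suppressMessages(run_pipeline(small_config())))
}

test_that("fit_species_ensemble evaluates all three techniques", {
  withr::with_seed(109, {
    pres <- cbind(v = rnorm(60, 1, 0.4), w = runif(60))
    bg <- cbind(v = rnorm(200, -0.8, 0.8), w = runif(200))
  })
  fit <- fit_species_ensemble(pres, bg, reps = 5, seed = 4, n_trees = 100)
  expect_identical(fit$evaluation$technique,
                   c("envelope", "maxent_like", "random_forest"))
  expect_identical(nrow(fit$evaluation), 3L)
  expect_true(all(fit$evaluation$mean_auc >= 0 & fit$evaluation$mean_auc <= 1))
  # the consensus contains exactly the passing techniques
  if (any(fit$evaluation$pass)) {
    expect_s3_class(fit$ensemble, "sdm_ensemble")
    expect_identical(sort(unname(fit$ensemble$techniques)),
                     sort(fit$evaluation$technique[fit$evaluation$pass]))
    expect_equal(sum(fit$ensemble$weights), 1)
  } else {
    expect_null(fit$ensemble)
  }
  # deterministic
  fit2 <- fit_species_ensemble(pres, bg, reps = 5, seed = 4, n_trees = 100)
  expect_identical(fit$evaluation, fit2$evaluation)
})

test_that("the pipeline produces a coherent cross-referenced result", {
  res <- small_run()
  cfg <- res$config
  sp_names <- vapply(cfg$species, `[[`, character(1), "name")

  # screening respects the threshold on its own sample
  cm <- res$screen$cor_matrix[res$screen$retained, res$screen$retained]
  expect_true(all(abs(cm[upper.tri(cm)]) <= cfg$thresholds$r_max))

  # occurrences: thinned, on islands, within the record rule for modelled spp.
  for (nm in names(res$occurrences)) {
    occ <- res$occurrences[[nm]]
    expect_identical(nrow(dplyr::distinct(occ, row, col)), nrow(occ))
    expect_true(all(res$mask$island_id[cbind(occ$row, occ$col)] > 0))
  }
  modelled <- names(res$ensembles)
  expect_true(length(modelled) >= 1)
  expect_true(all(modelled %in% sp_names))
  expect_identical(sort(unique(c(modelled, names(res$excluded)))),
                   sort(unique(sp_names)))

  # evaluation table covers 3 techniques per species that reached evaluation
  expect_true(all(table(res$evaluation$species) == 3))

  # thresholds respect the 5% omission budget against the stored occurrences
  for (i in seq_len(nrow(res$thresholds))) {
    nm <- res$thresholds$species[i]
    expect_lte(res$thresholds$omission[i], cfg$thresholds$error_rate)
    occ <- res$occurrences[[nm]]
    surf <- predict_surface(res$ensembles[[nm]], res$stack)
    scores <- surf$grid[cbind(occ$row, occ$col)]
    below <- mean(scores < res$thresholds$threshold[i])
    expect_equal(below, res$thresholds$omission[i])
  }

  # report counts equal direct recounts from the stored binary ranges
  for (i in seq_len(nrow(res$report))) {
    rw <- res$report[i, ]
    rng_p <- res$ranges[[rw$species]]$present
    rng_f <- res$ranges[[rw$species]][[rw$scenario]]
    sel <- switch(rw$region,
      macaronesia = res$mask$island_id > 0,
      continent = res$mask$continent,
      !is.na(res$mask$archipelago) & res$mask$archipelago == rw$region)
    expect_identical(rw$n_present, sum(rng_p$grid & sel))
    expect_identical(rw$n_future, sum(rng_f$grid & sel))
    expect_equal(rw$pct_remaining, pct_remaining(rw$n_present, rw$n_future))
  }

  # ranges never include invalid cells, and regions partition macaronesia
  for (nm in modelled) {
    for (rg in res$ranges[[nm]]) {
      expect_false(any(rg$grid & !res$stack$valid_mask))
    }
  }
  arch_regions <- setdiff(unique(res$report$region), c("macaronesia", "continent"))
  mac <- res$report[res$report$region == "macaronesia", ]
  for (i in seq_len(nrow(mac))) {
    parts <- res$report[res$report$species == mac$species[i] &
                          res$report$scenario == mac$scenario[i] &
                          res$report$region %in% arch_regions, ]
    expect_identical(sum(parts$n_present), mac$n_present[i])
    expect_identical(sum(parts$n_future), mac$n_future[i])
  }

  # summary rows agree with an independent aggregation
  for (i in seq_len(nrow(res$summary))) {
    sc <- res$summary$scenario[i]
    sub <- mac[mac$scenario == sc, ]
    expect_identical(res$summary$n_extinct[i],
                     sum(sub$n_present > 0 & sub$n_future == 0))
    expect_equal(res$summary$mean_pct_remaining[i],
                 mean(sub$pct_remaining, na.rm = TRUE))
  }

  # elevation and PA columns only on macaronesia rows
  expect_true(all(is.na(res$report$pa_coverage_present[res$report$region != "macaronesia"])))
  expect_true(all(!is.na(mac$pa_coverage_present)))
  expect_true(all(mac$pa_coverage_present >= 0 & mac$pa_coverage_present <= 100))
})

test_that("the pipeline is bit-reproducible for a fixed configuration", {
  res <- small_run()
  res2 <- suppressMessages(run_pipeline(small_config()))
  expect_identical(res2$report, res$report)
  expect_identical(res2$evaluation, res$evaluation)
  expect_identical(res2$thresholds, res$thresholds)
  expect_identical(res2$summary, res$summary)
  expect_identical(res2$pa, res$pa)
  # a different master seed changes the landscape
  res3 <- suppressMessages(suppressWarnings(run_pipeline(small_config(seed = 6))))
  expect_false(identical(res3$stack$elevation, res$stack$elevation))
})

test_that("artifacts round-trip the key tables and rasters", {
  out <- withr::local_tempdir()
  res <- suppressMessages(run_pipeline(small_config(), out_dir = out))
  expect_true(all(file.exists(file.path(out, c(
    "occurrences.csv", "screening.csv", "evaluation.csv", "thresholds.csv",
    "report.csv", "archipelago_tests.csv", "summary.csv",
    "protected_areas.geojson", "manifest.json")))))
  rep_back <- utils::read.csv(file.path(out, "report.csv"))
  expect_identical(nrow(rep_back), nrow(res$report))
  expect_equal(rep_back$pct_remaining, res$report$pct_remaining)
  pa_back <- read_protected_areas(file.path(out, "protected_areas.geojson"))
  expect_identical(length(pa_back$polygons), length(res$pa$polygons))
  # a written range raster reproduces the in-memory grid
  nm <- names(res$ranges)[1]
  ras <- read_ascii_grid(file.path(out, "rasters",
                                   sprintf("%s_present_range.asc", nm)))
  expect_identical(ras$grid == 1, res$ranges[[nm]]$present$grid)
  mf <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_identical(mf$seed, 5L)
  expect_identical(mf$n_modelled, length(res$ensembles))
})

test_that("a vacuous min-records rule excludes every species with warnings", {
  cfg <- small_config()
  cfg$thresholds$min_records <- 1000
  warns <- capture_warnings(res <- suppressMessages(run_pipeline(cfg)))
  expect_identical(length(warns), length(cfg$species))
  expect_true(all(grepl("excluded", warns)))
  expect_identical(length(res$ensembles), 0L)
  expect_identical(nrow(res$report), 0L)
  expect_identical(sort(names(res$excluded)),
                   sort(vapply(cfg$species, `[[`, character(1), "name")))
  # empty-result tables keep their schema
  expect_true(all(c("species", "region", "scenario", "n_present", "n_future",
                    "pct_remaining", "status") %in% names(res$report)))
})

test_that("YAML configuration merges over the defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 9",
    "n_occurrences: 80",
    "thresholds:",
    "  min_records: 5",
    "species:",
    "- name: only_sp",
    "  responses:",
    "    bio5: [21.7, 0.8]",
    "    bio13: [150.0, 15.0]"
  ), path)
  cfg <- read_run_config(path)
  expect_identical(cfg$seed, 9L)
  expect_identical(cfg$n_occurrences, 80L)
  expect_identical(cfg$thresholds$min_records, 5L)
  # untouched defaults survive the merge
  expect_equal(cfg$thresholds$auc_min, 0.8)
  expect_equal(cfg$pa_fraction, 0.35)
  expect_identical(length(cfg$species), 1L)
  expect_identical(cfg$species[[1]]$name, "only_sp")
  expect_identical(cfg$species[[1]]$responses$bio5, c(21.7, 0.8))
  # the merged configuration is valid and runnable
  expect_identical(bryoclim:::validate_config(cfg)$seed, 9L)
})

test_that("validate_config rejects out-of-range thresholds", {
  cfg <- default_config()
  cfg$thresholds$error_rate <- 1
  expect_error(run_pipeline(cfg), "error_rate")
  cfg <- default_config()
  cfg$split <- 1
  expect_error(run_pipeline(cfg), "split")
  cfg <- default_config()
  cfg$species <- list()
  expect_error(run_pipeline(cfg), "species")
})
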
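#' Fit, evaluate and combine the three techniques for one species
#'
#' Runs the repeated-split evaluation of the climatic envelope, the
#' MaxEnt-style penalized regression and the random forest on one species'
#' presence/background environments, refits each passing technique once on
#' the full calibration data, and combines them into the AUC-weighted
#' consensus.
#'
#' @param presence_env,background_env environment matrices (named columns).
#' @param split,reps evaluation split fraction and repetitions.
#' @param seed integer seed.
#' @param auc_min,tss_min quality-filter thresholds.
#' @param regularization,n_trees technique parameters, see
#'   [technique_fitters()].
#' @return list with `ensemble` (an `sdm_ensemble` or `NULL` if no technique
#'   passed) and `evaluation` (tibble: technique, mean_auc, mean_tss, pass).
#' @export
fit_species_ensemble <- function(presence_env, background_env,
                                 split = 0.7, reps = 10, seed = 1L,
                                 auc_min = 0.8, tss_min = 0.7,
                                 regularization = 0.001, n_trees = 500) {
  fitters <- technique_fitters(regularization, n_trees)
  evals <- list(); models <- list()
  for (i in seq_along(fitters)) {
    nm <- names(fitters)[i]
    evals[[nm]] <- evaluate_technique(
      fitters[[nm]], presence_env, background_env,
      split = split, reps = reps, seed = derive_seed(seed, i),
      auc_min = auc_min, tss_min = tss_min
    )
    models[[nm]] <- fitters[[nm]](presence_env, background_env,
                                  seed = derive_seed(seed, 100L + i))
  }
  evaluation <- tibble::tibble(
    technique = names(fitters),
    mean_auc = vapply(evals, `[[`, numeric(1), "mean_auc"),
    mean_tss = vapply(evals, `[[`, numeric(1), "mean_tss"),
    pass = vapply(evals, `[[`, logical(1), "pass")
  )
  list(ensemble = build_consensus(models, evals), evaluation = evaluation)
}

#' Default pipeline configuration
#'
#' The bundled study conditions: a 200 x 200 cell landscape with six islands
#' in three archipelagos and a continental margin, three temperature- and
#' precipitation-limited virtual species sampled at 200 presence-only records
#' each, 1000 background cells, the two built-in climate scenarios, and the
#' standard thresholds (|r| <= 0.8 screening, >= 11 records, AUC >= 0.8,
#' TSS >= 0.7, 5% omission threshold, 5% protected-pixel overlap).
#'
#' @param seed master seed.
#' @return a nested configuration list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    landscape = list(
      n_rows = 200, n_cols = 200, cell_size = 0.0083,
      n_islands = 6, n_archipelagos = 3, sea_level = 50,
      continent_cols = 30
    ),
    # narrow-niche specialists whose optima are elevationally coherent
    # (optimum = base + lapse x a target elevation of 800/500/1000 m)
    species = list(
      list(name = "virtual_sp1",
           responses = list(bio5 = c(21.7, 0.6), bio13 = c(154, 14))),
      list(name = "virtual_sp2",
           responses = list(bio5 = c(23.5, 0.6), bio18 = c(65, 9))),
      list(name = "virtual_sp3",
           responses = list(bio6 = c(9.0, 0.6), bio13 = c(170, 15)))
    ),
    n_occurrences = 200,
    n_background = 1000,
    scenarios = "demo",
    pa_fraction = 0.35,
    thresholds = list(r_max = 0.8, min_records = 11, auc_min = 0.8,
                      tss_min = 0.7, error_rate = 0.05, pa_overlap = 0.05),
    reps = 10, split = 0.7,
    regularization = 0.001, n_trees = 500,
    screen_sample = 10000
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [default_config()]. Missing keys fall
#'   back to the defaults.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config(seed = cfg$seed %||% 1L)
  merge_cfg <- function(base, new) {
    for (nm in names(new)) {
      if (is.list(base[[nm]]) && is.list(new[[nm]]) && nm != "species") {
        base[[nm]] <- merge_cfg(base[[nm]], new[[nm]])
      } else {
        base[[nm]] <- new[[nm]]
      }
    }
    base
  }
  cfg <- merge_cfg(base, cfg)
  cfg$species <- lapply(cfg$species, function(sp) {
    sp$responses <- lapply(sp$responses, as.numeric)
    sp
  })
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_config <- function(config) {
  th <- config$thresholds
  if (th$r_max <= 0 || th$r_max > 1) abort_bryoclim("r_max must lie in (0, 1].")
  if (th$auc_min < 0 || th$auc_min > 1) abort_bryoclim("auc_min must lie in [0, 1].")
  if (th$tss_min < -1 || th$tss_min > 1) abort_bryoclim("tss_min must lie in [-1, 1].")
  if (th$error_rate < 0 || th$error_rate >= 1) abort_bryoclim("error_rate must lie in [0, 1).")
  if (th$pa_overlap <= 0 || th$pa_overlap > 1) abort_bryoclim("pa_overlap must lie in (0, 1].")
  if (config$split <= 0 || config$split >= 1) abort_bryoclim("split must lie in (0, 1).")
  if (length(config$species) == 0L) abort_bryoclim("at least one species is required.")
  invisible(config)
}

resolve_scenarios <- function(config) {
  if (identical(config$scenarios, "demo")) return(demo_scenarios())
  scs <- lapply(config$scenarios, function(s) {
    scenario_delta(s$label, offsets = unlist(s$offsets %||% list()),
                   factors = unlist(s$factors %||% list()),
                   region_offsets = s$region_offsets)
  })
  names(scs) <- vapply(scs, `[[`, character(1), "label")
  scs
}

count_suitable <- function(range, sel) sum(range$grid & sel)

#' Run the full modelling pipeline
#'
#' Composes all stages — simulate, prepare, fit, project, report — from a
#' single configuration: landscape generation, collinearity screening,
#' per-species occurrence sampling, thinning and the minimum-records rule,
#' three-technique evaluation and AUC-weighted consensus, present and
#' scenario projections with MESS masking and sensitivity-based
#' binarization, and the downstream range-change, elevation-shift,
#' archipelago-comparison and protected-area statistics. All randomness
#' derives from the master seed, so a rerun with the same configuration
#' reproduces every output bit-identically.
#'
#' @param config configuration list (see [default_config()]) or path of a
#'   YAML file.
#' @param out_dir optional directory; when given, rasters (ESRI ASCII), CSV
#'   tables, the protected-area GeoJSON and a manifest are written there.
#' @return (invisibly) a list: `stack`, `mask`, `screen`, `pa`,
#'   `occurrences`, `evaluation`, `thresholds`, `report` (species x region x
#'   scenario tibble), `archipelago_tests`, `summary`, `excluded`,
#'   `ensembles`, `ranges`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  validate_config(config)
  seed <- config$seed

  land_args <- config$landscape
  land_args$seed <- derive_seed(seed, 1L)
  land_args$variable_defs <- land_args$variable_defs %||% default_variable_defs()
  landscape <- do.call(landscape_spec, land_args)
  gen <- generate_landscape(landscape)
  stack <- gen$stack; mask <- gen$mask

  all_vars <- names(stack$variables)
  screen <- screen_collinearity(
    stack, all_vars, priority_order = all_vars,
    r_max = config$thresholds$r_max, n_sample = config$screen_sample,
    seed = derive_seed(seed, 2L)
  )
  vars <- screen$retained

  pa <- generate_protected_areas(mask, stack, config$pa_fraction,
                                 seed = derive_seed(seed, 3L))
  scenarios <- resolve_scenarios(config)
  future_stacks <- lapply(scenarios, apply_scenario, stack = stack, mask = mask)

  island_sel <- mask$island_id > 0
  cont_sel <- mask$continent
  archipelagos <- sort(unique(stats::na.omit(as.vector(mask$archipelago))))

  occurrences <- list(); evaluation <- list(); thresholds <- list()
  report <- list(); excluded <- list(); ensembles <- list(); ranges <- list()

  for (si in seq_along(config$species)) {
    sp_cfg <- config$species[[si]]
    sp <- virtual_species(sp_cfg$name, sp_cfg$responses)
    sp_seed <- derive_seed(seed, 1000L + si)
    raw <- sample_occurrences(sp, stack, config$n_occurrences, seed = sp_seed,
                              mask = mask)
    occ <- snap_and_thin(raw, stack)
    occurrences[[sp$name]] <- occ
    if (!passes_min_records(occ, config$thresholds$min_records)) {
      excluded[[sp$name]] <- sprintf("only %d thinned cells (< %d)",
                                     nrow(occ), config$thresholds$min_records)
      warning(sprintf("species '%s' excluded: %s", sp$name, excluded[[sp$name]]),
              call. = FALSE)
      next
    }
    bg <- sample_background(stack, config$n_background,
                            seed = derive_seed(sp_seed, 2L), exclude = occ)
    presence_env <- env_at_cells(stack, occ, vars)
    background_env <- env_at_cells(stack, bg, vars)

    fit <- fit_species_ensemble(
      presence_env, background_env,
      split = config$split, reps = config$reps, seed = derive_seed(sp_seed, 3L),
      auc_min = config$thresholds$auc_min, tss_min = config$thresholds$tss_min,
      regularization = config$regularization, n_trees = config$n_trees
    )
    evaluation[[sp$name]] <- dplyr::mutate(fit$evaluation, species = sp$name,
                                           .before = 1)
    if (is.null(fit$ensemble)) {
      excluded[[sp$name]] <- "no technique passed the AUC/TSS filter"
      next
    }
    ensembles[[sp$name]] <- fit$ensemble

    present_surface <- predict_surface(fit$ensemble, stack, sp$name, "present")
    pres_scores <- present_surface$grid[cbind(occ$row, occ$col)]
    thr <- select_threshold(pres_scores, config$thresholds$error_rate)
    thresholds[[sp$name]] <- tibble::tibble(
      species = sp$name, threshold = thr$threshold, omission = thr$omission
    )
    mess_present <- compute_mess(presence_env, stack)
    present_range <- binarize_and_mask(present_surface, thr$threshold, mess_present)
    ranges[[sp$name]] <- list(present = present_range)

    for (sc in names(scenarios)) {
      fstack <- future_stacks[[sc]]
      fsurf <- predict_surface(fit$ensemble, fstack, sp$name, sc)
      fmess <- compute_mess(presence_env, fstack)
      frange <- binarize_and_mask(fsurf, thr$threshold, fmess)
      ranges[[sp$name]][[sc]] <- frange

      shift <- elevation_shift(present_range, frange, stack$elevation, mask)
      test <- glance(shift)
      pa_p <- pa_coverage(present_range, pa, stack,
                          config$thresholds$pa_overlap)
      pa_f <- pa_coverage(frange, pa, stack, config$thresholds$pa_overlap)

      regions <- c(list(macaronesia = island_sel, continent = cont_sel),
                   stats::setNames(
                     lapply(archipelagos, function(a)
                       !is.na(mask$archipelago) & mask$archipelago == a),
                     archipelagos))
      for (rg in names(regions)) {
        sel <- regions[[rg]]
        if (!any(sel)) next
        np <- count_suitable(present_range, sel)
        nf <- count_suitable(frange, sel)
        report[[length(report) + 1L]] <- tibble::tibble(
          species = sp$name, region = rg, scenario = sc,
          n_present = np, n_future = nf,
          mean_elev_present = if (rg == "macaronesia") mean(stack$elevation[present_range$grid & sel]) else NA_real_,
          mean_elev_future = if (rg == "macaronesia" && nf > 0) mean(stack$elevation[frange$grid & sel]) else NA_real_,
          t_stat = if (rg == "macaronesia") test$t_stat else NA_real_,
          p_value = if (rg == "macaronesia") test$p_value else NA_real_,
          pa_coverage_present = if (rg == "macaronesia") pa_p else NA_real_,
          pa_coverage_future = if (rg == "macaronesia") pa_f else NA_real_
        )
      }
    }
  }

  report <- if (length(report) > 0) {
    range_change_table(dplyr::bind_rows(report))
  } else {
    tibble::tibble(species = character(), region = character(),
                   scenario = character(), n_present = integer(),
                   n_future = integer(), pct_remaining = numeric(),
                   status = factor(character(), levels = status_levels))
  }
  evaluation <- if (length(evaluation) > 0) dplyr::bind_rows(evaluation) else
    tibble::tibble(species = character(), technique = character(),
                   mean_auc = numeric(), mean_tss = numeric(), pass = logical())
  thresholds <- if (length(thresholds) > 0) dplyr::bind_rows(thresholds) else
    tibble::tibble(species = character(), threshold = numeric(), omission = numeric())

  archipelago_tests <- list()
  if (nrow(report) > 0) {
    for (sc in unique(report$scenario)) {
      arch_rows <- report[report$scenario == sc & report$region %in% archipelagos &
                            !is.na(report$pct_remaining), ]
      if (nrow(arch_rows) > 0) {
        tab <- table(arch_rows$region)
        if (length(tab) >= 2 && all(tab >= 2)) {
          cmp <- compare_archipelagos(tibble::tibble(
            archipelago = arch_rows$region, value = arch_rows$pct_remaining))
          archipelago_tests[[sc]] <- dplyr::mutate(glance(cmp), scenario = sc,
                                                   .before = 1)
        }
      }
    }
  }
  archipelago_tests <- if (length(archipelago_tests) > 0) {
    dplyr::bind_rows(archipelago_tests)
  } else {
    tibble::tibble(scenario = character(), h = numeric(), df = numeric(),
                   p_value = numeric())
  }

  summary_tbl <- report |>
    dplyr::filter(.data$region == "macaronesia") |>
    dplyr::group_by(.data$scenario) |>
    dplyr::group_modify(~ summarize_range_changes(.x)) |>
    dplyr::ungroup()

  result <- list(
    config = config, stack = stack, mask = mask, screen = screen, pa = pa,
    occurrences = occurrences, evaluation = evaluation,
    thresholds = thresholds, report = report,
    archipelago_tests = archipelago_tests, summary = summary_tbl,
    excluded = excluded, ensembles = ensembles, ranges = ranges
  )
  if (!is.null(out_dir)) write_artifacts(result, out_dir)
  invisible(result)
}

# Serialize a pipeline result to a reproducible artifact directory.
write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "rasters"), showWarnings = FALSE)
  stack <- result$stack
  gt <- list(west = stack$west, north = stack$north, cell_size = stack$cell_size)

  occ_all <- dplyr::bind_rows(result$occurrences)
  utils::write.csv(occ_all[, c("species", "lon", "lat")],
                   file.path(out_dir, "occurrences.csv"), row.names = FALSE)
  utils::write.csv(result$screen$dropped, file.path(out_dir, "screening.csv"),
                   row.names = FALSE)
  utils::write.csv(result$evaluation, file.path(out_dir, "evaluation.csv"),
                   row.names = FALSE)
  utils::write.csv(result$thresholds, file.path(out_dir, "thresholds.csv"),
                   row.names = FALSE)
  utils::write.csv(result$report, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  utils::write.csv(result$archipelago_tests,
                   file.path(out_dir, "archipelago_tests.csv"), row.names = FALSE)
  utils::write.csv(result$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  write_protected_areas(result$pa, file.path(out_dir, "protected_areas.geojson"))
  for (sp in names(result$ranges)) {
    for (sc in names(result$ranges[[sp]])) {
      r <- result$ranges[[sp]][[sc]]
      write_ascii_grid(r$grid * 1, file.path(out_dir, "rasters",
                                             sprintf("%s_%s_range.asc", sp, sc)),
                       gt$west, gt$north, gt$cell_size)
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("bryoclim")),
    seed = result$config$seed,
    config_hash = rlang::hash(result$config),
    n_species = length(result$config$species),
    n_modelled = length(result$ensembles),
    retained_variables = result$screen$retained
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
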
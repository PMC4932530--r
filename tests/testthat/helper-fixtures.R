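# Shared fixtures, built in code. The cache avoids regenerating the same
# landscape across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small hand-built stack: two variables on a 6 x 8 grid with simple gradients.
tiny_stack <- function(na_cells = NULL) {
  nr <- 6; nc <- 8
  elev <- matrix(rep(seq(0, 500, length.out = nr), nc), nr, nc)
  t_var <- 25 - 0.006 * elev
  p_var <- matrix(rep(seq(50, 120, length.out = nc), each = nr), nr, nc)
  if (!is.null(na_cells)) {
    for (cell in na_cells) t_var[cell[1], cell[2]] <- NA_real_
  }
  climate_stack(list(tmax = t_var, pwet = p_var), elev,
                west = -10, north = 40, cell_size = 0.1)
}

# Medium synthetic landscape with islands, continent and default variables.
small_landscape <- function() {
  cached("small_landscape", {
    spec <- landscape_spec(seed = 7, n_rows = 120, n_cols = 120,
                           n_islands = 4, n_archipelagos = 2,
                           continent_cols = 20)
    generate_landscape(spec)
  })
}

# Noise-free landscape: climate is a pure function of elevation.
noise_free_landscape <- function() {
  cached("noise_free_landscape", {
    defs <- list(
      variable_def("bio5", 26.5, -0.006, 0, 5),
      variable_def("bio13", 90, 0.08, 0, 5)
    )
    spec <- landscape_spec(seed = 11, n_rows = 100, n_cols = 100,
                           n_islands = 4, n_archipelagos = 2,
                           variable_defs = defs)
    generate_landscape(spec)
  })
}

# Random environment matrix for model contract checks.
random_env <- function(n, vars = c("a", "b"), seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * length(vars)), n, length(vars))
    colnames(m) <- vars
    m
  })
}

# The transcribed published table of suitable-pixel counts.
published_counts <- function() bryophyte_suitable_pixels()
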
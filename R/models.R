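#' Per-record weights enforcing neutral prevalence
#'
#' Calibration weights such that the total presence weight equals the total
#' absence weight (prevalence 0.5), with the presence weight fixed at 1.
#'
#' @param n_presence,n_absence class counts (both >= 1).
#' @return named numeric vector `c(presence = 1, absence = n_p / n_a)`.
#' @export
prevalence_weights <- function(n_presence, n_absence) {
  if (n_presence < 1 || n_absence < 1) {
    abort_bryoclim("both class counts must be >= 1.")
  }
  c(presence = 1, absence = n_presence / n_absence)
}

#' Suitability prediction generic
#'
#' All fitted techniques and the ensemble implement this contract: given an
#' environment matrix with (at least) the training variables as columns,
#' return suitabilities in \[0, 1\].
#'
#' @param object a fitted model.
#' @param env numeric matrix with named columns.
#' @param ... unused.
#' @return numeric vector in \[0, 1\], one value per row of `env`.
#' @export
predict_suitability <- function(object, env, ...) UseMethod("predict_suitability")

check_env <- function(object, env) {
  miss <- setdiff(object$vars, colnames(env))
  if (length(miss) > 0L) {
    abort_bryoclim(sprintf("prediction environment lacks variable(s): %s",
                           paste(miss, collapse = ", ")))
  }
  env[, object$vars, drop = FALSE]
}

#' Fit a climatic envelope (surface-range envelope) model
#'
#' Stores the presence values per variable. A query scores, per variable,
#' `s(v) = 1 - 2 * |F(v) - 0.5|` where `F` is the mid-rank empirical CDF of
#' the presence values (`F = (#\{x < v\} + #\{x <= v\}) / (2 n)`), giving 1 at
#' the presence median and 0 strictly outside the presence min-max. The
#' suitability is the minimum score over variables. A variable constant
#' across presences scores 1 at that value and 0 elsewhere.
#'
#' @param presence_env numeric matrix of presence environments (>= 3 rows,
#'   no missing values, named columns).
#' @return a `fitted_envelope` model honouring [predict_suitability()].
#' @export
fit_envelope <- function(presence_env) {
  if (nrow(presence_env) < 3L) abort_bryoclim("need at least 3 presences.")
  if (anyNA(presence_env)) abort_bryoclim("presence environments contain missing values.")
  vars <- colnames(presence_env)
  values <- lapply(seq_along(vars), function(j) sort(presence_env[, j]))
  names(values) <- vars
  degenerate <- vars[vapply(values, function(v) v[1] == v[length(v)], logical(1))]
  if (length(degenerate) > 0L) {
    message(sprintf("fit_envelope: variable(s) constant across presences (degenerate envelope): %s",
                    paste(degenerate, collapse = ", ")))
  }
  structure(list(technique = "envelope", vars = vars, values = values),
            class = c("fitted_envelope", "bryoclim_model"))
}

#' @export
predict_suitability.fitted_envelope <- function(object, env, ...) {
  env <- check_env(object, env)
  score <- matrix(NA_real_, nrow(env), length(object$vars))
  for (j in seq_along(object$vars)) {
    x <- object$values[[j]]
    n <- length(x)
    v <- env[, j]
    n_lt <- findInterval(v, x, left.open = TRUE)   # #{x < v}
    n_le <- findInterval(v, x)                     # #{x <= v}
    f <- (n_lt + n_le) / (2 * n)
    s <- 1 - 2 * abs(f - 0.5)
    s[v < x[1] | v > x[n]] <- 0
    score[, j] <- s
  }
  apply(score, 1, min)
}

# Linear + quadratic feature expansion with training-set standardization.
maxent_features <- function(env, vars, center = NULL, scale = NULL) {
  x <- env[, vars, drop = FALSE]
  feats <- cbind(x, x^2)
  colnames(feats) <- c(vars, paste0(vars, "_sq"))
  if (is.null(center)) {
    center <- colMeans(feats)
    scale <- apply(feats, 2, stats::sd)
    scale[scale == 0] <- 1
  }
  list(x = sweep(sweep(feats, 2, center, "-"), 2, scale, "/"),
       center = center, scale = scale)
}

#' Fit a penalized presence-background model (MaxEnt-style)
#'
#' A lasso-penalized logistic discrimination of presences against background
#' on standardized linear + quadratic features — a convex stand-in for
#' maximum-entropy presence-background modelling with the same smooth
#' suitability contract. Class weights enforce neutral prevalence. The
#' suitability is the logistic output; the fit is deterministic.
#'
#' @param presence_env,background_env environment matrices (named columns);
#'   at least 5 presences and at least as many background points.
#' @param regularization lasso penalty (glmnet `lambda`; default 0.001).
#' @return a `fitted_maxent` model honouring [predict_suitability()].
#' @export
fit_maxent_like <- function(presence_env, background_env, regularization = 0.001) {
  if (nrow(presence_env) < 5L) abort_bryoclim("need at least 5 presences.")
  if (nrow(background_env) < nrow(presence_env)) {
    abort_bryoclim("background must be at least as large as the presence set.")
  }
  vars <- colnames(presence_env)
  env <- rbind(presence_env[, vars, drop = FALSE],
               background_env[, vars, drop = FALSE])
  y <- c(rep(1L, nrow(presence_env)), rep(0L, nrow(background_env)))
  w <- prevalence_weights(nrow(presence_env), nrow(background_env))
  weights <- ifelse(y == 1L, w[["presence"]], w[["absence"]])
  ft <- maxent_features(env, vars)
  fit <- glmnet::glmnet(ft$x, y, family = "binomial", weights = weights,
                        alpha = 1, lambda = regularization,
                        standardize = FALSE)
  structure(
    list(technique = "maxent_like", vars = vars, fit = fit,
         center = ft$center, scale = ft$scale, regularization = regularization),
    class = c("fitted_maxent", "bryoclim_model")
  )
}

#' @export
predict_suitability.fitted_maxent <- function(object, env, ...) {
  env <- check_env(object, env)
  ft <- maxent_features(env, object$vars, object$center, object$scale)
  as.numeric(stats::predict(object$fit, newx = ft$x, type = "response"))
}

#' Coefficients of a fitted MaxEnt-style model
#'
#' @param x a `fitted_maxent` model.
#' @param ... unused.
#' @return tibble with columns `term`, `estimate` (on the standardized
#'   feature scale).
#' @export
tidy.fitted_maxent <- function(x, ...) {
  b <- as.matrix(stats::coef(x$fit))
  tibble::tibble(term = rownames(b), estimate = as.numeric(b))
}

#' Fit a random-forest presence-background model
#'
#' Delegates to the `randomForest` package; neutral prevalence is imposed by
#' a balanced stratified bootstrap (each tree draws the same number of
#' presences and absences). Suitability is the presence class probability.
#'
#' @inheritParams fit_maxent_like
#' @param n_trees number of trees (default 500).
#' @param seed integer seed; identical seeds give identical forests.
#' @return a `fitted_rf` model honouring [predict_suitability()].
#' @export
fit_random_forest <- function(presence_env, background_env, n_trees = 500,
                              seed = 1L) {
  if (nrow(presence_env) < 2L || nrow(background_env) < 2L) {
    abort_bryoclim("need at least 2 records of each class.")
  }
  vars <- colnames(presence_env)
  x <- rbind(presence_env[, vars, drop = FALSE],
             background_env[, vars, drop = FALSE])
  y <- factor(c(rep("presence", nrow(presence_env)),
                rep("absence", nrow(background_env))),
              levels = c("absence", "presence"))
  if (length(unique(y)) < 2L) abort_bryoclim("degenerate single-class input.")
  m <- min(table(y))
  fit <- with_seed(seed, randomForest::randomForest(
    x = as.data.frame(x), y = y, ntree = n_trees,
    strata = y, sampsize = c(m, m)
  ))
  structure(list(technique = "random_forest", vars = vars, fit = fit),
            class = c("fitted_rf", "bryoclim_model"))
}

#' @export
predict_suitability.fitted_rf <- function(object, env, ...) {
  env <- check_env(object, env)
  as.numeric(stats::predict(object$fit, newdata = as.data.frame(env),
                            type = "prob")[, "presence"])
}

#' @export
print.bryoclim_model <- function(x, ...) {
  cat(sprintf("<bryoclim model: %s> variables: %s\n",
              x$technique, paste(x$vars, collapse = ", ")))
  invisible(x)
}
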
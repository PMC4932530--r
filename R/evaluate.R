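#' Area under the ROC curve
#'
#' Rank-statistic AUC: the probability that a random presence outscores a
#' random absence, with ties counted half.
#'
#' @param scores_presence,scores_absence numeric score vectors (non-empty).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores_presence, scores_absence) {
  np <- length(scores_presence); na <- length(scores_absence)
  if (np == 0L || na == 0L) abort_bryoclim("both score vectors must be non-empty.")
  r <- rank(c(scores_presence, scores_absence))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na)
}

#' True skill statistic
#'
#' Maximum over observed score thresholds of sensitivity + specificity - 1,
#' where a score >= threshold predicts presence.
#'
#' @inheritParams auc
#' @return TSS in \[-1, 1\].
#' @export
tss <- function(scores_presence, scores_absence) {
  np <- length(scores_presence); na <- length(scores_absence)
  if (np == 0L || na == 0L) abort_bryoclim("both score vectors must be non-empty.")
  thr <- sort(unique(c(scores_presence, scores_absence)))
  best <- -1
  for (t in thr) {
    sens <- sum(scores_presence >= t) / np
    spec <- sum(scores_absence < t) / na
    best <- max(best, sens + spec - 1)
  }
  best
}

#' Construct an evaluation result
#'
#' Holds per-split AUC and TSS from repeated data splitting and the pass flag
#' of the quality filter: a technique passes when its mean AUC is at least
#' `auc_min` and its mean TSS at least `tss_min`.
#'
#' @param auc_splits,tss_splits per-split statistics.
#' @param auc_min,tss_min filter thresholds (defaults 0.8 and 0.7).
#' @return an `evaluation_result` list with `mean_auc`, `mean_tss`, `pass`.
#' @export
evaluation_result <- function(auc_splits, tss_splits, auc_min = 0.8, tss_min = 0.7) {
  if (any(auc_splits < 0 | auc_splits > 1)) abort_bryoclim("AUC must lie in [0, 1].")
  if (any(tss_splits < -1 | tss_splits > 1)) abort_bryoclim("TSS must lie in [-1, 1].")
  mean_auc <- mean(auc_splits); mean_tss <- mean(tss_splits)
  structure(
    list(auc_splits = auc_splits, tss_splits = tss_splits,
         mean_auc = mean_auc, mean_tss = mean_tss,
         auc_min = auc_min, tss_min = tss_min,
         pass = mean_auc >= auc_min && mean_tss >= tss_min),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> mean AUC %.3f, mean TSS %.3f over %d splits -> %s\n",
              x$mean_auc, x$mean_tss, length(x$auc_splits),
              if (x$pass) "PASS" else "eliminated"))
  invisible(x)
}

#' Evaluate a technique by repeated stratified data splitting
#'
#' Performs `reps` independent stratified 70/30 (by default) splits of the
#' presence and background records, refits the technique on each calibration
#' part and scores the held-out part with AUC and TSS. Split seeds derive
#' deterministically from `seed` and the split index.
#'
#' @param fitter function `(presence_env, background_env, seed)` returning a
#'   model honouring [predict_suitability()]; see [technique_fitters()].
#' @param presence_env,background_env environment matrices (named columns).
#' @param split calibration fraction (default 0.7).
#' @param reps number of splits (default 10).
#' @param seed integer seed.
#' @param auc_min,tss_min pass thresholds forwarded to [evaluation_result()].
#' @return an [evaluation_result()].
#' @export
evaluate_technique <- function(fitter, presence_env, background_env,
                               split = 0.7, reps = 10, seed = 1L,
                               auc_min = 0.8, tss_min = 0.7) {
  np <- nrow(presence_env); na <- nrow(background_env)
  np_train <- round(split * np); na_train <- round(split * na)
  if (np_train < 2 || na_train < 2 || np - np_train < 2 || na - na_train < 2) {
    abort_bryoclim("too few records for a stratified split with >= 2 of each class per part.")
  }
  auc_splits <- numeric(reps); tss_splits <- numeric(reps)
  for (i in seq_len(reps)) {
    si <- derive_seed(seed, i)
    parts <- with_seed(si, list(
      p = sample.int(np, np_train),
      a = sample.int(na, na_train)
    ))
    model <- fitter(presence_env[parts$p, , drop = FALSE],
                    background_env[parts$a, , drop = FALSE],
                    seed = derive_seed(si, 1L))
    sp <- predict_suitability(model, presence_env[-parts$p, , drop = FALSE])
    sa <- predict_suitability(model, background_env[-parts$a, , drop = FALSE])
    auc_splits[i] <- auc(sp, sa)
    tss_splits[i] <- tss(sp, sa)
  }
  evaluation_result(auc_splits, tss_splits, auc_min, tss_min)
}

#' Standard fitter functions for the three techniques
#'
#' @param regularization penalty for the MaxEnt-style technique.
#' @param n_trees forest size for the random-forest technique.
#' @return named list of fitter functions with the signature expected by
#'   [evaluate_technique()].
#' @export
technique_fitters <- function(regularization = 0.001, n_trees = 500) {
  list(
    envelope = function(presence_env, background_env, seed) {
      fit_envelope(presence_env)
    },
    maxent_like = function(presence_env, background_env, seed) {
      fit_maxent_like(presence_env, background_env, regularization)
    },
    random_forest = function(presence_env, background_env, seed) {
      fit_random_forest(presence_env, background_env, n_trees, seed)
    }
  )
}

#' Build the AUC-weighted consensus ensemble
#'
#' Keeps the models whose evaluation passed the quality filter and weights
#' them proportionally to their mean AUC (weights sum to 1). The ensemble
#' suitability is the weighted mean of member suitabilities, hence always a
#' convex combination of member predictions.
#'
#' @param models list of fitted models.
#' @param evaluations list of matching [evaluation_result()]s.
#' @return an `sdm_ensemble` honouring [predict_suitability()], or `NULL`
#'   (with a message) when no model passes — the species is excluded.
#' @export
build_consensus <- function(models, evaluations) {
  stopifnot(length(models) == length(evaluations))
  pass <- vapply(evaluations, `[[`, logical(1), "pass")
  if (!any(pass)) {
    message("build_consensus: no technique passed the AUC/TSS filter; species excluded.")
    return(NULL)
  }
  models <- models[pass]
  evaluations <- evaluations[pass]
  mean_auc <- vapply(evaluations, `[[`, numeric(1), "mean_auc")
  weights <- mean_auc / sum(mean_auc)
  structure(
    list(members = models, weights = weights, mean_auc = mean_auc,
         mean_tss = vapply(evaluations, `[[`, numeric(1), "mean_tss"),
         techniques = vapply(models, `[[`, character(1), "technique"),
         vars = models[[1]]$vars),
    class = "sdm_ensemble"
  )
}

#' @export
predict_suitability.sdm_ensemble <- function(object, env, ...) {
  preds <- vapply(object$members, predict_suitability, numeric(nrow(env)), env = env)
  preds <- matrix(preds, nrow = nrow(env))
  as.numeric(preds %*% object$weights)
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat("<sdm_ensemble>\n")
  for (i in seq_along(x$members)) {
    cat(sprintf("  %-14s weight %.3f (mean AUC %.3f)\n",
                x$techniques[i], x$weights[i], x$mean_auc[i]))
  }
  invisible(x)
}

#' Tidy an ensemble into a member table
#'
#' @param x an `sdm_ensemble`.
#' @param ... unused.
#' @return tibble with columns `technique`, `weight`, `mean_auc`, `mean_tss`.
#' @export
tidy.sdm_ensemble <- function(x, ...) {
  tibble::tibble(technique = x$techniques, weight = x$weights,
                 mean_auc = x$mean_auc, mean_tss = x$mean_tss)
}

#' One-line summary of an ensemble
#'
#' @param x an `sdm_ensemble`.
#' @param ... unused.
#' @return tibble with `n_members`, `mean_auc` (weighted), `mean_tss`.
#' @export
glance.sdm_ensemble <- function(x, ...) {
  tibble::tibble(n_members = length(x$members),
                 mean_auc = sum(x$weights * x$mean_auc),
                 mean_tss = sum(x$weights * x$mean_tss))
}
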
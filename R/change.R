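#' Percent of suitable area remaining
#'
#' `100 * n_future / n_present`, rounded half-up to one decimal. Values above
#' 100 indicate expansion. Undefined (`NA`) when no present suitable area
#' exists.
#'
#' @param n_present,n_future suitable-cell counts (vectorized).
#' @return numeric vector of percentages (1 decimal), `NA` where
#'   `n_present` is 0.
#' @export
pct_remaining <- function(n_present, n_future) {
  if (any(n_present < 0 | n_future < 0)) abort_bryoclim("counts must be >= 0.")
  out <- ifelse(n_present > 0, round_half_up(100 * n_future / n_present, 1), NA_real_)
  out
}

#' Threat-status classes, most to least severe
#' @export
status_levels <- c("extinct", "near_extinct", "sub5", "endangered",
                   "vulnerable", "below_VU", "expanding")

#' Classify range-change status
#'
#' Maps percent-remaining onto threat classes anchored on the IUCN A-criterion
#' range-reduction thresholds for island species: a reduction of at least 50%
#' (remaining <= 50%) is `endangered`, at least 30% (remaining <= 70%) is
#' `vulnerable`. Below those, `sub5` marks under 5% remaining, `near_extinct`
#' under 1%, `extinct` exactly 0. Remaining above 100% is `expanding`.
#' Boundary values belong to the more severe class.
#'
#' @param pct percent remaining (>= 0), as from [pct_remaining()].
#' @return ordered factor with levels [status_levels] (severe to mild); `NA`
#'   propagates.
#' @export
classify_status <- function(pct) {
  if (any(pct < 0, na.rm = TRUE)) abort_bryoclim("percent remaining cannot be negative.")
  out <- dplyr::case_when(
    is.na(pct) ~ NA_character_,
    pct == 0 ~ "extinct",
    pct < 1 ~ "near_extinct",
    pct < 5 ~ "sub5",
    pct <= 50 ~ "endangered",
    pct <= 70 ~ "vulnerable",
    pct <= 100 ~ "below_VU",
    TRUE ~ "expanding"
  )
  factor(out, levels = status_levels, ordered = TRUE)
}

#' Range-change table from suitable-cell counts
#'
#' Data-frame-first wrapper combining [pct_remaining()] and
#' [classify_status()]: one row per species x region x scenario.
#'
#' @param counts data frame with columns `species`, `n_present`, `n_future`
#'   and optionally `region`, `scenario`.
#' @return the input tibble with `pct_remaining` and `status` columns added.
#' @export
range_change_table <- function(counts) {
  counts <- tibble::as_tibble(counts)
  counts$pct_remaining <- pct_remaining(counts$n_present, counts$n_future)
  counts$status <- classify_status(counts$pct_remaining)
  counts
}

#' Headline summary of a range-change table
#'
#' @param table output of [range_change_table()].
#' @return one-row tibble: `n_species`, `n_with_present` (present count > 0),
#'   `n_extinct` (present > 0, future 0), `n_sub5` (remaining in (0, 5)),
#'   `mean_pct_remaining` and `sd_pct_remaining` over species with a defined
#'   percentage.
#' @export
summarize_range_changes <- function(table) {
  pct <- table$pct_remaining
  tibble::tibble(
    n_species = nrow(table),
    n_with_present = sum(table$n_present > 0),
    n_extinct = sum(table$n_present > 0 & table$n_future == 0),
    n_sub5 = sum(!is.na(pct) & pct > 0 & pct < 5),
    mean_pct_remaining = mean(pct, na.rm = TRUE),
    sd_pct_remaining = stats::sd(pct, na.rm = TRUE)
  )
}

#' Per-island elevational shift of the suitable range
#'
#' Computes the mean elevation of suitable cells per island for the present
#' and future binary ranges, then a two-sided paired t-test across islands of
#' the future-minus-present difference. Islands where either period has no
#' suitable cell are dropped from the pairing (losing them reduces the power
#' of the test); fewer than 2 usable pairs makes the test not computable.
#'
#' @param present,future `binary_range`s from [binarize_and_mask()].
#' @param elevation elevation matrix of the stack.
#' @param mask a [region_mask()].
#' @return an `elevation_shift` object; see [tidy.elevation_shift()] and
#'   [glance.elevation_shift()].
#' @export
elevation_shift <- function(present, future, elevation, mask) {
  ids <- sort(setdiff(unique(as.vector(mask$island_id)), 0L))
  per_island <- purrr::map_dfr(ids, function(i) {
    isl <- mask$island_id == i
    p_cells <- isl & present$grid
    f_cells <- isl & future$grid
    tibble::tibble(
      island = i,
      n_present = sum(p_cells), n_future = sum(f_cells),
      mean_elev_present = if (any(p_cells)) mean(elevation[p_cells]) else NA_real_,
      mean_elev_future = if (any(f_cells)) mean(elevation[f_cells]) else NA_real_
    )
  })
  usable <- per_island[!is.na(per_island$mean_elev_present) &
                         !is.na(per_island$mean_elev_future), ]
  if (nrow(usable) < 2L) {
    test <- tibble::tibble(n_islands = nrow(usable), t_stat = NA_real_,
                           df = NA_real_, p_value = NA_real_, computable = FALSE)
  } else {
    d <- usable$mean_elev_future - usable$mean_elev_present
    if (stats::sd(d) == 0) {
      # all differences identical: zero shift gives t = 0, p = 1; a constant
      # nonzero shift is an infinitely precise one
      t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
      test <- tibble::tibble(n_islands = nrow(usable), t_stat = t_stat,
                             df = nrow(usable) - 1, p_value = p, computable = TRUE)
    } else {
      tt <- stats::t.test(usable$mean_elev_future, usable$mean_elev_present,
                          paired = TRUE)
      test <- tibble::tibble(n_islands = nrow(usable),
                             t_stat = unname(tt$statistic),
                             df = unname(tt$parameter),
                             p_value = tt$p.value, computable = TRUE)
    }
  }
  structure(list(per_island = per_island, test = test),
            class = "elevation_shift")
}

#' @export
print.elevation_shift <- function(x, ...) {
  cat(sprintf("<elevation_shift> %d islands paired; t = %.3f, p = %.4g\n",
              x$test$n_islands, x$test$t_stat, x$test$p_value))
  invisible(x)
}

#' Per-island means of an elevational-shift analysis
#' @param x an `elevation_shift` object.
#' @param ... unused.
#' @return tibble with one row per island.
#' @export
tidy.elevation_shift <- function(x, ...) x$per_island

#' Paired t-test of an elevational-shift analysis
#' @param x an `elevation_shift` object.
#' @param ... unused.
#' @return one-row tibble with `n_islands`, `t_stat`, `df`, `p_value`,
#'   `computable`.
#' @export
glance.elevation_shift <- function(x, ...) x$test

#' Compare per-species losses among archipelagos
#'
#' Tie-corrected Kruskal-Wallis test of the per-species percent values across
#' archipelago groups, followed by pairwise Nemenyi post-hoc comparisons.
#' The default post-hoc distribution is the Tukey studentized range applied
#' to mean rank differences; a tie-corrected chi-square variant is available.
#'
#' @param losses data frame with columns `archipelago` and `value`
#'   (e.g. percent suitable area remaining per species).
#' @param dist `"tukey"` (default) or `"chisq"` approximation for the
#'   Nemenyi p-values.
#' @return an `archipelago_comparison`: list with `h` (Kruskal-Wallis H),
#'   `df`, `p_value`, and `pairwise` (tibble group1/group2/statistic/p_value).
#' @export
compare_archipelagos <- function(losses, dist = c("tukey", "chisq")) {
  dist <- match.arg(dist)
  losses <- tibble::as_tibble(losses)
  g <- factor(losses$archipelago)
  x <- losses$value
  if (nlevels(g) < 2L) abort_bryoclim("need at least two archipelagos.")
  if (any(table(g) < 2L)) abort_bryoclim("every archipelago needs at least two values.")
  if (anyNA(x)) abort_bryoclim("`value` must not contain NA.")

  n <- length(x)
  k <- nlevels(g)
  if (length(unique(x)) == 1L) {
    h <- 0; p <- 1
  } else {
    kw <- stats::kruskal.test(x, g)
    h <- unname(kw$statistic); p <- kw$p.value
  }

  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tapply(x, g, length)
  ties <- table(x)
  tie_c <- 1 - sum(ties^3 - ties) / (n^3 - n)
  pairs <- utils::combn(levels(g), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diff <- abs(rbar[[a]] - rbar[[b]])
    se2 <- (n * (n + 1) / 12) * (1 / ni[[a]] + 1 / ni[[b]])
    if (dist == "tukey") {
      stat <- diff / sqrt(se2)
      pv <- stats::ptukey(stat * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
    } else {
      stat <- diff^2 / se2 / tie_c
      pv <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
    }
    tibble::tibble(group1 = a, group2 = b, statistic = stat, p_value = min(pv, 1))
  })
  structure(list(h = h, df = k - 1, p_value = p, pairwise = pairwise,
                 dist = dist),
            class = "archipelago_comparison")
}

#' @export
print.archipelago_comparison <- function(x, ...) {
  cat(sprintf("<archipelago_comparison> Kruskal-Wallis H = %.3f (df %d), p = %.4g\n",
              x$h, x$df, x$p_value))
  print(x$pairwise)
  invisible(x)
}

#' Pairwise Nemenyi comparisons of an archipelago comparison
#' @param x an `archipelago_comparison`.
#' @param ... unused.
#' @return tibble of pairwise statistics and p-values.
#' @export
tidy.archipelago_comparison <- function(x, ...) x$pairwise

#' Kruskal-Wallis summary of an archipelago comparison
#' @param x an `archipelago_comparison`.
#' @param ... unused.
#' @return one-row tibble with `h`, `df`, `p_value`.
#' @export
glance.archipelago_comparison <- function(x, ...) {
  tibble::tibble(h = x$h, df = x$df, p_value = x$p_value)
}

#' Protected-area coverage of a binary range
#'
#' A suitable pixel counts as protected when at least `min_overlap` (default
#' 5%) of its cell area is covered by protected-area polygons. Returns
#' `100 * protected suitable pixels / suitable pixels`.
#'
#' @param range a `binary_range`.
#' @param pa a `protected_areas` object.
#' @param stack the matching [climate_stack()].
#' @param min_overlap minimum covered fraction for a pixel to count as
#'   protected (default 0.05).
#' @param subdiv per-cell sub-sampling density for the coverage fraction.
#' @return percent in \[0, 100\], or `NA` for an empty range.
#' @export
pa_coverage <- function(range, pa, stack, min_overlap = 0.05, subdiv = 10) {
  idx <- which(range$grid, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NA_real_)
  cells <- tibble::tibble(row = idx[, 1], col = idx[, 2])
  frac <- protected_fraction(pa, stack, cells, subdiv)
  100 * sum(frac >= min_overlap) / nrow(cells)
}
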
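#' Overlap coefficient of two sample distributions
#'
#' Estimates the overlapping coefficient `integral of min(f, g)` between the
#' densities of two samples using Gaussian-kernel density estimates with
#' Silverman's bandwidth on a shared 4096-point grid spanning the pooled
#' range plus three bandwidths on either side; each density is renormalized
#' to unit mass on the grid, so identical samples give exactly 1. The
#' standard error is the SD
#' of the statistic over paired nonparametric bootstrap resamples (both
#' samples resampled, bandwidths recomputed, each iteration).
#'
#' @param samples_a,samples_b Numeric vectors of at least 50 finite values.
#' @param n_boot Number of bootstrap resamples for the SE (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return A one-row tibble: `overlap` (fraction in \[0, 1\]), `se`,
#'   `n_boot`, `seed`.
#' @export
overlap_coefficient <- function(samples_a, samples_b, n_boot = 1000, seed = 1) {
  samples_a <- samples_a[is.finite(samples_a)]
  samples_b <- samples_b[is.finite(samples_b)]
  if (length(samples_a) < 50 || length(samples_b) < 50) {
    abort("overlap_coefficient: need at least 50 finite values per sample")
  }
  if (sd(samples_a) == 0 || sd(samples_b) == 0) {
    abort("overlap_coefficient: zero variance in a sample (degenerate density)")
  }
  est <- overlap_stat(samples_a, samples_b)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    a <- sample(samples_a, replace = TRUE)
    bb <- sample(samples_b, replace = TRUE)
    if (sd(a) == 0 || sd(bb) == 0) return(NA_real_)
    overlap_stat(a, bb)
  }, 0)
  tibble(overlap = est, se = sd(boots, na.rm = TRUE),
         n_boot = n_boot, seed = seed)
}

overlap_stat <- function(a, b, n_grid = 4096) {
  bw_a <- stats::bw.nrd0(a)
  bw_b <- stats::bw.nrd0(b)
  pad <- 3 * max(bw_a, bw_b)
  lo <- min(a, b) - pad
  hi <- max(a, b) + pad
  fa <- density(a, bw = bw_a, from = lo, to = hi, n = n_grid)$y
  fb <- density(b, bw = bw_b, from = lo, to = hi, n = n_grid)$y
  dx <- (hi - lo) / (n_grid - 1)
  trapz <- function(f) sum((f[-1] + f[-n_grid]) / 2) * dx
  # renormalize each KDE to unit mass on the shared grid so that
  # overlap(x, x) == 1 exactly despite tail truncation
  fa <- fa / trapz(fa)
  fb <- fb / trapz(fb)
  trapz(pmin(fa, fb))
}

#' Posterior overlap of population-level life-history parameters
#'
#' For each posterior draw, derives the life-history parameters of each
#' population's curve, then computes the overlap coefficient between the two
#' populations' posterior distributions of each parameter. Draws where a
#' population curve has no peak are dropped (with a message if any).
#'
#' @param fit A `senes_fit`.
#' @param early_age Age for early-life performance (years).
#' @param n_boot,seed Passed to [overlap_coefficient()].
#' @return A tibble with one row per parameter: `parameter`, `overlap`,
#'   `se`, `n_boot`.
#' @export
population_overlap <- function(fit, early_age = 10, n_boot = 1000, seed = 1) {
  pc <- extract_population_curves(fit)
  lh <- lapply(pc$draws, derive_life_history_draws, scaling = fit$scaling,
               early_age = early_age)
  params <- c("onset_age", "senescence_rate", "early_life_performance",
              "peak_performance")
  dropped <- sum(is.na(lh[[1]][, "onset_age"])) + sum(is.na(lh[[2]][, "onset_age"]))
  if (dropped > 0) {
    message("population_overlap: dropped ", dropped,
            " non-senescent posterior draws")
  }
  rows <- lapply(seq_along(params), function(j) {
    a <- lh[[1]][, params[j]]
    b <- lh[[2]][, params[j]]
    ov <- overlap_coefficient(a[is.finite(a)], b[is.finite(b)],
                              n_boot = n_boot, seed = seed + j)
    tibble(parameter = params[j], overlap = ov$overlap, se = ov$se,
           n_boot = n_boot)
  })
  bind_rows(rows)
}

#' Among-individual variance of life-history parameters, by population
#'
#' Sample variances (n - 1 denominator) of individual point estimates per
#' population, and their ratio (population A over population B), used to
#' ask whether environmental variability is associated with higher
#' among-individual variance in life-history strategies. Excluded
#' individuals are dropped first.
#'
#' @param life_history A life-history tibble from [derive_life_history()]
#'   with a `population` column.
#' @param parameters Character vector of parameter columns to compare.
#' @return A tibble: `parameter`, `var_a`, `var_b`, `ratio`.
#' @export
among_individual_variance <- function(life_history,
                                      parameters = c("onset_age",
                                                     "senescence_rate",
                                                     "early_life_performance",
                                                     "peak_performance")) {
  lh <- life_history[!life_history$excluded, , drop = FALSE]
  pops <- sort(unique(lh$population))
  if (length(pops) != 2) abort("among_individual_variance: need two populations")
  counts <- table(lh$population)
  if (any(counts < 2)) {
    abort("among_individual_variance: need >= 2 non-excluded individuals per population")
  }
  rows <- lapply(parameters, function(p) {
    va <- var(lh[[p]][lh$population == pops[1]])
    vb <- var(lh[[p]][lh$population == pops[2]])
    tibble(parameter = p, var_a = va, var_b = vb, ratio = va / vb)
  })
  bind_rows(rows)
}

#' Posterior among-year and among-cohort variances in reproductive success
#'
#' Posterior means of the squared year and cohort random-intercept SDs per
#' population, with the A/B variance ratio, quantifying how much more
#' variable reproductive success is between years (and cohorts) in one
#' population than the other.
#'
#' @param fit A `senes_fit`.
#' @return A tibble: `parameter` (`year_variance`, `cohort_variance`),
#'   `var_a`, `var_b`, `ratio`.
#' @export
random_effect_variances <- function(fit) {
  pops <- fit$populations
  v <- function(name, p) mean(fit$draws[, paste(name, p, sep = "_")]^2)
  tibble(
    parameter = c("year_variance", "cohort_variance"),
    var_a = c(v("sd_year", pops[1]), v("sd_cohort", pops[1])),
    var_b = c(v("sd_year", pops[2]), v("sd_cohort", pops[2])),
  ) |>
    mutate(ratio = .data$var_a / .data$var_b)
}

#' Correlation between onset age and senescence rate, per population
#'
#' Pearson correlation between individual point-estimate onset ages and
#' senescence rates within each population: a strong negative correlation
#' indicates a fast-slow continuum (early onset pairs with fast decline).
#'
#' @param life_history A life-history tibble from [derive_life_history()].
#' @return A tibble: `population`, `r`, `n`.
#' @export
onset_rate_correlation <- function(life_history) {
  lh <- life_history[!life_history$excluded, , drop = FALSE]
  lh |>
    group_by(.data$population) |>
    summarise(r = {
      if (n() < 3) abort("onset_rate_correlation: need >= 3 non-excluded individuals")
      if (sd(.data$onset_age) == 0 || sd(.data$senescence_rate) == 0) {
        abort("onset_rate_correlation: zero variance, correlation undefined")
      }
      cor(.data$onset_age, .data$senescence_rate)
    }, n = n(), .groups = "drop")
}

#' Full between-population comparison
#'
#' Bundles the three population comparisons: overlap of population-level
#' posterior distributions of the four life-history parameters,
#' among-individual (plus among-year/cohort) variances with A/B ratios, and
#' the within-population onset-rate correlations.
#'
#' @param fit A `senes_fit`.
#' @param life_history Individual life-history tibble from
#'   [derive_life_history()].
#' @param early_age Age for early-life performance (years).
#' @param n_boot,seed Bootstrap settings for the overlap SEs.
#' @return A `senes_comparison` list with tibbles `overlap`, `variances`
#'   (year/cohort variance rows followed by among-individual rows) and
#'   `correlations`.
#' @export
compare_populations <- function(fit, life_history, early_age = 10,
                                n_boot = 1000, seed = 1) {
  structure(list(
    overlap = population_overlap(fit, early_age = early_age,
                                 n_boot = n_boot, seed = seed),
    variances = bind_rows(random_effect_variances(fit),
                          among_individual_variance(life_history)),
    correlations = onset_rate_correlation(life_history)
  ), class = "senes_comparison")
}

#' @export
print.senes_comparison <- function(x, ...) {
  cat("Population comparison\n\nPosterior overlap (population-level parameters):\n")
  print(as.data.frame(x$overlap), row.names = FALSE)
  cat("\nVariances and A/B ratios:\n")
  print(as.data.frame(x$variances), row.names = FALSE)
  cat("\nOnset-rate correlations:\n")
  print(as.data.frame(x$correlations), row.names = FALSE)
  invisible(x)
}
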
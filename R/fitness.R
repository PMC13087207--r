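#' Poisson regression of a lifetime fitness count on a life-history
#' parameter
#'
#' Fits, by maximum likelihood (IRLS, log link), a Poisson GLM of a
#' non-negative count response on a (standardized) life-history predictor,
#' population, and their two-way interaction, so the association can differ
#' between populations. Population A (the alphabetically first label) is
#' the reference level.
#'
#' @param data A data frame with one row per individual containing the
#'   response and predictor columns and a `population` column.
#' @param response Name of the count response column (e.g. `"lrs"`).
#' @param predictor Name of the predictor column (e.g. `"onset_age"`).
#' @param standardize Centre and scale the predictor to SD units before
#'   fitting (default `TRUE`), so coefficients are per-SD effects.
#' @return A `senes_glm` object wrapping the [stats::glm()] fit, with the
#'   standardization constants recorded.
#' @export
fit_poisson_glm <- function(data, response, predictor, standardize = TRUE) {
  if (!all(c(response, predictor, "population") %in% names(data))) {
    abort("fit_poisson_glm: data must contain response, predictor and population columns")
  }
  d <- data[stats::complete.cases(data[c(response, predictor, "population")]), ]
  if (nrow(d) < 10) abort("fit_poisson_glm: need at least 10 observations")
  y <- d[[response]]
  if (any(y < 0) || any(y %% 1 != 0)) {
    abort("fit_poisson_glm: response must be non-negative integer counts")
  }
  pops <- sort(unique(d$population))
  if (length(pops) != 2) {
    abort("fit_poisson_glm: both populations must be present")
  }
  std <- if (standardize) {
    c(mean = mean(d[[predictor]]), sd = sd(d[[predictor]]))
  } else c(mean = 0, sd = 1)
  if (std[["sd"]] == 0) abort("fit_poisson_glm: predictor has zero variance")
  md <- tibble(
    y = y,
    z = (d[[predictor]] - std[["mean"]]) / std[["sd"]],
    population = factor(d$population, levels = pops)
  )
  model <- glm(y ~ z * population, family = poisson(), data = md,
               control = list(epsilon = 1e-12, maxit = 100))
  if (!model$converged) {
    warn("fit_poisson_glm: IRLS did not converge (possible separation)")
  }
  structure(list(model = model, response = response, predictor = predictor,
                 standardization = std, populations = pops,
                 converged = model$converged),
            class = "senes_glm")
}

#' @export
print.senes_glm <- function(x, ...) {
  cat(sprintf("Poisson GLM: %s ~ %s * population (predictor standardized: mean %.3f, sd %.3f)\n",
              x$response, x$predictor,
              x$standardization[["mean"]], x$standardization[["sd"]]))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy coefficients of a fitness GLM
#'
#' @param x A `senes_glm`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high` (Wald 95%).
#' @method tidy senes_glm
#' @export
tidy.senes_glm <- function(x, ...) {
  ct <- summary(x$model)$coefficients
  tibble(
    term = rownames(ct),
    estimate = ct[, 1], std.error = ct[, 2],
    statistic = ct[, 3], p.value = ct[, 4],
    conf.low = ct[, 1] - qnorm(0.975) * ct[, 2],
    conf.high = ct[, 1] + qnorm(0.975) * ct[, 2]
  )
}

#' @method glance senes_glm
#' @export
glance.senes_glm <- function(x, ...) {
  tibble(
    n_obs = length(x$model$y),
    logLik = as.numeric(logLik(x$model)),
    deviance = x$model$deviance,
    converged = x$converged
  )
}

#' Per-population predictor slopes from a fitness GLM
#'
#' The reference-population slope is the predictor coefficient; the second
#' population's slope adds the interaction term. Wald 95% intervals use the
#' coefficient covariance.
#'
#' @param fit A `senes_glm`.
#' @return A tibble: `population`, `slope`, `conf.low`, `conf.high`.
#' @export
population_slopes <- function(fit) {
  b <- coef(fit$model)
  V <- vcov(fit$model)
  zc <- "z"
  ic <- grep(":", names(b), value = TRUE)
  s_a <- b[[zc]]
  v_a <- V[zc, zc]
  s_b <- b[[zc]] + b[[ic]]
  v_b <- V[zc, zc] + V[ic, ic] + 2 * V[zc, ic]
  tibble(
    population = fit$populations,
    slope = c(s_a, s_b),
    conf.low = c(s_a - qnorm(0.975) * sqrt(v_a), s_b - qnorm(0.975) * sqrt(v_b)),
    conf.high = c(s_a + qnorm(0.975) * sqrt(v_a), s_b + qnorm(0.975) * sqrt(v_b))
  )
}

#' Propagate life-history estimation uncertainty through the fitness GLM
#'
#' Re-runs the fitness Poisson GLM `n_reruns` times, each time replacing
#' every individual's point estimate by one joint posterior draw of its
#' (onset age, senescence rate), restricted to draws where both parameters
#' fall inside that individual's central 95% credible interval (both taken
#' from the same posterior draw so the within-draw onset-rate dependence is
#' preserved; out-of-interval draws are redrawn per individual).
#' Individuals with fewer than `min_retained` usable draws are dropped with
#' a warning.
#'
#' @param curves Individual curves with a `draws` list-column, from
#'   [extract_individual_curves()], restricted (by joining with the
#'   response data) to the individuals being analysed.
#' @param scaling Age scaling list with `mean` and `sd`.
#' @param response_data A data frame with `individual_id` and the response
#'   count column.
#' @param response Name of the response column (e.g. `"lrs"`).
#' @param predictor `"onset_age"` or `"senescence_rate"`.
#' @param n_reruns Number of GLM re-runs (default 2000).
#' @param seed Integer seed.
#' @param max_onset,early_age Passed to [derive_life_history()] for the
#'   point-estimate exclusion step.
#' @param min_retained Minimum usable draws per individual (default 50).
#' @return A `senes_propagated` object: `reruns` (tibble of per-rerun
#'   coefficients), `summary` (per-term mean, SD and 2.5/97.5 percentiles),
#'   the seed and the excluded individuals.
#' @export
propagate_uncertainty <- function(curves, scaling, response_data, response,
                                  predictor = c("onset_age", "senescence_rate"),
                                  n_reruns = 2000, seed = 1, max_onset = 40,
                                  early_age = 10, min_retained = 50) {
  predictor <- match.arg(predictor)
  if (!"draws" %in% names(curves)) {
    abort("propagate_uncertainty: curves must carry a 'draws' list-column")
  }
  point <- derive_life_history(curves, scaling, max_onset = max_onset,
                               early_age = early_age)
  d <- inner_join(point[!point$excluded, ],
                  response_data[c("individual_id", response)],
                  by = "individual_id")
  keep <- match(d$individual_id, curves$individual_id)
  n_ind <- nrow(d)
  n_draws <- nrow(curves$draws[[1]])

  onset_m <- matrix(NA_real_, n_draws, n_ind)
  rate_m <- matrix(NA_real_, n_draws, n_ind)
  for (i in seq_len(n_ind)) {
    lh <- derive_life_history_draws(curves$draws[[keep[i]]], scaling,
                                    early_age = early_age)
    onset_m[, i] <- lh[, "onset_age"]
    rate_m[, i] <- lh[, "senescence_rate"]
  }
  finite <- is.finite(onset_m) & is.finite(rate_m)
  within95 <- matrix(FALSE, n_draws, n_ind)
  for (i in seq_len(n_ind)) {
    f <- finite[, i]
    qo <- quantile(onset_m[f, i], c(0.025, 0.975))
    qr <- quantile(rate_m[f, i], c(0.025, 0.975))
    within95[, i] <- f & onset_m[, i] >= qo[1] & onset_m[, i] <= qo[2] &
      rate_m[, i] >= qr[1] & rate_m[, i] <= qr[2]
  }
  n_ret <- colSums(within95)
  drop <- n_ret < min_retained
  if (any(drop)) {
    warn(paste0("propagate_uncertainty: excluding ", sum(drop),
                " individual(s) with < ", min_retained, " retained draws"))
  }
  excluded_ids <- d$individual_id[drop]
  d <- d[!drop, , drop = FALSE]
  P <- if (predictor == "onset_age") onset_m[, !drop, drop = FALSE] else
    rate_m[, !drop, drop = FALSE]
  W <- within95[, !drop, drop = FALSE]
  retained_idx <- lapply(seq_len(ncol(W)), function(i) which(W[, i]))

  pops <- sort(unique(d$population))
  pop_b <- as.numeric(d$population == pops[2])
  y <- d[[response]]
  terms <- c("(Intercept)", "z", paste0("population", pops[2]),
             paste0("z:population", pops[2]))

  set.seed(seed)
  coefs <- matrix(NA_real_, n_reruns, 4, dimnames = list(NULL, terms))
  for (r in seq_len(n_reruns)) {
    dr <- sample.int(n_draws, 1)
    vals <- P[dr, ]
    bad <- which(!W[dr, ])
    for (i in bad) {
      vals[i] <- P[sample(retained_idx[[i]], 1), i]
    }
    z <- (vals - mean(vals)) / sd(vals)
    X <- cbind(1, z, pop_b, z * pop_b)
    fit_r <- suppressWarnings(
      stats::glm.fit(X, y, family = poisson(),
                     control = list(epsilon = 1e-10, maxit = 100)))
    coefs[r, ] <- fit_r$coefficients
  }
  reruns <- as_tibble(coefs)
  reruns$rerun <- seq_len(n_reruns)
  summ <- tibble(
    term = terms,
    mean = unname(colMeans(coefs)),
    sd = unname(apply(coefs, 2, sd)),
    conf.low = unname(apply(coefs, 2, quantile, 0.025)),
    conf.high = unname(apply(coefs, 2, quantile, 0.975))
  )
  structure(list(reruns = reruns[, c("rerun", terms)], summary = summ,
                 predictor = predictor, response = response,
                 n_reruns = n_reruns, seed = seed,
                 excluded = excluded_ids),
            class = "senes_propagated")
}

#' @export
print.senes_propagated <- function(x, ...) {
  cat(sprintf("Propagated fitness GLM (%s on %s): %d re-runs\n",
              x$response, x$predictor, x$n_reruns))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Tidy summary of a propagated fitness analysis
#'
#' @param x A `senes_propagated`.
#' @param ... Unused.
#' @return The per-term summary tibble (mean, SD, 2.5/97.5 percentiles over
#'   re-runs).
#' @method tidy senes_propagated
#' @export
tidy.senes_propagated <- function(x, ...) x$summary

#' Fit both fitness GLMs (onset model and rate model)
#'
#' Onset age and senescence rate are never co-predictors (they are strongly
#' negatively correlated), so the association with fitness is assessed in
#' two separate Poisson GLMs.
#'
#' @param data One row per individual with the response count, `onset_age`,
#'   `senescence_rate` and `population` columns (excluded individuals
#'   already removed).
#' @param response Name of the count response column (default `"lrs"`).
#' @return A list with `onset` and `rate` `senes_glm` fits.
#' @export
fitness_models <- function(data, response = "lrs") {
  list(onset = fit_poisson_glm(data, response, "onset_age"),
       rate = fit_poisson_glm(data, response, "senescence_rate"))
}

#' Robustness check: breeding attempts instead of fledged chicks
#'
#' Re-fits the onset and rate fitness GLMs with the lifetime number of
#' breeding attempts as the response, separating the cost of successful
#' breeding from the cost of attempting to breed.
#'
#' @param data As in [fitness_models()], with an `n_attempts` column.
#' @return A list with `onset` and `rate` `senes_glm` fits on attempts.
#' @export
attempts_robustness <- function(data) {
  fitness_models(data, response = "n_attempts")
}
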
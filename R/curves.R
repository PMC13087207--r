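#' Population-level curve coefficients from fixed effects
#'
#' Applies the contrast coding of the trajectory model: the reference
#' population's logit-quadratic curve is (intercept, age, age_sq); the
#' second population's is the componentwise sum with the population main
#' effect and the two age-by-population interaction terms.
#'
#' @param beta A named numeric vector, or a draws matrix with named columns,
#'   containing `intercept`, `age`, `age_sq`, `population`,
#'   `age_x_population`, `age_sq_x_population`.
#' @return For a vector input, a list with elements `A` and `B`, each a
#'   named numeric `c(c0, c1, c2)`; for a matrix input, a list of two
#'   draws x 3 matrices.
#' @export
population_curve_components <- function(beta) {
  if (is.matrix(beta)) {
    a <- cbind(c0 = beta[, "intercept"], c1 = beta[, "age"],
               c2 = beta[, "age_sq"])
    b <- cbind(c0 = beta[, "intercept"] + beta[, "population"],
               c1 = beta[, "age"] + beta[, "age_x_population"],
               c2 = beta[, "age_sq"] + beta[, "age_sq_x_population"])
    list(A = a, B = b)
  } else {
    list(
      A = c(c0 = unname(beta[["intercept"]]), c1 = unname(beta[["age"]]),
            c2 = unname(beta[["age_sq"]])),
      B = c(c0 = unname(beta[["intercept"]] + beta[["population"]]),
            c1 = unname(beta[["age"]] + beta[["age_x_population"]]),
            c2 = unname(beta[["age_sq"]] + beta[["age_sq_x_population"]]))
    )
  }
}

#' Extract population-level curves from a fit
#'
#' @param fit A `senes_fit`.
#' @param include_draws Attach per-draw coefficient matrices as a `draws`
#'   list-column (default `TRUE`).
#' @return A tibble with one row per population: `population`, posterior-
#'   mean `c0`, `c1`, `c2` on the standardized-age logit scale, and
#'   optionally `draws` (draws x 3 matrix per row).
#' @export
extract_population_curves <- function(fit, include_draws = TRUE) {
  stopifnot(inherits(fit, "senes_fit"))
  comp <- population_curve_components(fit$draws)
  names(comp) <- fit$populations
  out <- tibble(
    population = fit$populations,
    c0 = unname(vapply(comp, function(m) mean(m[, 1]), 0)),
    c1 = unname(vapply(comp, function(m) mean(m[, 2]), 0)),
    c2 = unname(vapply(comp, function(m) mean(m[, 3]), 0))
  )
  if (include_draws) out$draws <- unname(comp)
  out
}

#' Extract per-individual curves from a fit
#'
#' Per-individual coefficients are BLUP-style sums, per posterior draw, of
#' the individual's population fixed part and its random deviations
#' (u0, u1, u2); point estimates are posterior means (which, by linearity,
#' equal the curve of the mean coefficients).
#'
#' @param fit A `senes_fit`.
#' @param include_draws Attach per-draw coefficient matrices as a `draws`
#'   list-column (default `TRUE`).
#' @return A tibble with one row per modelled individual: `individual_id`,
#'   `population`, `n_records`, posterior-mean `c0`, `c1`, `c2`, and
#'   optionally `draws`.
#' @export
extract_individual_curves <- function(fit, include_draws = TRUE) {
  stopifnot(inherits(fit, "senes_fit"))
  comp <- population_curve_components(fit$draws)
  names(comp) <- fit$populations
  ind <- fit$individuals
  draws_list <- lapply(seq_len(nrow(ind)), function(i) {
    base <- comp[[ind$population[i]]]
    m <- base + fit$u_draws[, ind$index[i], ]
    colnames(m) <- c("c0", "c1", "c2")
    m
  })
  out <- tibble(
    individual_id = ind$individual_id,
    population = ind$population,
    n_records = ind$n_records,
    c0 = vapply(draws_list, function(m) mean(m[, 1]), 0),
    c1 = vapply(draws_list, function(m) mean(m[, 2]), 0),
    c2 = vapply(draws_list, function(m) mean(m[, 3]), 0)
  )
  if (include_draws) out$draws <- draws_list
  out
}
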
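#' Probability of breeding success at a given age
#'
#' Evaluates the logistic of the quadratic logit curve,
#' `p = logistic(c0 + c1 x + c2 x^2)` with `x = (age - mean) / sd`.
#'
#' @param curve Numeric vector `c(c0, c1, c2)` on the standardized-age
#'   logit scale.
#' @param age Age(s) in years.
#' @param scaling Age scaling list with `mean` and `sd` in years.
#' @return Success probability, same length as `age`.
#' @export
success_probability_at <- function(curve, age, scaling) {
  x <- (age - scaling$mean) / scaling$sd
  plogis(curve[[1]] + curve[[2]] * x + curve[[3]] * x^2)
}

peak_x_vec <- function(c1, c2) -c1 / (2 * c2)

#' Age at the onset of senescence
#'
#' The onset of senescence is the age at the peak of the quadratic curve of
#' reproductive success versus age: `x* = -c1 / (2 c2)` in standardized-age
#' units, back-transformed to years. Because the logistic link is monotone,
#' the peak of the logit-quadratic is also the unique maximizer of the
#' success probability.
#'
#' @inheritParams success_probability_at
#' @return Onset age in years.
#' @export
onset_age <- function(curve, scaling) {
  if (curve[[3]] >= 0) {
    abort("onset_age: c2 >= 0, the curve has no peak (no-peak condition)")
  }
  unstandardize_age(peak_x_vec(curve[[2]], curve[[3]]), scaling)
}

# g(x) = (1 - 2*sigma(q)) q'(x)^2 + q''(x); p''(x) = sigma(1-sigma) * g(x),
# so the inflection points of p are the roots of g.
curvature_factor <- function(x, c0, c1, c2) {
  q <- c0 + c1 * x + c2 * x^2
  (1 - 2 * plogis(q)) * (c1 + 2 * c2 * x)^2 + 2 * c2
}

# First root of g after the peak, vectorized over curves: sign-change scan
# outward from the peak (g(x*) = 2 c2 < 0, and g -> +Inf as x -> Inf, so a
# root always exists), then bisection to ~1e-16 on x. The scan uses fine
# steps near the peak and widens further out: nearly flat curves
# (c2 close to 0) can inflect tens of SD units beyond their peak.
inflection_x_vec <- function(c0, c1, c2, max_span = 1000) {
  xs <- peak_x_vec(c1, c2)
  n <- length(xs)
  lo <- xs
  hi <- rep(NA_real_, n)
  active <- rep(TRUE, n)
  offsets <- c(seq(0.5, 20, by = 0.5), seq(22, max_span, by = 2))
  prev <- 0
  for (off in offsets) {
    if (!any(active)) break
    xn <- xs[active] + off
    pos <- curvature_factor(xn, c0[active], c1[active], c2[active]) > 0
    idx <- which(active)[pos]
    hi[idx] <- xs[idx] + off
    lo[idx] <- xs[idx] + prev
    active[idx] <- FALSE
    prev <- off
  }
  ok <- !is.na(hi)
  lo_ok <- lo[ok]; hi_ok <- hi[ok]
  a0 <- c0[ok]; a1 <- c1[ok]; a2 <- c2[ok]
  for (it in seq_len(64)) {
    mid <- (lo_ok + hi_ok) / 2
    neg <- curvature_factor(mid, a0, a1, a2) < 0
    lo_ok[neg] <- mid[neg]
    hi_ok[!neg] <- mid[!neg]
  }
  out <- rep(NA_real_, n)
  out[ok] <- (lo_ok + hi_ok) / 2
  out
}

#' Post-peak inflection point of the success curve
#'
#' Finds the smallest root greater than the peak of
#' `(1 - 2 sigma(q)) q'(x)^2 + q''(x)`, i.e. the first inflection point of
#' the success-probability curve after its peak. By definition this is the
#' age at which senescence is fastest (the steepest decline).
#'
#' @inheritParams success_probability_at
#' @return Inflection location in standardized-age units.
#' @export
senescence_inflection <- function(curve) {
  if (curve[[3]] >= 0) {
    abort("senescence_inflection: c2 >= 0, the curve has no declining branch")
  }
  out <- inflection_x_vec(curve[[1]], curve[[2]], curve[[3]])
  if (is.na(out)) {
    abort("senescence_inflection: no sign change found beyond the peak")
  }
  out
}

rate_at_x <- function(x, c0, c1, c2, sd_years) {
  q <- c0 + c1 * x + c2 * x^2
  p <- plogis(q)
  -(p * (1 - p) * (c1 + 2 * c2 * x)) / sd_years
}

#' Senescence rate (tangent slope at the inflection point)
#'
#' The senescence rate is the magnitude of the slope of the tangent to the
#' success-probability-versus-age curve at its post-peak inflection point:
#' `rate = -p'(x_infl) / sd` per year of age, positive on the declining
#' branch (higher rate = faster decline).
#'
#' @inheritParams success_probability_at
#' @return Decline in success probability per year of age (positive).
#' @export
senescence_rate <- function(curve, scaling) {
  xi <- senescence_inflection(curve)
  rate_at_x(xi, curve[[1]], curve[[2]], curve[[3]], scaling$sd)
}

life_history_vec <- function(c0, c1, c2, scaling, early_age = 10) {
  sen <- c2 < 0
  xs <- ifelse(sen, peak_x_vec(c1, c2), NA_real_)
  xi <- rep(NA_real_, length(c0))
  if (any(sen)) xi[sen] <- inflection_x_vec(c0[sen], c1[sen], c2[sen])
  xe <- (early_age - scaling$mean) / scaling$sd
  tibble(
    onset_age = unstandardize_age(xs, scaling),
    senescence_rate = ifelse(sen, rate_at_x(xi, c0, c1, c2, scaling$sd),
                             NA_real_),
    early_life_performance = plogis(c0 + c1 * xe + c2 * xe^2),
    peak_performance = ifelse(sen, plogis(c0 + c1 * xs + c2 * xs^2),
                              NA_real_),
    inflection_age = unstandardize_age(xi, scaling)
  )
}

#' Derive life-history parameters from fitted curves
#'
#' Computes, for each curve, the four life-history parameters: age at the
#' onset of senescence (peak of the curve, years), senescence rate (tangent
#' slope at the post-peak inflection, probability per year), early-life
#' performance (success probability at `early_age`) and peak performance
#' (success probability at onset), plus the inflection age. Curves with no
#' peak (`c2 >= 0`) or with onset later than `max_onset` years are flagged
#' `excluded` and carry no downstream parameters.
#'
#' @param curves A tibble with columns `c0`, `c1`, `c2` (e.g. from
#'   [extract_individual_curves()]); identifier columns are carried through
#'   and a `draws` list-column, if present, is dropped.
#' @param scaling Age scaling list with `mean` and `sd` in years.
#' @param max_onset Exclusion threshold for onset age in years (default 40):
#'   little-to-no senescence within the observable lifespan.
#' @param early_age Age in years at which early-life performance is
#'   evaluated (default 10, the average age at first reproduction).
#' @return The input (minus `draws`) with columns `onset_age`,
#'   `senescence_rate`, `early_life_performance`, `peak_performance`,
#'   `inflection_age`, `excluded` appended.
#' @export
derive_life_history <- function(curves, scaling, max_onset = 40,
                                early_age = 10) {
  stopifnot(all(c("c0", "c1", "c2") %in% names(curves)))
  lh <- life_history_vec(curves$c0, curves$c1, curves$c2, scaling, early_age)
  lh$excluded <- curves$c2 >= 0 |
    (!is.na(lh$onset_age) & lh$onset_age > max_onset)
  out <- curves[setdiff(names(curves), "draws")]
  bind_cols(as_tibble(out), lh)
}

#' Per-draw life-history parameters for one curve's posterior
#'
#' @param draws A draws x 3 matrix of (c0, c1, c2) posterior draws.
#' @param scaling Age scaling list with `mean` and `sd` in years.
#' @param early_age Age for early-life performance (years).
#' @return A draws x 5 matrix (onset_age, senescence_rate,
#'   early_life_performance, peak_performance, inflection_age); rows with
#'   `c2 >= 0` are `NA` except early-life performance.
#' @export
derive_life_history_draws <- function(draws, scaling, early_age = 10) {
  lh <- life_history_vec(draws[, 1], draws[, 2], draws[, 3], scaling, early_age)
  as.matrix(lh)
}
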
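ref_scaling <- list(mean = 20, sd = 8)

test_that("success probability evaluates the logistic of the quadratic", {
  flat <- c(0, 0, 0)
  expect_equal(success_probability_at(flat, 7, ref_scaling), 0.5)
  expect_equal(success_probability_at(flat, 33, ref_scaling), 0.5)

  # stable-environment population curve at age 10: direct arithmetic
  curve <- c(0.87, 0.20, -0.15)
  x <- (10 - 20) / 8
  expect_equal(success_probability_at(curve, 10, ref_scaling),
               plogis(0.87 + 0.20 * x - 0.15 * x^2))
  expect_equal(success_probability_at(curve, 10, ref_scaling), 0.595,
               tolerance = 1e-3)

  # peak property for declining curves
  on <- onset_age(curve, ref_scaling)
  expect_gte(success_probability_at(curve, on, ref_scaling),
             success_probability_at(curve, on + 5, ref_scaling))
  expect_gte(success_probability_at(curve, on, ref_scaling),
             success_probability_at(curve, on - 5, ref_scaling))
})

test_that("onset age matches the dense-grid argmax of the quadratic", {
  expect_equal(onset_age(c(0, 0, -1), ref_scaling), ref_scaling$mean)

  # variable-environment population point estimates
  x_star <- (onset_age(c(-0.73, 0.56, -0.27), ref_scaling) - 20) / 8
  expect_equal(x_star, grid_peak_x(-0.73, 0.56, -0.27), tolerance = 1e-3)
  expect_equal(x_star, 1.0370, tolerance = 1e-3)

  # stable-environment population point estimates
  x_star_b <- (onset_age(c(0.87, 0.20, -0.15), ref_scaling) - 20) / 8
  expect_equal(x_star_b, grid_peak_x(0.87, 0.20, -0.15), tolerance = 1e-3)
  expect_equal(x_star_b, 0.6667, tolerance = 1e-3)

  expect_error(onset_age(c(0, 0, 0.2), ref_scaling), "no peak")
})

test_that("inflection finder matches the second-difference oracle", {
  curve <- c(0, 0, -1)
  xi <- senescence_inflection(curve)
  expect_equal(xi, grid_inflection_x(0, 0, -1), tolerance = 1e-3)

  # inflection comes strictly after the peak
  c2 <- c(-0.73, 0.56, -0.27)
  expect_gt(senescence_inflection(c2), -0.56 / (2 * -0.27))

  # translation equivariance: q(x - a) shifts the inflection by exactly a
  a <- 1.3
  shifted <- c(c2[1] - c2[2] * a + c2[3] * a^2, c2[2] - 2 * c2[3] * a, c2[3])
  expect_equal(senescence_inflection(shifted), senescence_inflection(c2) + a,
               tolerance = 1e-9)
  expect_error(senescence_inflection(c(0, 0, 0.5)), "declining")
})

test_that("senescence rate is the steepest post-peak decline per year", {
  curve <- c(0, 0, -1)
  r1 <- senescence_rate(curve, list(mean = 20, sd = 1))
  # tangent at the inflection is by definition the steepest decline
  xs <- seq(0, 10, by = 1e-4)
  p <- plogis(-xs^2)
  grid_max <- max(-diff(p) / 1e-4)
  expect_equal(r1, grid_max, tolerance = 1e-4)
  expect_gt(r1, 0)

  # doubling the age SD halves the per-year rate (chain rule)
  r2 <- senescence_rate(curve, list(mean = 20, sd = 2))
  expect_equal(r1 / r2, 2, tolerance = 1e-10)

  expect_gt(senescence_rate(c(0.87, 0.20, -0.15), ref_scaling), 0)
})

test_that("life-history derivation assembles and flags exclusions", {
  curves <- tibble::tibble(
    individual_id = c("i1", "i2", "i3"),
    c0 = c(0.87, 0, 0.5),
    c1 = c(0.20, 0.55, 0.1),
    c2 = c(-0.15, -0.1, 0.1)
  )
  lh <- derive_life_history(curves, ref_scaling, max_onset = 40)
  # i1: onset 20 + 8 * 0.6667 years, senescing, retained
  expect_equal(lh$onset_age[1], 20 + 8 * (0.20 / 0.30), tolerance = 1e-6)
  expect_equal(lh$onset_age[1], 25.3, tolerance = 0.05)
  expect_false(lh$excluded[1])
  # i2: peak at x = 2.75 -> onset 42 years -> little-to-no senescence
  expect_gt(lh$onset_age[2], 40)
  expect_true(lh$excluded[2])
  # i3: no peak at all
  expect_true(lh$excluded[3])
  expect_true(is.na(lh$onset_age[3]))
  # ordering and link-monotonicity for the retained curve
  expect_gt(lh$inflection_age[1], lh$onset_age[1])
  ages <- seq(2, 60, by = 0.01)
  expect_true(all(success_probability_at(c(0.87, 0.20, -0.15), ages,
                                         ref_scaling) <=
                    lh$peak_performance[1] + 1e-12))
  expect_equal(lh$early_life_performance[1],
               success_probability_at(c(0.87, 0.20, -0.15), 10, ref_scaling))
})

test_that("parameters are invariant to reparameterizing the age axis", {
  set.seed(2)
  for (i in 1:25) {
    c0 <- runif(1, -2, 2); c1 <- runif(1, -0.5, 1); c2 <- runif(1, -1, -0.01)
    m <- ref_scaling$mean; s <- ref_scaling$sd
    raw <- c(c0 - c1 * m / s + c2 * m^2 / s^2,
             c1 / s - 2 * c2 * m / s^2,
             c2 / s^2)
    std_lh <- derive_life_history(
      tibble::tibble(c0 = c0, c1 = c1, c2 = c2), ref_scaling)
    raw_lh <- derive_life_history(
      tibble::tibble(c0 = raw[1], c1 = raw[2], c2 = raw[3]),
      list(mean = 0, sd = 1))
    expect_equal(std_lh$onset_age, raw_lh$onset_age, tolerance = 1e-8)
    expect_equal(std_lh$senescence_rate, raw_lh$senescence_rate,
                 tolerance = 1e-8)
    expect_equal(std_lh$peak_performance, raw_lh$peak_performance,
                 tolerance = 1e-8)
  }
})
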
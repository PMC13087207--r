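test_that("age standardization uses the pooled sample SD and inverts", {
  rec <- tibble::tibble(
    individual_id = c("a", "b", "c"), population = "A",
    cohort = 2000L, season = c(2018L, 2020L, 2022L), age = c(18L, 20L, 22L),
    primiparous = c(TRUE, TRUE, TRUE), success = c(1L, 0L, 1L)
  )
  std <- standardize_age(rec)
  expect_equal(std$records$x, c(-1, 0, 1))
  expect_equal(std$scaling$mean, 20)
  expect_equal(std$scaling$sd, 2)
  expect_equal(unstandardize_age(std$records$x, std$scaling), rec$age)

  rec$age <- 20L
  rec$season <- rec$cohort + rec$age
  expect_error(standardize_age(rec), "zero age variance")
})

test_that("population curve components apply the contrast sums", {
  comp <- population_curve_components(reference_fixed_effects)
  expect_equal(comp$A, c(c0 = -0.73, c1 = 0.56, c2 = -0.27))
  expect_equal(comp$B[["c0"]], -0.73 + 1.60)
  expect_equal(comp$B[["c2"]], -0.27 + 0.12)

  # zero interactions collapse both populations onto one curve
  beta0 <- reference_fixed_effects
  beta0[c("population", "age_x_population", "age_sq_x_population")] <- 0
  comp0 <- population_curve_components(beta0)
  expect_equal(comp0$A, comp0$B)

  # matrix (draws) input agrees with the vector path row by row
  drw <- rbind(reference_fixed_effects, reference_fixed_effects * 0.5)
  colnames(drw) <- names(reference_fixed_effects)
  compm <- population_curve_components(drw)
  expect_equal(unname(compm$B[1, ]), unname(comp$B))
})

test_that("a small fit returns coherent draws, curves and diagnostics", {
  fx <- cached_small_fit()
  fit <- fx$fit
  expect_s3_class(fit, "senes_fit")
  expect_equal(fit$n_draws, 2 * 400)
  expect_equal(dim(fit$u_draws), c(fit$n_draws, nrow(fit$individuals), 3))
  td <- tidy(fit)
  expect_true(all(c("intercept", "sd_year_A", "cor_age_age_sq_B") %in% td$term))
  expect_true(all(is.finite(td$estimate)))
  expect_true(all(td$rhat > 0.8 & td$rhat < 2))
  gl <- glance(fit)
  expect_equal(gl$n_individuals, nrow(fit$individuals))

  curves <- extract_individual_curves(fit)
  expect_equal(nrow(curves), nrow(fit$individuals))
  # posterior-mean curve equals the mean of per-draw curves (linearity)
  expect_equal(curves$c0, vapply(curves$draws, function(m) mean(m[, "c0"]), 0))
  expect_equal(curves$c2, vapply(curves$draws, function(m) mean(m[, "c2"]), 0))

  pc <- extract_population_curves(fit)
  expect_equal(pc$population, c("A", "B"))
  # per-draw contrast identity, checked on the posterior means
  expect_equal(pc$c0[2] - pc$c0[1], mean(fit$draws[, "population"]),
               tolerance = 1e-10)
})

test_that("individuals with few records shrink harder to the population curve", {
  fx <- cached_small_fit()
  curves <- extract_individual_curves(fx$fit, include_draws = FALSE)
  pc <- extract_population_curves(fx$fit, include_draws = FALSE)
  dist <- vapply(seq_len(nrow(curves)), function(i) {
    p <- pc[pc$population == curves$population[i], ]
    sqrt((curves$c0[i] - p$c0)^2 + (curves$c1[i] - p$c1)^2 +
           (curves$c2[i] - p$c2)^2)
  }, 0)
  few <- curves$n_records <= median(curves$n_records)
  expect_lt(mean(dist[few]), mean(dist[!few]))
})

test_that("the linear predictor is invariant to shifting the age origin", {
  # refitting is not needed: transform the curve analytically and compare
  curve <- c(0.4, 0.3, -0.2)
  scaling <- list(mean = 15, sd = 6)
  shift <- 4
  scaling2 <- list(mean = 15 + shift, sd = 6)
  a <- shift / scaling$sd
  curve2 <- c(curve[1] + curve[2] * a + curve[3] * a^2,
              curve[2] + 2 * curve[3] * a,
              curve[3])
  ages <- seq(5, 40, by = 0.5)
  expect_equal(success_probability_at(curve, ages, scaling),
               success_probability_at(curve2, ages, scaling2),
               tolerance = 1e-12)
})

test_that("fit refuses degenerate designs", {
  rec <- five_bird_fixture()
  one_pop <- rec[rec$population == "A", ]
  expect_error(fit_trajectory_model(one_pop), "two populations")
})
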
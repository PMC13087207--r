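make_fitness_data <- function(n_per_pop = 30, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    individual_id = sprintf("i%03d", seq_len(2 * n_per_pop)),
    population = rep(c("A", "B"), each = n_per_pop),
    onset_age = rnorm(2 * n_per_pop, 20, 2),
    senescence_rate = runif(2 * n_per_pop, 0.01, 0.05),
    lrs = rpois(2 * n_per_pop, 4),
    n_attempts = NA_integer_
  )
}

test_that("Poisson GLM reproduces closed-form MLEs", {
  d <- make_fitness_data()
  # constant response: intercept log k, all slopes zero
  d$lrs <- 3L
  fit <- fit_poisson_glm(d, "lrs", "onset_age")
  expect_equal(unname(coef(fit$model)), c(log(3), 0, 0, 0), tolerance = 1e-8)

  # two-group design with group means 2 and 4: population coefficient log 2
  d2 <- make_fitness_data()
  d2$lrs <- rep(c(2L, 4L), each = 30)
  fit2 <- fit_poisson_glm(d2, "lrs", "onset_age")
  expect_equal(coef(fit2$model)[["populationB"]], log(2), tolerance = 1e-8)
  expect_equal(coef(fit2$model)[["z"]], 0, tolerance = 1e-8)
  sl <- population_slopes(fit2)
  expect_equal(sl$slope, c(0, 0), tolerance = 1e-8)
})

test_that("Poisson GLM slope is consistent on simulated counts", {
  set.seed(7)
  n <- 5000
  d <- tibble::tibble(
    individual_id = as.character(seq_len(n)),
    population = rep(c("A", "B"), length.out = n),
    onset_age = rnorm(n),          # already standardized scale
    senescence_rate = runif(n),
    n_attempts = NA_integer_
  )
  d$lrs <- rpois(n, exp(0.5 + 0.3 * d$onset_age))
  fit <- fit_poisson_glm(d, "lrs", "onset_age", standardize = FALSE)
  expect_lt(abs(coef(fit$model)[["z"]] - 0.3), 0.05)
  expect_true(fit$converged)
})

test_that("Poisson GLM validates its inputs", {
  d <- make_fitness_data()
  d$lrs[1] <- -1L
  expect_error(fit_poisson_glm(d, "lrs", "onset_age"), "non-negative integer")
  expect_error(fit_poisson_glm(make_fitness_data()[1:5, ], "lrs", "onset_age"),
               "at least 10")
  one_pop <- make_fitness_data()
  one_pop$population <- "A"
  expect_error(fit_poisson_glm(one_pop, "lrs", "onset_age"),
               "both populations")
})

# curves tibble whose draws are controlled perturbations of a base curve
synthetic_curve_draws <- function(d, n_draws = 400, width = 0.02, seed = 5) {
  set.seed(seed)
  curves <- lapply(seq_len(nrow(d)), function(i) {
    base <- c(d$c0[i], d$c1[i], d$c2[i])
    m <- matrix(rep(base, each = n_draws), n_draws, 3) +
      matrix(rnorm(3 * n_draws, 0, width), n_draws, 3)
    colnames(m) <- c("c0", "c1", "c2")
    m
  })
  tibble::tibble(
    individual_id = d$individual_id, population = d$population,
    c0 = d$c0, c1 = d$c1, c2 = d$c2, draws = curves
  )
}

propagation_inputs <- function(n_per_pop = 20, width = 0.02, seed = 5) {
  set.seed(seed)
  n <- 2 * n_per_pop
  d <- tibble::tibble(
    individual_id = sprintf("p%03d", seq_len(n)),
    population = rep(c("A", "B"), each = n_per_pop),
    c0 = runif(n, 0, 1),
    c1 = runif(n, 0.2, 0.6),
    c2 = runif(n, -0.4, -0.15)
  )
  curves <- synthetic_curve_draws(d, width = width, seed = seed + 1)
  response <- tibble::tibble(
    individual_id = d$individual_id,
    lrs = rpois(n, 4)
  )
  list(curves = curves, response = response,
       scaling = list(mean = 15, sd = 6))
}

test_that("degenerate (zero-width) posteriors propagate to identical re-runs", {
  inp <- propagation_inputs(width = 0)
  pu <- propagate_uncertainty(inp$curves, inp$scaling, inp$response, "lrs",
                              "onset_age", n_reruns = 10, seed = 3,
                              min_retained = 10)
  expect_equal(nrow(pu$reruns), 10)
  for (term in c("z", "(Intercept)")) {
    expect_equal(diff(range(pu$reruns[[term]])), 0, tolerance = 1e-10)
  }
})

test_that("tight posteriors reproduce the point-estimate GLM", {
  inp <- propagation_inputs(width = 0.004)
  point <- derive_life_history(inp$curves, inp$scaling)
  d <- dplyr::inner_join(point, inp$response, by = "individual_id")
  ref <- fit_poisson_glm(d, "lrs", "onset_age")
  pu <- propagate_uncertainty(inp$curves, inp$scaling, inp$response, "lrs",
                              "onset_age", n_reruns = 200, seed = 3)
  expect_equal(pu$summary$mean, unname(coef(ref$model)), tolerance = 0.05)
})

test_that("propagation summaries are recomputable and order-invariant", {
  inp <- propagation_inputs()
  pu <- propagate_uncertainty(inp$curves, inp$scaling, inp$response, "lrs",
                              "senescence_rate", n_reruns = 50, seed = 11)
  expect_equal(nrow(pu$reruns), 50)
  shuffled <- pu$reruns[sample.int(50), ]
  expect_equal(colMeans(shuffled[, -1]), setNames(pu$summary$mean,
                                                  pu$summary$term))
  expect_equal(apply(shuffled[, -1], 2, quantile, 0.975),
               setNames(pu$summary$conf.high, pu$summary$term))
  expect_equal(tidy(pu), pu$summary)
})

test_that("attempts robustness mirrors the LRS models", {
  d <- make_fitness_data(seed = 3)
  # every attempt succeeds: attempts response equals the LRS response
  d$n_attempts <- d$lrs
  rb <- attempts_robustness(d)
  lrs_fit <- fitness_models(d, "lrs")
  expect_named(rb, c("onset", "rate"))
  expect_equal(coef(rb$onset$model), coef(lrs_fit$onset$model))
  expect_equal(coef(rb$rate$model), coef(lrs_fit$rate$model))

  # constant attempts with varying LRS: attempts model has zero slopes
  d$n_attempts <- 8L
  rb2 <- attempts_robustness(d)
  expect_equal(coef(rb2$onset$model)[["z"]], 0, tolerance = 1e-8)
  expect_equal(coef(rb2$rate$model)[["z"]], 0, tolerance = 1e-8)
})
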
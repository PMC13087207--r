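# Programmatic fixtures shared across test files.

# Hand-enumerable toy table: one row per attempt, built from a compact spec
# list(id = list(population, cohort, ages, successes)).
toy_records <- function(spec, final_season = NULL) {
  rows <- lapply(names(spec), function(id) {
    s <- spec[[id]]
    tibble::tibble(
      individual_id = id,
      population = s$population,
      cohort = s$cohort,
      season = s$cohort + s$ages,
      age = s$ages,
      primiparous = seq_along(s$ages) == 1,
      success = s$successes
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "study_final_season") <-
    if (is.null(final_season)) max(out$season) else final_season
  out
}

# A small standard five-individual fixture used by several filter tests.
five_bird_fixture <- function() {
  toy_records(list(
    a1 = list(population = "A", cohort = 1980, ages = c(8, 9, 10, 11),
              successes = c(0, 1, 1, 0)),
    a2 = list(population = "A", cohort = 1985, ages = c(21, 22),
              successes = c(1, 1)),
    a3 = list(population = "A", cohort = 1990, ages = c(19, 20, 21, 22, 23, 24, 25),
              successes = c(0, 0, 1, 1, 1, 0, 1)),
    b1 = list(population = "B", cohort = 1982, ages = c(5, 6),
              successes = c(1, 0)),
    b2 = list(population = "B", cohort = 1988, ages = c(20, 25),
              successes = c(0, 1))
  ), final_season = 2023)
}

# One modest two-population fit, simulated from the default scenarios and
# cached for the whole test run (several model-level tests share it).
fit_cache <- new.env(parent = emptyenv())

cached_small_fit <- function() {
  if (!is.null(fit_cache$fit)) return(fit_cache)
  sc_a <- default_scenario("A")
  sc_b <- default_scenario("B")
  sc_a$n_individuals <- 60
  sc_b$n_individuals <- 60
  sim <- simulate_two_population_study(sc_a, sc_b, seed = 424242)
  rec <- filter_first_breeding_age(sim$records)
  fit <- suppressWarnings(fit_trajectory_model(
    rec, sampler_control(chains = 2, iter = 900, warmup = 500, seed = 99),
    scaling = sim$truth$scaling))
  fit_cache$sim <- sim
  fit_cache$records <- rec
  fit_cache$fit <- fit
  fit_cache
}

# Table-style fixed-effect point estimates used for contrast-sum checks.
reference_fixed_effects <- c(
  intercept = -0.73, age = 0.56, age_sq = -0.27,
  population = 1.60, age_x_population = -0.37, age_sq_x_population = 0.12,
  primiparity = -0.48
)

# Dense-grid argmax oracle for the onset (peak) of a logit-quadratic.
grid_peak_x <- function(c0, c1, c2, lower = -3, upper = 5, step = 1e-4) {
  xs <- seq(lower, upper, by = step)
  xs[which.max(c0 + c1 * xs + c2 * xs^2)]
}

# Second-difference sign-change oracle for the post-peak inflection of
# p(x) = plogis(q(x)): coarse scan, then refinement near the change point.
grid_inflection_x <- function(c0, c1, c2, span = 60) {
  xstar <- -c1 / (2 * c2)
  scan <- function(from, to, step) {
    xs <- seq(from, to, by = step)
    p <- plogis(c0 + c1 * xs + c2 * xs^2)
    d2 <- diff(diff(p))
    i <- which(d2[-1] > 0 & d2[-length(d2)] <= 0)[1]
    if (is.na(i)) return(NA_real_)
    xs[i + 1]
  }
  coarse <- scan(xstar, xstar + span, 0.01)
  scan(coarse - 0.02, coarse + 0.02, 1e-5)
}
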
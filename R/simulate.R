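#' Default two-population simulation scenarios
#'
#' Returns a generator configuration for one of two populations of a
#' long-lived annual breeder under contrasting environmental variability.
#' Population `"A"` emulates a colony in a highly variable environment
#' (lower average success, steeper age trajectory, large among-year
#' variance); population `"B"` a colony in a more stable environment (higher
#' average success, shallower trajectory, smaller among-year variance).
#' Fixed effects are on the logit scale over standardized age; random-effect
#' SDs and the 3x3 individual-effect correlation matrix
#' (intercept, age, age^2) are population specific.
#'
#' @param population `"A"` or `"B"`.
#' @return A `senes_scenario` list with elements `population`,
#'   `n_individuals`, `fixed` (intercept, age, age_sq, primiparity),
#'   `sd` (id_intercept, id_age, id_age_sq, year, cohort), `cor` (3x3),
#'   `cohort_range`, `first_age_mean`, `first_age_sd`, `adult_survival`,
#'   `max_age`, `breeding_propensity`, `final_season`, `age_mean`, `age_sd`.
#' @export
default_scenario <- function(population = c("A", "B")) {
  population <- match.arg(population)
  shared <- list(
    cohort_range = 1976:2000,
    first_age_mean = if (population == "A") 10.2 else 9.9,
    first_age_sd = if (population == "A") 2.2 else 2.5,
    max_age = 45,
    breeding_propensity = 0.9,
    final_season = 2023,
    age_mean = 15,
    age_sd = 6
  )
  if (population == "A") {
    cfg <- c(list(
      population = "A",
      n_individuals = 360,
      fixed = c(intercept = -0.73, age = 0.56, age_sq = -0.27,
                primiparity = -0.48),
      sd = c(id_intercept = 0.72, id_age = 0.37, id_age_sq = 0.12,
             year = 1.21, cohort = 0.13),
      cor = cor_matrix3(-0.32, -0.40, -0.10),
      adult_survival = 0.94
    ), shared)
  } else {
    cfg <- c(list(
      population = "B",
      n_individuals = 874,
      fixed = c(intercept = 0.87, age = 0.19, age_sq = -0.15,
                primiparity = -0.48),
      sd = c(id_intercept = 0.58, id_age = 0.19, id_age_sq = 0.13,
             year = 0.70, cohort = 0.10),
      cor = cor_matrix3(0.04, -0.47, -0.23),
      adult_survival = 0.92
    ), shared)
  }
  structure(cfg, class = "senes_scenario")
}

cor_matrix3 <- function(r12, r13, r23) {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- r12
  m[1, 3] <- m[3, 1] <- r13
  m[2, 3] <- m[3, 2] <- r23
  dimnames(m) <- rep(list(c("intercept", "age", "age_sq")), 2)
  m
}

#' Validate a simulation scenario
#'
#' @param config A `senes_scenario` list.
#' @return `config`, invisibly, if valid.
#' @export
validate_scenario <- function(config) {
  need <- c("population", "n_individuals", "fixed", "sd", "cor",
            "cohort_range", "first_age_mean", "first_age_sd",
            "adult_survival", "max_age", "breeding_propensity",
            "final_season", "age_mean", "age_sd")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    abort(paste0("invalid scenario: missing field(s) ",
                 paste(missing, collapse = ", ")))
  }
  if (any(config$sd < 0)) abort("invalid scenario: SDs must be >= 0")
  cm <- config$cor
  if (!isTRUE(all.equal(cm, t(cm))) || any(diag(cm) != 1)) {
    abort("invalid scenario: correlation matrix must be symmetric with unit diagonal")
  }
  if (min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    abort("invalid scenario: correlation matrix must be positive definite")
  }
  if (config$adult_survival <= 0 || config$adult_survival > 1) {
    abort("invalid scenario: adult_survival must be in (0, 1]")
  }
  if (config$age_sd <= 0) abort("invalid scenario: age_sd must be > 0")
  invisible(config)
}

#' Simulate breeding histories for one population
#'
#' Generative mirror of the age-trajectory model. For each individual a
#' fledge cohort is drawn uniformly over `cohort_range`, age at first
#' reproduction from a discretized normal on 5..19 years, and lifespan via
#' constant annual adult survival (geometric, capped at `max_age`).
#' Individual coefficient deviations (u0, u1, u2) come from the multivariate
#' normal implied by the scenario SDs and correlations; year and cohort
#' effects are drawn once per season/cohort and shared across individuals.
#' Each season between first breeding and death is attempted with
#' probability `breeding_propensity` (the first is always attempted and
#' flagged primiparous); success is Bernoulli with
#' `logit p = fixed + primiparity + u0 + u1 x + u2 x^2 + year + cohort`,
#' where `x = (age - age_mean) / age_sd` uses the scenario's own
#' standardization constants. Records after `final_season` are truncated.
#' Output is deterministic given `seed`.
#'
#' @param config A `senes_scenario`, e.g. from [default_scenario()].
#' @param seed Integer seed.
#' @return A list with `records` (breeding-record tibble) and `truth`
#'   (list: per-individual tibble of realized coefficients, year and cohort
#'   effect tibbles, the age scaling and the config).
#' @export
simulate_population <- function(config, seed = 1) {
  validate_scenario(config)
  set.seed(seed)
  n <- config$n_individuals
  lab <- config$population
  ids <- sprintf("%s%04d", lab, seq_len(n))
  cohort <- sample(config$cohort_range, n, replace = TRUE)
  fa_support <- 5:19
  fa_prob <- stats::dnorm(fa_support, config$first_age_mean, config$first_age_sd)
  first_age <- sample(fa_support, n, replace = TRUE, prob = fa_prob)
  extra_years <- if (config$adult_survival >= 1) rep(Inf, n) else
    rgeom(n, 1 - config$adult_survival)
  last_age <- pmin(first_age + extra_years, config$max_age)

  u <- MASS::mvrnorm(n, mu = c(0, 0, 0),
                     Sigma = diag(config$sd[1:3]) %*% config$cor %*% diag(config$sd[1:3]))
  if (n == 1) u <- matrix(u, nrow = 1)
  colnames(u) <- c("u0", "u1", "u2")

  seasons <- (min(config$cohort_range) + min(fa_support)):config$final_season
  year_eff <- setNames(rnorm(length(seasons), 0, config$sd[["year"]]), seasons)
  coh_levels <- sort(unique(config$cohort_range))
  coh_eff <- setNames(rnorm(length(coh_levels), 0, config$sd[["cohort"]]), coh_levels)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ages <- first_age[i]:last_age[i]
    attempt <- c(TRUE, runif(length(ages) - 1) < config$breeding_propensity)
    ages <- ages[attempt]
    season <- cohort[i] + ages
    keep <- season <= config$final_season
    ages <- ages[keep]; season <- season[keep]
    if (!length(ages)) next
    x <- (ages - config$age_mean) / config$age_sd
    eta <- config$fixed[["intercept"]] + config$fixed[["age"]] * x +
      config$fixed[["age_sq"]] * x^2 +
      config$fixed[["primiparity"]] * (seq_along(ages) == 1) +
      u[i, 1] + u[i, 2] * x + u[i, 3] * x^2 +
      year_eff[as.character(season)] + coh_eff[as.character(cohort[i])]
    rows[[i]] <- tibble(
      individual_id = ids[i], population = lab, cohort = cohort[i],
      season = season, age = ages,
      primiparous = seq_along(ages) == 1,
      success = rbinom(length(ages), 1, plogis(eta))
    )
  }
  records <- bind_rows(rows)
  attr(records, "study_final_season") <- config$final_season
  truth <- list(
    individuals = tibble(
      individual_id = ids, population = lab, cohort = cohort,
      first_age = first_age, last_age = last_age,
      u0 = u[, 1], u1 = u[, 2], u2 = u[, 3]
    ),
    year_effects = tibble(population = lab, season = as.integer(seasons),
                          effect = unname(year_eff)),
    cohort_effects = tibble(population = lab, cohort = as.integer(coh_levels),
                            effect = unname(coh_eff)),
    scaling = list(mean = config$age_mean, sd = config$age_sd),
    config = config
  )
  list(records = records, truth = truth)
}

#' Simulate a two-population study
#'
#' Simulates both populations with sub-seeds derived from one root seed and
#' concatenates them into a single study table with disjoint individual IDs
#' and a shared season range. Year effects are independent between
#' populations; both scenarios must share the same age-standardization
#' constants and final season.
#'
#' @param config_a,config_b Scenarios for populations A and B.
#' @param seed Integer root seed.
#' @return A list with `records` and `truth` (as [simulate_population()],
#'   with components combined across populations).
#' @export
simulate_two_population_study <- function(config_a = default_scenario("A"),
                                          config_b = default_scenario("B"),
                                          seed = 1) {
  if (identical(config_a$population, config_b$population)) {
    abort("internal error: the two scenarios must use distinct population labels")
  }
  if (config_a$age_mean != config_b$age_mean || config_a$age_sd != config_b$age_sd) {
    abort("invalid scenarios: age standardization constants must be shared")
  }
  set.seed(seed)
  sub <- sample.int(2^30, 2)
  sim_a <- simulate_population(config_a, sub[1])
  sim_b <- simulate_population(config_b, sub[2])
  if (length(intersect(sim_a$records$individual_id, sim_b$records$individual_id))) {
    abort("internal error: overlapping individual ID namespaces")
  }
  records <- bind_rows(sim_a$records, sim_b$records)
  attr(records, "study_final_season") <-
    max(config_a$final_season, config_b$final_season)
  truth <- list(
    individuals = bind_rows(sim_a$truth$individuals, sim_b$truth$individuals),
    year_effects = bind_rows(sim_a$truth$year_effects, sim_b$truth$year_effects),
    cohort_effects = bind_rows(sim_a$truth$cohort_effects, sim_b$truth$cohort_effects),
    scaling = sim_a$truth$scaling,
    config_a = config_a, config_b = config_b, seed = seed
  )
  list(records = records, truth = truth)
}
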
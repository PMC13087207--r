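#' Sampler settings for the trajectory model
#'
#' Defaults mirror the headline analysis (8 chains of 4000 iterations
#' including a 2000-iteration warm-up); test and exploratory fits scale
#' these down. Warm-up is split between JAGS adaptation and burn-in.
#'
#' @param chains Number of MCMC chains.
#' @param iter Iterations per chain, including warm-up.
#' @param warmup Warm-up iterations per chain.
#' @param thin Thinning interval for kept draws.
#' @param seed Integer seed; per-chain RNG streams are derived from it.
#' @param rhat_max,ess_min Convergence gate: largest acceptable
#'   rank-normalized split R-hat and smallest acceptable bulk effective
#'   sample size over the reported fixed-effect and SD parameters.
#' @param quiet Suppress JAGS progress output.
#' @return A `senes_control` list.
#' @export
sampler_control <- function(chains = 8, iter = 4000, warmup = 2000, thin = 1,
                            seed = 1, rhat_max = 1.01, ess_min = 400,
                            quiet = TRUE) {
  if (warmup >= iter) abort("sampler_control: warmup must be < iter")
  structure(list(chains = chains, iter = iter, warmup = warmup, thin = thin,
                 seed = seed, rhat_max = rhat_max, ess_min = ess_min,
                 quiet = quiet),
            class = "senes_control")
}

trajectory_model_string <- function(prior_int_sd, prior_beta_sd, prior_sd_scale) {
  sprintf("
model {
  for (n in 1:N) {
    y[n] ~ dbern(p[n])
    logit(p[n]) <- b[1] + b[2]*x[n] + b[3]*x2[n]
      + (b[4] + b[5]*x[n] + b[6]*x2[n]) * popB[n] + b[7]*primi[n]
      + u[id[n],1] + u[id[n],2]*x[n] + u[id[n],3]*x2[n]
      + v[yr[n]] + w[ch[n]]
  }
  # non-centered individual effects: u_i = diag(sd) L z_i, L = chol(R)
  for (i in 1:I) {
    for (j in 1:3) { z[i,j] ~ dnorm(0, 1) }
    u[i,1] <- sid[popi[i],1] * z[i,1]
    u[i,2] <- sid[popi[i],2] * (L21[popi[i]]*z[i,1] + L22[popi[i]]*z[i,2])
    u[i,3] <- sid[popi[i],3] * (L31[popi[i]]*z[i,1] + L32[popi[i]]*z[i,2]
                                + L33[popi[i]]*z[i,3])
  }
  b[1] ~ dnorm(0, %.8f)
  for (j in 2:7) { b[j] ~ dnorm(0, %.8f) }
  for (k in 1:2) {
    # D-vine construction of an LKJ(eta = 2) correlation matrix (d = 3)
    t12[k] ~ dbeta(2.5, 2.5); r12[k] <- 2*t12[k] - 1
    t23[k] ~ dbeta(2.5, 2.5); r23[k] <- 2*t23[k] - 1
    t13[k] ~ dbeta(2, 2);     pc13[k] <- 2*t13[k] - 1
    r13[k] <- pc13[k]*sqrt((1 - r12[k]^2)*(1 - r23[k]^2)) + r12[k]*r23[k]
    L21[k] <- r12[k];  L22[k] <- sqrt(1 - r12[k]^2)
    L31[k] <- r13[k];  L32[k] <- (r23[k] - r12[k]*r13[k]) / L22[k]
    L33[k] <- sqrt(max(1 - L31[k]^2 - L32[k]^2, 1e-12))
    for (j in 1:3) { sid[k,j] ~ dt(0, %.8f, 3) T(0,) }
    syear[k] ~ dt(0, %.8f, 3) T(0,)
    scoh[k]  ~ dt(0, %.8f, 3) T(0,)
  }
  for (a in 1:NY) { zv[a] ~ dnorm(0, 1); v[a] <- syear[ypop[a]] * zv[a] }
  for (a in 1:NC) { zw[a] ~ dnorm(0, 1); w[a] <- scoh[cpop[a]] * zw[a] }
}", 1 / prior_int_sd^2, 1 / prior_beta_sd^2,
    1 / prior_sd_scale^2, 1 / prior_sd_scale^2, 1 / prior_sd_scale^2)
}

fixed_effect_names <- c("intercept", "age", "age_sq", "population",
                        "age_x_population", "age_sq_x_population",
                        "primiparity")

#' Fit the hierarchical binomial age-trajectory model
#'
#' Fits, by MCMC, a binomial GLMM for breeding success with linear and
#' quadratic standardized-age effects, a population contrast and its
#' interactions with both age terms, and a primiparity deficit; random
#' intercepts and linear/quadratic age slopes per individual with a separate
#' 3x3 covariance matrix per population; and year and cohort random
#' intercepts with population-specific SDs. Priors: normal(0, 5) for the
#' intercept, normal(0, 2) for other fixed effects, half-Student-t(3, 0, 1)
#' for group-level SDs, and LKJ(eta = 2) for the individual-effect
#' correlation matrices (realised via its D-vine partial-correlation
#' representation). `priors = "flat"` substitutes very diffuse versions of
#' the same families for sensitivity runs.
#'
#' @param records A breeding-record tibble with exactly two populations and
#'   at least two individuals in each.
#' @param control A [sampler_control()] list.
#' @param scaling Optional age scaling (list with `mean`, `sd`); by default
#'   the pooled empirical mean/SD of age is used, see [standardize_age()].
#' @param priors `"paper"` (weakly informative, the default) or `"flat"`.
#' @return A `senes_fit` object: posterior `draws` matrix (merged chains,
#'   named columns) for fixed effects, SDs and correlations; `u_draws`
#'   (draws x individuals x 3) of individual deviations; `individuals`
#'   lookup tibble; `scaling`; `diagnostics` (per-parameter R-hat and bulk
#'   ESS); `converged` flag; the control used.
#' @export
fit_trajectory_model <- function(records, control = sampler_control(),
                                 scaling = NULL, priors = c("paper", "flat")) {
  priors <- match.arg(priors)
  validate_breeding_records(records)
  pops <- sort(unique(records$population))
  if (length(pops) != 2) {
    abort("fit_trajectory_model: exactly two populations are required")
  }
  per_pop <- tapply(records$individual_id, records$population,
                    function(i) length(unique(i)))
  if (any(per_pop < 2)) {
    abort("fit_trajectory_model: need >= 2 individuals per population")
  }
  std <- standardize_age(records, scaling)
  d <- std$records

  individuals <- d |>
    group_by(.data$individual_id, .data$population) |>
    summarise(n_records = n(), .groups = "drop") |>
    arrange(.data$individual_id) |>
    mutate(index = row_number(),
           pop_index = match(.data$population, pops))

  yr_key <- paste(d$population, d$season)
  yr_levels <- sort(unique(yr_key))
  ch_key <- paste(d$population, d$cohort)
  ch_levels <- sort(unique(ch_key))

  jd <- list(
    y = d$success, x = d$x, x2 = d$x^2,
    popB = as.numeric(d$population == pops[2]),
    primi = as.numeric(d$primiparous),
    id = individuals$index[match(d$individual_id, individuals$individual_id)],
    yr = match(yr_key, yr_levels), ch = match(ch_key, ch_levels),
    N = nrow(d), I = nrow(individuals),
    popi = individuals$pop_index,
    NY = length(yr_levels), ypop = match(sub(" .*", "", yr_levels), pops),
    NC = length(ch_levels), cpop = match(sub(" .*", "", ch_levels), pops)
  )

  pr <- if (priors == "paper") c(5, 2, 1) else c(100, 100, 10)
  model_str <- trajectory_model_string(pr[1], pr[2], pr[3])

  set.seed(control$seed)
  chain_seeds <- sample.int(2^30, control$chains)
  rngs <- c("base::Wichmann-Hill", "base::Marsaglia-Multicarry",
            "base::Super-Duper", "base::Mersenne-Twister")
  inits <- lapply(seq_len(control$chains), function(k) {
    list(.RNG.name = rngs[(k - 1) %% 4 + 1], .RNG.seed = chain_seeds[k])
  })

  rjags::load.module("glm", quiet = TRUE)
  adapt <- max(100L, floor(control$warmup / 2))
  burn <- control$warmup - adapt
  keep <- control$iter - control$warmup
  pb <- if (control$quiet) "none" else "text"
  m <- rjags::jags.model(textConnection(model_str), data = jd, inits = inits,
                         n.chains = control$chains, n.adapt = adapt,
                         quiet = control$quiet)
  if (burn > 0) update(m, burn, progress.bar = pb)
  monitors <- c("b", "sid", "syear", "scoh", "r12", "r13", "r23", "u")
  samp <- rjags::coda.samples(m, monitors, n.iter = keep, thin = control$thin,
                              progress.bar = pb)

  cn <- coda::varnames(samp)
  pick <- function(nm) which(cn == nm)
  hyper_map <- c(
    setNames(sprintf("b[%d]", 1:7), fixed_effect_names),
    setNames(as.vector(outer(1:3, 1:2, function(j, k) sprintf("sid[%d,%d]", k, j))),
             as.vector(outer(c("sd_id_intercept", "sd_id_age", "sd_id_age_sq"),
                             pops, paste, sep = "_"))),
    setNames(sprintf("syear[%d]", 1:2), paste("sd_year", pops, sep = "_")),
    setNames(sprintf("scoh[%d]", 1:2), paste("sd_cohort", pops, sep = "_")),
    setNames(sprintf("r12[%d]", 1:2), paste("cor_intercept_age", pops, sep = "_")),
    setNames(sprintf("r13[%d]", 1:2), paste("cor_intercept_age_sq", pops, sep = "_")),
    setNames(sprintf("r23[%d]", 1:2), paste("cor_age_age_sq", pops, sep = "_"))
  )

  chain_arrays <- lapply(samp, as.matrix)
  per_param_mat <- function(col) {
    sapply(chain_arrays, function(a) a[, col])  # iterations x chains
  }
  diagnostics <- tibble(
    parameter = names(hyper_map),
    rhat = vapply(hyper_map, function(v) rhat_rank(per_param_mat(pick(v))), 0),
    ess = vapply(hyper_map, function(v) ess_bulk(per_param_mat(pick(v))), 0)
  )

  all_draws <- do.call(rbind, chain_arrays)
  draws <- all_draws[, unname(hyper_map), drop = FALSE]
  colnames(draws) <- names(hyper_map)

  n_draws <- nrow(all_draws)
  u_draws <- array(NA_real_, c(n_draws, jd$I, 3))
  for (j in 1:3) {
    cols <- sprintf("u[%d,%d]", seq_len(jd$I), j)
    u_draws[, , j] <- all_draws[, cols, drop = FALSE]
  }

  gate <- diagnostics[!grepl("^cor_", diagnostics$parameter), ]
  converged <- all(gate$rhat <= control$rhat_max) && all(gate$ess >= control$ess_min)
  if (!converged) {
    warn(paste0("fit_trajectory_model: convergence gate not met (max R-hat ",
                sprintf("%.3f", max(gate$rhat)), ", min bulk ESS ",
                sprintf("%.0f", min(gate$ess)), "); inspect diagnostics"))
  }

  structure(list(
    draws = draws, u_draws = u_draws,
    individuals = individuals[, c("individual_id", "population", "n_records", "index")],
    populations = pops, scaling = std$scaling,
    diagnostics = diagnostics, converged = converged,
    control = control, priors = priors,
    n_obs = nrow(d), n_chains = control$chains, n_draws = n_draws
  ), class = "senes_fit")
}

#' @export
print.senes_fit <- function(x, ...) {
  cat("Hierarchical binomial age-trajectory model (MCMC)\n")
  cat(sprintf("  %d records, %d individuals, populations %s\n", x$n_obs,
              nrow(x$individuals), paste(x$populations, collapse = "/")))
  cat(sprintf("  %d chains, %d kept draws; converged: %s (max R-hat %.3f)\n",
              x$n_chains, x$n_draws, x$converged, max(x$diagnostics$rhat)))
  cat(sprintf("  age scaling: mean %.2f, sd %.2f years\n",
              x$scaling$mean, x$scaling$sd))
  invisible(x)
}

#' Tidy posterior summaries of a trajectory-model fit
#'
#' @param x A `senes_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: posterior mean, SD, central
#'   95% interval bounds, R-hat and bulk ESS.
#' @method tidy senes_fit
#' @export
tidy.senes_fit <- function(x, ...) {
  qs <- apply(x$draws, 2, quantile, probs = c(0.025, 0.975))
  tibble(
    term = colnames(x$draws),
    estimate = colMeans(x$draws),
    std.error = apply(x$draws, 2, sd),
    conf.low = qs[1, ], conf.high = qs[2, ],
    rhat = x$diagnostics$rhat[match(colnames(x$draws), x$diagnostics$parameter)],
    ess = x$diagnostics$ess[match(colnames(x$draws), x$diagnostics$parameter)]
  )
}

#' One-line summary of a trajectory-model fit
#'
#' @param x A `senes_fit`.
#' @param ... Unused.
#' @return A one-row tibble: sizes, sampler settings, convergence.
#' @method glance senes_fit
#' @export
glance.senes_fit <- function(x, ...) {
  tibble(
    n_obs = x$n_obs, n_individuals = nrow(x$individuals),
    n_chains = x$n_chains, n_draws = x$n_draws,
    converged = x$converged,
    max_rhat = max(x$diagnostics$rhat), min_ess = min(x$diagnostics$ess)
  )
}
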
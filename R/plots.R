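#' Plot population-level age trajectories of breeding success
#'
#' Posterior-mean success-probability curves over age for each population,
#' with pointwise 95% credible ribbons computed from the posterior draws of
#' the population curves.
#'
#' @param object A `senes_fit`.
#' @param age_range Age range in years to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot senes_fit
#' @export
autoplot.senes_fit <- function(object, age_range = c(5, 40), ...) {
  ages <- seq(age_range[1], age_range[2], length.out = 200)
  x <- (ages - object$scaling$mean) / object$scaling$sd
  pc <- extract_population_curves(object)
  grid <- purrr::map2(pc$population, pc$draws, function(pop, d) {
    eta <- cbind(1, x, x^2) %*% t(d)  # ages x draws
    p <- plogis(eta)
    tibble(population = pop, age = ages,
           p = rowMeans(p),
           lo = apply(p, 1, quantile, 0.025),
           hi = apply(p, 1, quantile, 0.975))
  }) |> bind_rows()
  ggplot2::ggplot(grid, ggplot2::aes(.data$age, .data$p,
                                     colour = .data$population,
                                     fill = .data$population)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Age (years)", y = "P(successful reproduction)",
                  colour = "Population", fill = "Population") +
    ggplot2::theme_minimal()
}

#' Fast-slow continuum plot: onset age versus senescence rate
#'
#' Scatter of individual point-estimate onset ages against senescence
#' rates, coloured by population; a negative association indicates a
#' fast-slow continuum of life-history strategies.
#'
#' @param life_history A life-history tibble from [derive_life_history()].
#' @return A ggplot object.
#' @export
plot_fast_slow <- function(life_history) {
  lh <- life_history[!life_history$excluded, , drop = FALSE]
  ggplot2::ggplot(lh, ggplot2::aes(.data$onset_age, .data$senescence_rate,
                                   colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = "Age at onset of senescence (years)",
                  y = "Senescence rate (probability / year)",
                  colour = "Population") +
    ggplot2::theme_minimal()
}

#' Coefficient intervals from a propagated fitness analysis
#'
#' Means with 2.5-97.5 percentile error bars of each GLM coefficient over
#' the posterior-resampling re-runs.
#'
#' @param object A `senes_propagated`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot senes_propagated
#' @export
autoplot.senes_propagated <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$mean, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("Coefficient (%s model, %d re-runs)",
                              object$predictor, object$n_reruns),
                  y = NULL) +
    ggplot2::theme_minimal()
}
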
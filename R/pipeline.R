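#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()] with defaults
#' mirroring the headline study settings (8 chains of 4000 iterations with
#' 2000 warm-up, 1000-resample overlap bootstrap, 2000 propagation re-runs,
#' the default two-population simulation scenarios). Any subset of fields
#' can be overridden via a user list or YAML file.
#'
#' @return A nested configuration list.
#' @export
pipeline_config <- function() {
  list(
    seed = 1,
    out_dir = "senescurve_run",
    records = NULL,
    simulate = list(n_a = 360, n_b = 874),
    filter = list(max_first_age = 20, dead_gap = 4, min_attempts = 0,
                  min_cohort = NULL),
    sampler = list(chains = 8, iter = 4000, warmup = 2000),
    derive = list(max_onset = 40, early_age = 10),
    compare = list(n_boot = 1000),
    fitness = list(cohort_before = 2000, dead_only = TRUE, n_reruns = 2000),
    allow_nonconverged = FALSE
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

load_pipeline_config <- function(config) {
  user <- if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config error: file not found: ", config))
    yaml::read_yaml(config)
  } else if (is.list(config)) config else {
    abort("config error: config must be a list or a YAML file path")
  }
  cfg <- merge_config(pipeline_config(), user)
  if (is.null(cfg$seed)) abort("config error: seed must be set")
  if (!is.null(cfg$records) && !file.exists(cfg$records)) {
    abort(paste0("config error: records file not found: ", cfg$records))
  }
  cfg
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[senescurve] stage %s ...", name))
  out <- tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
  message(sprintf("[senescurve] stage %s done (%.1f s)", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Run the full senescence analysis pipeline
#'
#' Orchestrates simulate (or load) -> filter -> fit -> derive -> compare ->
#' fitness as a reproducible run. Every stage consumes only files written by
#' earlier stages, so any stage can be re-run independently from its
#' artifacts. Sub-seeds fan out deterministically from the root seed
#' (simulate: seed + 1, fit: seed + 2, compare: seed + 3, fitness:
#' seed + 4); this fan-out is recorded in the summary.
#'
#' @param config A configuration list (see [pipeline_config()]) or the path
#'   to a YAML file of overrides.
#' @param out_dir Output directory for artifacts; overrides
#'   `config$out_dir`.
#' @return The summary list (also written to `summary.json`), invisibly.
#'   Artifacts: `records.csv`, `truth.json` (if simulated),
#'   `filtered.csv`, `dead_flags.csv`, `fit.rds`, `fit_summary.csv`,
#'   `life_history.csv`, `compare.json`, `fitness.json`, `summary.json`,
#'   `report.md`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- load_pipeline_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$out_dir, f)
  seed <- as.integer(cfg$seed)

  records_path <- if (is.null(cfg$records)) {
    stage("simulate", {
      sc_a <- default_scenario("A")
      sc_b <- default_scenario("B")
      sc_a$n_individuals <- cfg$simulate$n_a
      sc_b$n_individuals <- cfg$simulate$n_b
      sim <- simulate_two_population_study(sc_a, sc_b, seed = seed + 1L)
      write_breeding_records(sim$records, p("records.csv"))
      truth <- list(
        seed = seed + 1L,
        scaling = sim$truth$scaling,
        individuals = sim$truth$individuals,
        year_effects = sim$truth$year_effects,
        cohort_effects = sim$truth$cohort_effects
      )
      write_json_artifact(truth, p("truth.json"))
      p("records.csv")
    })
  } else cfg$records

  stage("filter", {
    rec <- read_breeding_records(records_path)
    if (!is.null(cfg$filter$min_cohort)) {
      rec <- keep_attrs(rec[rec$cohort >= cfg$filter$min_cohort, ], rec)
    }
    rec <- filter_first_breeding_age(rec, cfg$filter$max_first_age)
    if (cfg$filter$min_attempts > 0) {
      rec <- subset_min_attempts(rec, cfg$filter$min_attempts)
    }
    dead <- mark_presumed_dead(rec, cfg$filter$dead_gap)
    write_breeding_records(rec, p("filtered.csv"))
    readr::write_csv(dead, p("dead_flags.csv"))
  })

  fit <- stage("fit", {
    rec <- read_breeding_records(p("filtered.csv"))
    control <- sampler_control(chains = cfg$sampler$chains,
                               iter = cfg$sampler$iter,
                               warmup = cfg$sampler$warmup,
                               seed = seed + 2L)
    f <- withCallingHandlers(
      fit_trajectory_model(rec, control),
      warning = function(w) {
        if (!cfg$allow_nonconverged &&
            grepl("convergence gate", conditionMessage(w))) {
          abort(conditionMessage(w))
        }
        invokeRestart("muffleWarning")
      })
    saveRDS(f, p("fit.rds"))
    readr::write_csv(tidy(f), p("fit_summary.csv"))
    f
  })

  stage("derive", {
    f <- readRDS(p("fit.rds"))
    curves <- extract_individual_curves(f, include_draws = FALSE)
    lh <- derive_life_history(curves, f$scaling,
                              max_onset = cfg$derive$max_onset,
                              early_age = cfg$derive$early_age)
    readr::write_csv(lh, p("life_history.csv"))
  })

  comparison <- stage("compare", {
    f <- readRDS(p("fit.rds"))
    lh <- readr::read_csv(p("life_history.csv"), show_col_types = FALSE)
    cmp <- compare_populations(f, lh, early_age = cfg$derive$early_age,
                               n_boot = cfg$compare$n_boot, seed = seed + 3L)
    write_json_artifact(unclass(cmp), p("compare.json"))
    cmp
  })

  fitness <- stage("fitness", {
    f <- readRDS(p("fit.rds"))
    rec <- read_breeding_records(p("filtered.csv"))
    dead <- readr::read_csv(p("dead_flags.csv"), show_col_types = FALSE)
    lh <- readr::read_csv(p("life_history.csv"), show_col_types = FALSE)
    sub <- subset_fitness_cohort(rec, dead,
                                 cohort_before = cfg$fitness$cohort_before,
                                 dead_only = cfg$fitness$dead_only)
    outputs <- compute_lifetime_outputs(sub)
    d <- inner_join(lh[!lh$excluded, ],
                    outputs[c("individual_id", "lrs", "n_attempts")],
                    by = "individual_id")
    models <- fitness_models(d, "lrs")
    curves <- extract_individual_curves(f)
    curves <- curves[curves$individual_id %in% d$individual_id, ]
    prop_onset <- propagate_uncertainty(
      curves, f$scaling, outputs, "lrs", "onset_age",
      n_reruns = cfg$fitness$n_reruns, seed = seed + 4L,
      max_onset = cfg$derive$max_onset, early_age = cfg$derive$early_age)
    prop_rate <- propagate_uncertainty(
      curves, f$scaling, outputs, "lrs", "senescence_rate",
      n_reruns = cfg$fitness$n_reruns, seed = seed + 4L,
      max_onset = cfg$derive$max_onset, early_age = cfg$derive$early_age)
    robust <- attempts_robustness(d)
    out <- list(
      n_individuals = nrow(d),
      onset_model = tidy(models$onset),
      rate_model = tidy(models$rate),
      onset_slopes = population_slopes(models$onset),
      rate_slopes = population_slopes(models$rate),
      onset_propagated = tidy(prop_onset),
      rate_propagated = tidy(prop_rate),
      attempts_onset_model = tidy(robust$onset),
      attempts_rate_model = tidy(robust$rate)
    )
    write_json_artifact(out, p("fitness.json"))
    out
  })

  summary <- stage("summary", {
    lh <- readr::read_csv(p("life_history.csv"), show_col_types = FALSE)
    lh_summary <- lh |>
      filter(!.data$excluded) |>
      group_by(.data$population) |>
      summarise(across(c("onset_age", "senescence_rate",
                         "early_life_performance", "peak_performance"),
                       mean), n = n(), .groups = "drop")
    s <- list(
      package_version = as.character(utils::packageVersion("senescurve")),
      seed = seed,
      seed_fanout = list(simulate = seed + 1L, fit = seed + 2L,
                         compare = seed + 3L, fitness = seed + 4L),
      converged = fit$converged,
      fit = tidy(fit),
      population_curves = extract_population_curves(fit, include_draws = FALSE),
      life_history_summary = lh_summary,
      overlap = comparison$overlap,
      variances = comparison$variances,
      correlations = comparison$correlations,
      fitness = fitness
    )
    write_json_artifact(s, p("summary.json"))
    s
  })

  make_report(cfg$out_dir)
  invisible(summary)
}

fmt_table <- function(df, digits = 4) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  }
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Render a human-readable pipeline report
#'
#' Assembles a markdown report from the artifacts in a pipeline output
#' directory: fixed/random-effect posterior summaries, the variance-ratio
#' table, overlap coefficients, onset-rate correlations and the fitness
#' coefficient tables. Missing artifacts are marked absent rather than
#' raising an error.
#'
#' @param out_dir A [run_pipeline()] output directory.
#' @param write Write `report.md` into `out_dir` (default `TRUE`).
#' @return The report as a single markdown string, invisibly.
#' @export
make_report <- function(out_dir, write = TRUE) {
  p <- function(f) file.path(out_dir, f)
  sec <- function(title, path, render) {
    body <- if (file.exists(path)) render(path) else "*artifact absent*"
    paste0("## ", title, "\n\n", body, "\n")
  }
  parts <- c(
    "# Reproductive senescence pipeline report\n",
    sec("Age-trajectory model (posterior summaries)", p("fit_summary.csv"),
        function(f) fmt_table(readr::read_csv(f, show_col_types = FALSE))),
    sec("Variances and population ratios", p("compare.json"), function(f) {
      cmp <- jsonlite::read_json(f, simplifyVector = TRUE)
      fmt_table(cmp$variances)
    }),
    sec("Posterior overlap of life-history parameters", p("compare.json"),
        function(f) {
          cmp <- jsonlite::read_json(f, simplifyVector = TRUE)
          fmt_table(cmp$overlap)
        }),
    sec("Onset-rate correlations", p("compare.json"), function(f) {
      cmp <- jsonlite::read_json(f, simplifyVector = TRUE)
      fmt_table(cmp$correlations)
    }),
    sec("Fitness models (lifetime reproductive success)", p("fitness.json"),
        function(f) {
          ft <- jsonlite::read_json(f, simplifyVector = TRUE)
          paste0("Onset model:\n\n", fmt_table(ft$onset_model),
                 "\n\nRate model:\n\n", fmt_table(ft$rate_model),
                 "\n\nPropagated (onset):\n\n", fmt_table(ft$onset_propagated),
                 "\n\nPropagated (rate):\n\n", fmt_table(ft$rate_propagated))
        }),
    sec("Run metadata", p("summary.json"), function(f) {
      s <- jsonlite::read_json(f, simplifyVector = TRUE)
      paste0("Root seed: ", s$seed, "; stage seeds: simulate ",
             s$seed_fanout$simulate, ", fit ", s$seed_fanout$fit,
             ", compare ", s$seed_fanout$compare, ", fitness ",
             s$seed_fanout$fitness, ". Converged: ", s$converged,
             ". Package version: ", s$package_version, ".")
    })
  )
  report <- paste(parts, collapse = "\n")
  if (write) writeLines(report, p("report.md"))
  invisible(report)
}
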
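test_that("CSV round trip reads back validated records", {
  rec <- five_bird_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_breeding_records(rec, path)
  back <- read_breeding_records(path)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$individual_id, rec$individual_id)
  expect_equal(back$success, rec$success)
  expect_type(back$primiparous, "logical")
  expect_equal(attr(back, "study_final_season"), max(rec$season))
})

test_that("malformed input is rejected with row-level diagnostics", {
  rec <- five_bird_fixture()
  path <- withr::local_tempfile(fileext = ".csv")

  write_breeding_records(rec[setdiff(names(rec), "cohort")], path)
  expect_error(read_breeding_records(path), "missing column.*cohort")

  bad <- rec
  bad$age[3] <- "ten"
  readr::write_csv(bad, path)
  expect_error(read_breeding_records(path), "non-integer age.*3")

  dup <- dplyr::bind_rows(rec, rec[1, ])
  dup$primiparous <- as.integer(dup$primiparous)
  readr::write_csv(dup, path)
  expect_error(read_breeding_records(path), paste0("duplicate.*", nrow(dup)))

  mism <- rec
  mism$age[5] <- mism$age[5] + 1L
  expect_error(validate_breeding_records(mism), "age != season - cohort.*5")
})

test_that("first-breeding age filter removes late-first-breeders entirely", {
  rec <- five_bird_fixture()
  # a2 first bred at 21, b2 at 20; a3 first bred at 19 and stays
  out <- filter_first_breeding_age(rec, max_age = 20)
  expect_setequal(unique(out$individual_id), c("a1", "a3", "b1"))
  expect_equal(nrow(out[out$individual_id == "a3", ]), 7)

  # retained individuals are untouched; filter is idempotent
  expect_equal(filter_first_breeding_age(out, 20), out)
})

test_that("presumed-dead rule flags absence from the final gap seasons", {
  rec <- toy_records(list(
    dead_bird = list(population = "A", cohort = 2009, ages = 8:10,
                     successes = c(1, 0, 1)),   # last seen 2019
    alive_gap = list(population = "A", cohort = 2010, ages = 8:10,
                     successes = c(1, 1, 0)),   # last seen 2020
    alive_now = list(population = "B", cohort = 2013, ages = 8:10,
                     successes = c(0, 1, 1))    # last seen 2023
  ), final_season = 2023)
  flags <- mark_presumed_dead(rec, gap = 4)
  expect_true(flags$presumed_dead[flags$individual_id == "dead_bird"])
  expect_false(flags$presumed_dead[flags$individual_id == "alive_gap"])
  expect_false(flags$presumed_dead[flags$individual_id == "alive_now"])
  expect_error(mark_presumed_dead(rec, gap = 0), "gap")
})

test_that("minimum-attempts subset keeps individuals with >= k records", {
  rec <- toy_records(list(
    two = list(population = "A", cohort = 1980, ages = 8:9, successes = c(0, 1)),
    four = list(population = "A", cohort = 1981, ages = 8:11, successes = rep(1, 4)),
    seven = list(population = "B", cohort = 1982, ages = 8:14, successes = rep(0, 7))
  ))
  out <- subset_min_attempts(rec, k = 4)
  expect_setequal(unique(out$individual_id), c("four", "seven"))
  expect_equal(subset_min_attempts(rec, k = 1), rec)
  expect_equal(subset_min_attempts(out, k = 4), out)
})

test_that("fitness cohort subset requires early fledging and death", {
  rec <- toy_records(list(
    old_dead = list(population = "A", cohort = 1990, ages = 8:10,
                    successes = c(1, 1, 0)),    # last seen 2000
    old_alive = list(population = "A", cohort = 1990, ages = 8:33,
                     successes = rep(c(1, 0), 13)),  # last seen 2023
    young_dead = list(population = "B", cohort = 2005, ages = 8:10,
                      successes = c(0, 0, 1))   # last seen 2015
  ), final_season = 2023)
  flags <- mark_presumed_dead(rec)
  out <- subset_fitness_cohort(rec, flags, cohort_before = 2000)
  expect_setequal(unique(out$individual_id), "old_dead")
  expect_error(subset_fitness_cohort(rec, NULL, dead_only = TRUE), "dead_flags")
  # cohort-only filtering drops just the late cohort
  out2 <- subset_fitness_cohort(rec, dead_only = FALSE)
  expect_setequal(unique(out2$individual_id), c("old_dead", "old_alive"))
})

test_that("lifetime outputs match hand counts and conserve totals", {
  rec <- toy_records(list(
    one = list(population = "A", cohort = 1980, ages = 8:10, successes = c(1, 0, 1)),
    two = list(population = "B", cohort = 1981, ages = 8:14, successes = rep(0, 7))
  ))
  out <- compute_lifetime_outputs(rec)
  expect_equal(out$lrs[out$individual_id == "one"], 2)
  expect_equal(out$n_attempts[out$individual_id == "one"], 3)
  expect_equal(out$lrs[out$individual_id == "two"], 0)
  expect_true(all(out$lrs <= out$n_attempts))
  expect_equal(sum(out$lrs), sum(rec$success))

  sim <- simulate_two_population_study(seed = 11)
  lo <- compute_lifetime_outputs(sim$records)
  expect_true(all(lo$lrs <= lo$n_attempts))
  by_pop <- tapply(lo$lrs, lo$population, sum)
  expect_equal(sum(by_pop), sum(sim$records$success))
})

test_that("filters are idempotent and commute on generated tables", {
  for (s in 1:3) {
    sim <- simulate_population(default_scenario("A"), seed = s)
    rec <- sim$records
    f1 <- filter_first_breeding_age(rec, 14)
    expect_equal(filter_first_breeding_age(f1, 14), f1)
    f2 <- subset_min_attempts(rec, 4)
    expect_equal(subset_min_attempts(f2, 4), f2)
    ab <- subset_min_attempts(filter_first_breeding_age(rec, 14), 4)
    ba <- filter_first_breeding_age(subset_min_attempts(rec, 4), 14)
    expect_setequal(unique(ab$individual_id), unique(ba$individual_id))
  }
})
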
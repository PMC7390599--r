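# Synthetic session generator: rate functions, Poisson statistics,
# determinism, population sampling, file round-trip.

test_that("rate functions reproduce their closed forms", {
  task <- task_config()
  r_unt <- build_rate_function(unit_spec(1, "untuned", 5), task, 2, 1)
  expect_equal(r_unt(c(-0.5, 0, 1.5, 3.2)), rep(5, 4))

  # zero gain: identical curves for every value
  tgrid <- seq(-0.5, 3.5, by = 0.05)
  r0 <- lapply(1:4, function(v)
    build_rate_function(unit_spec(1, "stable_linear", 4, value_gain = 0),
                        task, v, 1)(tgrid))
  for (v in 2:4) expect_equal(r0[[v]], r0[[1]])

  # sequential bump: maximal at the centre, baseline far away
  sp <- unit_spec(1, "sequential", 3, value_gain = 2, bump_center = 1,
                  bump_sd = 0.15)
  r_seq <- build_rate_function(sp, task, 4, 1)
  expect_equal(r_seq(1), 3 + 8, tolerance = 1e-12)
  expect_lt(abs(r_seq(0) - 3), 1e-6)
  expect_lt(abs(r_seq(2) - 3), 1e-6)
  # analytic Gaussian at an intermediate point
  expect_equal(r_seq(1.2), 3 + 8 * exp(-0.2^2 / (2 * 0.15^2)),
               tolerance = 1e-12)

  # reversing flips the value slope at reversal_time
  rv <- unit_spec(1, "reversing", 10, value_gain = 2, reversal_time = 1.5)
  r_rev <- build_rate_function(rv, task, 4, 1)
  expect_equal(r_rev(1.0), 10 + 2 * 1.5)
  expect_equal(r_rev(2.0), 10 - 2 * 1.5)

  # rates are clipped at zero
  low <- unit_spec(1, "stable_linear", 1, value_gain = 5)
  expect_gte(min(build_rate_function(low, task, 1, 1)(tgrid)), 0)

  expect_error(build_rate_function(unit_spec(1, "untuned", 5), task, 9, 1),
               "invalid")
})

test_that("spike counts match the rate integral within Monte-Carlo error", {
  task <- task_config(trials_per_condition = 25) # 200 trials
  classes <- list(
    unit_spec(1, "untuned", 10),
    unit_spec(2, "stable_linear", 6, value_gain = 2),
    unit_spec(3, "sequential", 5, value_gain = 2, bump_center = 1,
              bump_sd = 0.2),
    unit_spec(4, "reversing", 8, value_gain = 2, reversal_time = 1.5),
    unit_spec(5, "time_ramp", 4, value_gain = 5))
  s <- generate_session(classes, task, seed = 11)
  tgrid <- seq(s$span[1], s$span[2], length.out = 4001)
  dt <- diff(tgrid[1:2])
  for (u in seq_along(classes)) {
    for (v in c(1, 4)) {
      rows <- which(s$trials$value == v & s$trials$type == 1)
      rf <- build_rate_function(classes[[u]], task, v, 1)
      expected <- sum(rf(tgrid)) * dt
      counts <- lengths(s$spikes[[u]][rows])
      se <- sqrt(expected / length(rows)) # Poisson SE of the mean
      expect_lt(abs(mean(counts) - expected), 3.5 * se)
    }
  }
})

test_that("sessions are balanced and seed-deterministic", {
  task <- task_config(trials_per_condition = 5)
  specs <- sample_population(c(untuned = 3), task, seed = 3)
  s1 <- generate_session(specs, task, seed = 42)
  s2 <- generate_session(specs, task, seed = 42)
  s3 <- generate_session(specs, task, seed = 43)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$trials, s2$trials)
  expect_false(identical(s1$spikes, s3$spikes))
  tab <- table(s1$trials$value, s1$trials$type)
  expect_true(all(tab == 5))
  expect_identical(unname(s1$ground_truth), rep("untuned", 3))
})

test_that("sample_population tiles bump centres and is deterministic", {
  task <- task_config()
  specs <- sample_population(c(stable_linear = 30, sequential = 40,
                               untuned = 50), task, seed = 9)
  expect_length(specs, 120)
  cls <- vapply(specs, function(x) x$coding_class, character(1))
  expect_equal(unname(table(cls)[c("stable_linear", "sequential", "untuned")]),
               c(30L, 40L, 50L), ignore_attr = TRUE)
  centers <- vapply(specs[cls == "sequential"], function(x) x$bump_center,
                    numeric(1))
  expect_true(all(diff(centers) > 0)) # strictly increasing tiling
  expect_gte(min(centers), task$cue_on)
  expect_lte(max(centers), task$reward)

  specs2 <- sample_population(c(stable_linear = 30, sequential = 40,
                                untuned = 50), task, seed = 9)
  expect_identical(specs, specs2)
  expect_error(sample_population(c(), task, seed = 1), "empty")
})

test_that("session round-trips through the CSV layout", {
  task <- task_config(trials_per_condition = 3)
  specs <- sample_population(c(untuned = 2, stable_linear = 2), task, seed = 5)
  s <- generate_session(specs, task, seed = 6)
  dir <- withr::local_tempdir()
  write_session(s, dir)
  expect_true(all(file.exists(file.path(dir, c("spikes.csv", "trials.csv",
                                               "ground_truth.json")))))
  s2 <- read_session(dir)
  expect_equal(s2$trials$value, s$trials$value)
  expect_equal(s2$ground_truth, s$ground_truth)
  for (u in seq_along(s$spikes))
    for (tr in seq_along(s$spikes[[u]]))
      expect_equal(s2$spikes[[u]][[tr]], s$spikes[[u]][[tr]],
                   tolerance = 1e-12)
})
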
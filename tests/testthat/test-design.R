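test_that("default schedule reproduces the study design arithmetic", {
  sched <- build_trial_schedule(2, 4, 8, 32, seed = 7)
  expect_equal(nrow(sched), 2 * 4 * 144)
  per_block <- table(sched$participant, sched$block)
  expect_true(all(per_block == 144))
  b1 <- sched[sched$participant == 1 & sched$block == 1, ]
  counts <- table(b1$frequency)
  expect_equal(unname(counts[as.character(c(10, 14))]), c(32, 32),
               ignore_attr = TRUE)
  expect_true(all(counts >= 8))
  # equal prevalence of burst conditions within every frequency
  cell <- table(b1$frequency, b1$n_bursts)
  expect_true(all(apply(cell, 1, function(r) length(unique(r)) == 1)))
})

test_that("frequency-by-burst cell counts follow the repetition arguments", {
  sched <- build_trial_schedule(1, 1, 8, 32, seed = 3)
  cell <- table(sched$frequency, sched$n_bursts)
  base <- setdiff(presentation_frequencies, high_prevalence_frequencies)
  expect_true(all(cell[as.character(base), ] == 2))
  expect_true(all(cell[as.character(c(10, 14)), ] == 8))
})

test_that("indivisible repetition counts are an invalid design", {
  expect_error(build_trial_schedule(1, 1, 6, 32, seed = 1), "divisible")
  expect_error(build_trial_schedule(1, 1, 8, 30, seed = 1), "divisible")
})

test_that("schedules are seed-reproducible; the seed permutes order, not counts", {
  a <- build_trial_schedule(1, 2, 8, 32, seed = 5)
  b <- build_trial_schedule(1, 2, 8, 32, seed = 5)
  expect_identical(a, b)
  c <- build_trial_schedule(1, 2, 8, 32, seed = 6)
  expect_false(identical(a$frequency, c$frequency))
  expect_identical(table(a$frequency, a$n_bursts), table(c$frequency, c$n_bursts))
})

test_that("stimulus trains place burst onsets at multiples of the wavelength", {
  tr <- synthesize_stimulus_train(6, 5, 0.5, 1200)
  expect_equal(tr$onsets * 1000, c(0, 1, 2, 3, 4) * 1000 / 6, tolerance = 1e-9)
  expect_equal(tr$duration, (5 - 1 + 0.5) / 6)

  tr3 <- synthesize_stimulus_train(3, 4, 0.5, 1200)
  onset_samples <- which(diff(c(0, tr3$envelope)) == 1) - 1
  expect_equal(onset_samples, c(0, 400, 800, 1200))
  # envelope is 1 during bursts, 0 in gaps
  expect_setequal(unique(tr3$envelope), c(0, 1))
  # 4 bursts of half a cycle each over a 3.5-wavelength train
  expect_equal(mean(tr3$envelope == 1), 2 / 3.5, tolerance = 0.01)
})

test_that("a full duty cycle yields a gapless envelope", {
  tr <- synthesize_stimulus_train(8, 4, 1, 1200)
  expect_true(all(tr$envelope == 1))
})

test_that("invalid stimulus parameters are rejected", {
  expect_error(synthesize_stimulus_train(0, 5))
  expect_error(synthesize_stimulus_train(6, 3))
  expect_error(synthesize_stimulus_train(6, 5, duty_cycle = 0))
})
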
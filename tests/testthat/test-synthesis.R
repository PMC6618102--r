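test_that("epoch synthesis is deterministic under a fixed seed", {
  tr <- one_trial(10, 5)
  truth <- ground_truth()
  e1 <- synthesize_epoch(tr, truth, seed = 99)
  e2 <- synthesize_epoch(tr, truth, seed = 99)
  expect_identical(e1$samples, e2$samples)
  e3 <- synthesize_epoch(tr, truth, seed = 100)
  expect_false(identical(e1$samples, e3$samples))
  expect_length(e1$samples, 1920)
  expect_equal(e1$times[1], -0.8)
  expect_lt(max(e1$times), 0.8)
})

test_that("background spectral exponent is recoverable within 0.1", {
  truth <- null_truth(alpha = 1, participant_alpha_sd = 0,
                      participant_scale_sd = 0,
                      evoked = list(amplitude = 0, frequency = 8,
                                    onset = 0.03, duration = 0.25))
  tr <- one_trial()
  x <- vapply(1:200, function(i) synthesize_epoch(tr, truth, seed = i)$samples,
              numeric(1920))
  tf <- hilbert_tf(x, 1200, freqs = 3:100, decim = 8)
  menv <- apply(tf$amplitude, 2, mean)
  slope <- unname(coef(lm(log(menv) ~ log(3:100)))[2])
  expect_equal(slope, -1, tolerance = 0.1)
})

test_that("expected background envelope matches simulated envelopes", {
  truth <- null_truth(participant_alpha_sd = 0, participant_scale_sd = 0,
                      evoked = list(amplitude = 0, frequency = 8,
                                    onset = 0.03, duration = 0.25))
  tr <- one_trial()
  x <- vapply(1:120, function(i) synthesize_epoch(tr, truth, seed = 500 + i)$samples,
              numeric(1920))
  tf <- hilbert_tf(x, 1200, freqs = c(5, 10, 40, 71), decim = 8)
  for (j in 1:4) {
    emp <- mean(tf$amplitude[, j, ])
    th <- expected_bg_envelope(1, 1, c(5, 10, 40, 71)[j])
    expect_equal(emp / th, 1, tolerance = 0.08)
  }
})

test_that("with g = 0 the presentation band carries no stimulus effect", {
  st <- simulate_study(null_truth(reject_rate = 0), 1, 1, 16, 16, seed = 44)
  sub <- st$schedule
  tf <- hilbert_tf(st$epochs[[1]], st$fs, st$times, freqs = 10, decim = 8)
  amp10 <- window_mean_amplitude(tf, c(0.08, 0.43), 10)
  matched <- amp10[sub$frequency == 10]
  other <- amp10[sub$frequency != 10]
  expect_gt(t.test(matched, other)$p.value, 0.01)
})

test_that("behaviour under zero coupling is uniform guessing at 0.25", {
  sched <- build_trial_schedule(4, 1, 12, 12, seed = 2)
  prof <- matrix(rep(1 / presentation_frequencies, 4), nrow = 4, byrow = TRUE,
                 dimnames = list(NULL, presentation_frequencies))
  truth <- null_truth()
  out <- simulate_behaviour(sched, prof, truth, seed = 10)
  expect_lt(abs(mean(out$correct) - 0.25), 0.03)
  # wrong responses stay within the remaining 3 options
  wrong <- out[!out$correct, ]
  expect_true(all(wrong$response %in% 4:7))
  expect_true(all(wrong$response != wrong$n_bursts))
})

test_that("a saturated coupling makes every response correct", {
  sched <- build_trial_schedule(1, 1, 8, 8, seed = 2)
  prof <- setNames(1 / presentation_frequencies, presentation_frequencies)
  truth <- ground_truth(behaviour = list(floor = 0.25, slope = 0, intercept = 1))
  out <- simulate_behaviour(sched, prof, truth, seed = 1)
  expect_true(all(out$correct))
  expect_identical(out$response, out$n_bursts)
})

test_that("simulated studies mark rejected trials at the configured rate", {
  st <- simulate_study(null_truth(), 4, 1, 12, 12, seed = 3)
  expect_lt(abs(mean(st$schedule$rejected) - 0.068), 0.03)
  st0 <- simulate_study(null_truth(reject_rate = 0), 1, 1, 8, 8, seed = 3)
  expect_true(!any(st0$schedule$rejected))
})
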
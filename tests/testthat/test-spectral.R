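fs <- 1200
times <- epoch_times()

test_that("the epoch time axis is half-open with 1,920 samples", {
  expect_length(times, 1920)
  expect_equal(times[1], -0.8)
  expect_equal(diff(times)[1], 1 / 1200)
  expect_lt(max(times), 0.8)
})

test_that("band-pass keeps in-band content and rejects out-of-band content", {
  x10 <- sin(2 * pi * 10 * times)
  y <- bandpass(x10, fs, 10)
  mid <- 400:1500
  expect_equal(sd(y[mid]) / sd(x10[mid]), 1, tolerance = 0.01)
  x40 <- sin(2 * pi * 40 * times)
  y40 <- bandpass(x40, fs, 10)
  expect_lt(sd(y40[mid]) / sd(x40[mid]), 0.05)
})

test_that("the 3 Hz band clips its lower edge at 0.5 Hz and stays valid", {
  e <- oscrep:::band_edges(3)
  expect_equal(e, c(0.5, 6))
  y <- bandpass(sin(2 * pi * 4 * times), fs, 3)
  expect_true(all(is.finite(y)))
  g <- oscrep:::band_response(c(3, 30), 3)
  expect_gt(g[1], 0.9)
  expect_lt(g[2], 1e-4)
})

test_that("an empty passband errors", {
  expect_error(bandpass(times, fs, 700), "Nyquist")
})

test_that("fft and filtfilt band-pass methods agree away from the edges", {
  set.seed(1)
  x <- sin(2 * pi * 10 * times) + 0.3 * rnorm(1920)
  y1 <- bandpass(x, fs, 10)
  y2 <- bandpass(x, fs, 10, method = "filtfilt")
  mid <- 300:1620
  expect_lt(sqrt(mean((y1[mid] - y2[mid])^2)) / sd(y1[mid]), 0.05)
})

test_that("hilbert_tf recovers sinusoid envelopes in their own band", {
  a <- 2.5
  tf <- hilbert_tf(a * sin(2 * pi * 10 * times), fs)
  mid <- 400:1500
  expect_equal(mean(tf$amplitude[1, which(tf$freqs == 10), mid]), a,
               tolerance = 0.05 * a)
  # two components separate into their own bands with < 5% cross-talk
  x <- sin(2 * pi * 10 * times) + 2 * sin(2 * pi * 40 * times)
  tf2 <- hilbert_tf(x, fs, freqs = c(10, 40))
  expect_equal(mean(tf2$amplitude[1, 1, mid]), 1, tolerance = 0.05)
  expect_equal(mean(tf2$amplitude[1, 2, mid]), 2, tolerance = 0.1)
  x10only <- hilbert_tf(sin(2 * pi * 10 * times), fs, freqs = c(10, 40))
  expect_lt(mean(x10only$amplitude[1, 2, mid]), 0.05)
})

test_that("a constant-zero epoch decomposes to zero amplitude", {
  tf <- hilbert_tf(numeric(1920), fs, freqs = c(5, 50))
  expect_true(all(tf$amplitude == 0))
})

test_that("the default frequency grid has exactly 98 centres", {
  tf <- hilbert_tf(rnorm(1920), fs, decim = 24)
  expect_identical(tf$freqs, 3:100)
  expect_equal(dim(tf$amplitude)[2], 98)
})

test_that("amplitude and phase reconstruct the band-passed series", {
  set.seed(3)
  x <- rnorm(1920)
  tf <- hilbert_tf(x, fs, freqs = c(10, 40))
  for (j in 1:2) {
    rec <- tf$amplitude[1, j, ] * cos(tf$phase[1, j, ])
    bp <- bandpass(x, fs, c(10, 40)[j])
    expect_lt(sqrt(mean((rec - bp)^2)) / sd(bp), 0.01)
  }
})

test_that("time decimation subsamples the analytic signal exactly", {
  set.seed(4)
  x <- matrix(rnorm(1920 * 3), 1920, 3)
  full <- hilbert_tf(x, fs, freqs = c(10, 71))
  dec <- hilbert_tf(x, fs, freqs = c(10, 71), decim = 12)
  expect_equal(dec$amplitude, full$amplitude[, , seq(1, 1920, by = 12)],
               tolerance = 1e-12)
  expect_equal(dec$fs, 100)
})

test_that("band amplitude grows monotonically with injected signal power", {
  set.seed(5)
  noise <- rnorm(1920)
  amps <- c(0.5, 1, 2, 4)
  got <- vapply(amps, function(a) {
    tf <- hilbert_tf(noise + a * sin(2 * pi * 20 * times), fs, freqs = 20)
    mean(tf$amplitude)
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("subtractive baseline behaves on constants, steps, and repeats", {
  mk_tf <- function(ampmat) {
    structure(list(amplitude = array(ampmat, c(1, 1, length(ampmat))),
                   phase = array(0, c(1, 1, length(ampmat))),
                   freqs = 10, times = times, fs = fs, bandwidth = 6,
                   order = 3, decim = 1L, baselined = FALSE),
              class = "osc_tf")
  }
  const <- mk_tf(rep(3, 1920))
  expect_true(all(abs(apply_baseline(const)$amplitude) < 1e-12))
  step <- mk_tf(ifelse(times >= 0.03, 5, 3))
  b <- apply_baseline(step)
  expect_equal(mean(b$amplitude[1, 1, times > 0.1]), 2, tolerance = 1e-9)
  # second application is a no-op once the baseline mean is zero
  twice <- apply_baseline(b)
  expect_equal(twice$amplitude, b$amplitude, tolerance = 1e-12)
  expect_error(apply_baseline(const, c(5, 6)), "window")
})

test_that("window means reduce amplitude correctly", {
  amp <- rep(2.5, 1920)
  tfc <- structure(list(amplitude = array(amp, c(1, 1, 1920)),
                        phase = array(0, c(1, 1, 1920)), freqs = 10,
                        times = times, fs = fs, bandwidth = 6, order = 3,
                        decim = 1L, baselined = FALSE), class = "osc_tf")
  expect_equal(window_mean_amplitude(tfc, c(0.08, 0.43), 10), 2.5)
  # single-sample window returns that sample
  expect_equal(window_mean_amplitude(tfc, c(0, 1 / 1200), 10), 2.5)
  # linear ramp over the window averages to 1/2
  ramp <- pmin(pmax((times + 0.8) / 1.6, 0), 1)
  tfr <- tfc; tfr$amplitude <- array(ramp, c(1, 1, 1920))
  expect_equal(window_mean_amplitude(tfr, c(-0.8, 0.8), 10), 0.5,
               tolerance = 2 / 1920)
})

test_that("entrainment windows follow the seven-burst rule and the caps", {
  w28 <- entrainment_windows(28)
  expect_equal(w28$duration * 1000, 6.5 / 28 * 1000 + 200, tolerance = 0.01)
  expect_equal(w28$active[1], 0.03)
  expect_equal(w28$baseline[2], -0.02)  # ends 50 ms before onset
  # slow trains are capped and must fit within the epoch
  w6 <- entrainment_windows(6)
  expect_gt(w6$nominal_duration, 0.8)
  expect_lte(w6$duration, 0.8)
  expect_gte(w6$baseline[1], -0.8)
  expect_lte(w6$active[2], 0.8)
  # baseline duration always equals active duration
  for (f in presentation_frequencies) {
    w <- entrainment_windows(f)
    expect_equal(diff(w$active), diff(w$baseline), tolerance = 1e-12)
  }
})
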
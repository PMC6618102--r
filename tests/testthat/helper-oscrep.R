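# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Ground truth with the gamma/success coupling switched off (used where a
# stage under test should not be affected by gamma components).
gamma_off <- function(...) {
  ground_truth(gamma = list(frequency = 71.5, amplitude = 0,
                            window = c(-0.65, 0), post_window = c(0.05, 0.45),
                            t_ref = -0.45, preferred_phase = pi / 2,
                            kappa = 0, amp_depth = 0), ...)
}

# Small multi-participant study with behaviour/amplitude coupling and
# entrainment, no gamma: 8 participants x 1 block x 24 trials/frequency.
coupled_study <- function() {
  if (is.null(.fixtures$coupled)) {
    .fixtures$coupled <- simulate_study(gamma_off(), n_participants = 8,
                                        n_blocks = 1, base_reps = 24,
                                        high_prev_reps = 24, seed = 421)
  }
  .fixtures$coupled
}

# Small study with full default truth (gamma coupling on) for the
# success-contrast stage.
success_study <- function() {
  if (is.null(.fixtures$success)) {
    .fixtures$success <- simulate_study(ground_truth(), n_participants = 12,
                                        n_blocks = 1, base_reps = 4,
                                        high_prev_reps = 16, seed = 734)
  }
  .fixtures$success
}

# One-row schedule slice for single-epoch synthesis.
one_trial <- function(frequency = 10, n_bursts = 5, participant = 1,
                      correct = TRUE) {
  data.frame(participant = participant, block = 1L, trial = 1L,
             frequency = frequency, n_bursts = n_bursts,
             response = NA_integer_, correct = correct, rejected = FALSE)
}

# Independent dense-grid quadrature oracle for the JZS Bayes factor
# (substitution g = u / (1 - u); trapezoid rule), kept deliberately
# separate from the package's adaptive-quadrature implementation.
bf10_oracle <- function(t, n, r = sqrt(0.5), k = 40001) {
  nu <- n - 1
  u <- seq(1e-7, 1 - 1e-7, length.out = k)
  g <- u / (1 - u)
  f <- (1 + n * g)^(-0.5) * (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
    r / sqrt(2 * pi) * g^(-1.5) * exp(-r^2 / (2 * g)) / (1 - u)^2
  m1 <- sum((f[-1] + f[-k]) / 2) * (u[2] - u[1])
  m0 <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  m1 / m0
}

# Lightly smoothed null time-frequency difference maps for engine
# calibration (separable 3-point kernel, circular).
null_maps <- function(n = 20, nf = 30, nt = 40) {
  sm <- function(m) {
    k <- c(0.25, 0.5, 0.25)
    m <- apply(m, 2, function(v) stats::filter(v, k, circular = TRUE))
    t(apply(m, 1, function(v) stats::filter(v, k, circular = TRUE)))
  }
  a <- array(rnorm(n * nf * nt), c(n, nf, nt))
  for (p in seq_len(n)) a[p, , ] <- sm(a[p, , ])
  a
}
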
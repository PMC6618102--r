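# Von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0 gives
# the uniform circular distribution. Returns angles in (-pi, pi].
rvm <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(wrap_angle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(out + mu)
}

wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y <= -pi, y + 2 * pi, y)  # wrap to (-pi, pi]
}

# Batch synthesis of epochs for one participant. `freqs`, `bursts`,
# `success` are per-trial vectors. Consumes the current RNG stream.
synth_trials <- function(freqs, bursts, success, pp, truth,
                         fs = 1200, times = epoch_times(fs)) {
  n <- length(times)
  ntr <- length(freqs)
  gain <- background_gain(pp$alpha, pp$scale, fs, n)
  # draw the background directly in the frequency domain: a circular
  # Gaussian process with power spectrum gain^2, identical in law to
  # filtering white noise with `gain` but with a single inverse FFT
  w <- matrix(complex(real = stats::rnorm(n * ntr),
                      imaginary = stats::rnorm(n * ntr)), n, ntr)
  x <- Re(stats::mvfft(w * gain, inverse = TRUE)) / sqrt(n)

  ev_amp <- truth$evoked$amplitude *
    expected_bg_envelope(pp$alpha, pp$scale, truth$evoked$frequency, fs, n)
  if (ev_amp > 0) x <- x + ev_amp * evoked_waveform(times, truth$evoked)

  if (truth$entrain_gain > 0) {
    phis <- stats::runif(ntr, -pi, pi)
    for (f in unique(freqs)) {
      a_ind <- truth$entrain_gain * expected_bg_envelope(pp$alpha, pp$scale, f, fs, n)
      carrier <- 2 * pi * f * times
      for (nb in unique(bursts[freqs == f])) {
        env <- stimulus_envelope_at(times, f, nb, truth$duty_cycle, onset = 0.03)
        aenv <- a_ind * env
        for (j in which(freqs == f & bursts == nb)) {
          x[, j] <- x[, j] + aenv * cos(carrier + phis[j])
        }
      }
    }
  }

  gm <- truth$gamma
  if (gm$amplitude > 0) {
    a_g <- gm$amplitude * expected_bg_envelope(pp$alpha, pp$scale, gm$frequency, fs, n)
    pre_gate <- tukey_gate(times, gm$window)
    post_gate <- tukey_gate(times, gm$post_window)
    mus <- ifelse(success, gm$preferred_phase, gm$preferred_phase + pi)
    pre_amp <- a_g * (1 - gm$amp_depth * (2 * success - 1))
    post_amp <- a_g * (1 + gm$amp_depth * (2 * success - 1))
    post_phi <- stats::runif(ntr, -pi, pi)
    for (j in seq_len(ntr)) {
      phi <- rvm(1, mus[j], gm$kappa)
      x[, j] <- x[, j] +
        pre_amp[j] * pre_gate * cos(2 * pi * gm$frequency * (times - gm$t_ref) + phi) +
        post_amp[j] * post_gate * cos(2 * pi * gm$frequency * times + post_phi[j])
    }
  }
  x
}

#' Synthesise one virtual-sensor epoch
#'
#' Generates a single trial of the synthetic auditory-cortex virtual
#' sensor: 1/f background + evoked transient + entrained oscillation at the
#' presentation frequency (gated by the burst envelope from +30 ms) + a
#' gamma-band component whose prestimulus phase is drawn conditionally on
#' the trial's planned success state. Reproducible: identical
#' `(trial, truth, seed)` give identical samples.
#'
#' @param trial One-row slice of an `osc_schedule` (fields `participant`,
#'   `frequency`, `n_bursts`, and `correct` for the planned success state).
#' @param truth An `osc_truth`.
#' @param seed Integer seed.
#' @param fs Sampling rate (Hz).
#' @return An `osc_epoch` list: `samples` (length 1,920), `times`
#'   (seconds, `[-0.8, 0.8)`), `fs`, `audio_offset`, and the trial row.
#' @export
synthesize_epoch <- function(trial, truth, seed, fs = 1200) {
  stopifnot(nrow(trial) == 1)
  pp <- participant_params(truth, trial$participant)
  times <- epoch_times(fs)
  x <- with_seed(seed, {
    synth_trials(trial$frequency, trial$n_bursts, as.numeric(isTRUE(trial$correct)),
                 pp, truth, fs, times)
  })
  structure(list(samples = as.vector(x), times = times, fs = fs,
                 audio_offset = 0.03, trial = trial, seed = seed),
            class = "osc_epoch")
}

#' Simulate behavioural responses from a spectral profile
#'
#' Fills `response` and `correct` into a trial schedule. The probability of
#' a correct count is a monotone function of the participant's normalised
#' amplitude at the trial's presentation frequency, floored at guessing:
#' `P(correct) = floor + (1 - floor) * clip(intercept + slope * a_norm, 0, 1)`.
#' Wrong responses are drawn uniformly from the remaining three options.
#' The trial-by-trial success state drawn here also conditions the
#' prestimulus gamma phase when epochs are synthesised, which is how
#' success is additionally coupled to the gamma-band state.
#'
#' @param schedule An `osc_schedule`.
#' @param profile Spectral profile at the 12 presentation frequencies:
#'   named numeric vector (single participant) or matrix with one row per
#'   participant and frequency-named columns.
#' @param truth An `osc_truth` (behaviour parameters).
#' @param seed Integer seed.
#' @return The schedule with `response` and `correct` filled.
#' @export
simulate_behaviour <- function(schedule, profile, truth, seed) {
  if (is.null(dim(profile))) {
    profile <- matrix(profile, nrow = 1, dimnames = list(NULL, names(profile)))
  }
  participants <- sort(unique(schedule$participant))
  stopifnot(nrow(profile) == length(participants))
  fcols <- as.numeric(colnames(profile))
  if (!all(sort(unique(schedule$frequency)) %in% fcols)) {
    stop("profile must cover every presentation frequency in the schedule",
         call. = FALSE)
  }
  beh <- truth$behaviour
  with_seed(seed, {
    for (i in seq_along(participants)) {
      p <- participants[i]
      rows <- which(schedule$participant == p)
      a <- normalize_profile(profile[i, ])
      a_tr <- a[match(schedule$frequency[rows], fcols)]
      pc <- beh$floor + (1 - beh$floor) *
        pmin(pmax(beh$intercept + beh$slope * a_tr, 0), 1)
      success <- stats::rbinom(length(rows), 1, pc) == 1
      resp <- schedule$n_bursts[rows]
      for (j in which(!success)) {
        resp[j] <- sample(setdiff(4:7, schedule$n_bursts[rows[j]]), 1)
      }
      schedule$response[rows] <- resp
      schedule$correct[rows] <- success
    }
  })
  schedule
}

#' Simulate a complete synthetic study
#'
#' Builds the trial schedule, draws per-participant background parameters,
#' computes each participant's expected spectral profile, simulates
#' behaviour coupled to that profile, marks rejected trials, and
#' synthesises every epoch. The defaults reproduce the study conditions
#' (20 participants, 4 blocks of 144 trials); smaller designs are obtained
#' through the design arguments.
#'
#' @param truth An `osc_truth` (default [ground_truth()]).
#' @param n_participants,n_blocks,base_reps,high_prev_reps Design
#'   parameters passed to [build_trial_schedule()].
#' @param seed Master seed; every stage of the simulation derives its own
#'   stream from it.
#' @param fs Sampling rate (Hz).
#' @return An `osc_study` list: `schedule`, `epochs` (one samples-by-trials
#'   matrix per participant, columns aligned with that participant's
#'   schedule rows), `times`, `fs`, `truth`, `participants` (parameter
#'   table), `profiles` (expected spectral profiles), `seed`.
#' @export
simulate_study <- function(truth = ground_truth(), n_participants = 20,
                           n_blocks = 4, base_reps = 8, high_prev_reps = 32,
                           seed = 1, fs = 1200) {
  schedule <- build_trial_schedule(n_participants, n_blocks, base_reps,
                                   high_prev_reps,
                                   seed = derive_seed(seed, "schedule"))
  times <- epoch_times(fs)
  pps <- lapply(seq_len(n_participants), participant_params, truth = truth)
  prof_base <- expected_profile_base(truth, fs = fs)
  prev_w <- ifelse(presentation_frequencies %in% high_prevalence_frequencies,
                   high_prev_reps, base_reps)
  profiles <- t(vapply(seq_len(n_participants), function(p)
    expected_profile(truth, p, weights = prev_w, fs = fs, base = prof_base),
    numeric(length(presentation_frequencies))))
  colnames(profiles) <- presentation_frequencies

  schedule <- simulate_behaviour(schedule, profiles, truth,
                                 seed = derive_seed(seed, "behaviour"))
  if (truth$reject_rate > 0) {
    with_seed(derive_seed(seed, "rejection"), {
      schedule$rejected <- stats::runif(nrow(schedule)) < truth$reject_rate
    })
  }

  epochs <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    rows <- which(schedule$participant == p)
    epochs[[p]] <- with_seed(derive_seed(seed, paste0("epochs", p)), {
      synth_trials(schedule$frequency[rows], schedule$n_bursts[rows],
                   as.numeric(schedule$correct[rows]), pps[[p]], truth, fs, times)
    })
  }

  participants <- data.frame(
    participant = seq_len(n_participants),
    alpha = vapply(pps, `[[`, numeric(1), "alpha"),
    scale = vapply(pps, `[[`, numeric(1), "scale")
  )
  structure(list(schedule = schedule, epochs = epochs, times = times,
                 fs = fs, truth = truth, participants = participants,
                 profiles = profiles, seed = seed),
            class = "osc_study")
}

#' @export
print.osc_study <- function(x, ...) {
  cat("Synthetic study:", nrow(x$participants), "participant(s),",
      nrow(x$schedule), "trials,", sum(x$schedule$rejected), "rejected\n")
  acc <- mean(x$schedule$correct[!x$schedule$rejected])
  cat(sprintf("  overall accuracy %.3f (chance 0.25); fs %g Hz, epoch %d samples\n",
              acc, x$fs, length(x$times)))
  invisible(x)
}
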
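#' Ground-truth parameters for the synthetic virtual sensor
#'
#' Collects every generative parameter of the synthetic auditory-cortex
#' virtual sensor, so that all injected effects are recorded alongside the
#' data they produce. Setting `entrain_gain = 0`, `behaviour$slope = 0`,
#' `gamma$amplitude = 0` (or `gamma$kappa = 0` and `gamma$amp_depth = 0`)
#' yields pure null data.
#'
#' Component amplitudes are expressed in units of the participant's
#' expected background band envelope at the component's frequency, so the
#' injected effects scale with the 1/f background and stay comparable
#' across participants and bands.
#'
#' @param alpha Spectral exponent of the 1/f background: mean Hilbert
#'   envelope scales as `frequency^-alpha` over 3--100 Hz (default 1).
#' @param background_scale Overall background amplitude (arbitrary source
#'   units, default 1).
#' @param participant_alpha_sd,participant_scale_sd Between-participant
#'   spread: normal sd on `alpha`, log-normal sd on the scale.
#' @param entrain_gain Multiplier `g` on the induced oscillation at the
#'   presentation frequency, gated by the burst envelope (default 1.5;
#'   0 disables entrainment).
#' @param duty_cycle Burst duty cycle used for stimulus envelopes.
#' @param evoked List: `amplitude` (relative), `frequency` (Hz), `onset`
#'   and `duration` (s) of the stimulus-onset evoked transient (identical
#'   phase on every trial).
#' @param gamma List describing the prestimulus gamma-band state coupled
#'   to trial success: `frequency` (Hz), `amplitude` (relative), `window`
#'   (s, prestimulus extent), `post_window` (s, poststimulus burst),
#'   `t_ref` (s, phase reference time), `preferred_phase` (rad),
#'   `kappa` (von Mises concentration of the success-conditional phase;
#'   failures centre on the opposite angle), `amp_depth` (relative
#'   desynchronisation on successful trials before the stimulus and
#'   synchronisation after it).
#' @param behaviour List: `floor` (guessing rate, 0.25 for 4 options),
#'   `slope`, `intercept` mapping the normalised amplitude profile to
#'   P(correct) = floor + (1 - floor) * clip(intercept + slope * a, 0, 1).
#' @param reject_rate Fraction of trials marked as rejected (visual
#'   artefact screening emulation; default 0.068).
#' @param seed Base seed from which per-participant parameters derive.
#' @return An `osc_truth` list.
#' @export
ground_truth <- function(alpha = 1, background_scale = 1,
                         participant_alpha_sd = 0.05,
                         participant_scale_sd = 0.1,
                         entrain_gain = 1.5, duty_cycle = 0.5,
                         evoked = list(amplitude = 1.5, frequency = 8,
                                       onset = 0.03, duration = 0.25),
                         gamma = list(frequency = 71.5, amplitude = 1,
                                      window = c(-0.65, 0),
                                      post_window = c(0.05, 0.45),
                                      t_ref = -0.45, preferred_phase = pi / 2,
                                      kappa = 1, amp_depth = 0.4),
                         behaviour = list(floor = 0.25, slope = 1,
                                          intercept = 0),
                         reject_rate = 0.068, seed = 1) {
  truth <- list(alpha = alpha, background_scale = background_scale,
                participant_alpha_sd = participant_alpha_sd,
                participant_scale_sd = participant_scale_sd,
                entrain_gain = entrain_gain, duty_cycle = duty_cycle,
                evoked = evoked, gamma = gamma, behaviour = behaviour,
                reject_rate = reject_rate, seed = seed)
  class(truth) <- "osc_truth"
  truth
}

#' Pure-null ground truth
#'
#' Convenience wrapper: no entrainment, no behaviour/amplitude coupling,
#' no gamma/success coupling; accuracy is uniform guessing at 0.25.
#' @param ... Overrides passed to [ground_truth()].
#' @export
null_truth <- function(...) {
  args <- list(...)
  base <- ground_truth(entrain_gain = 0,
                       behaviour = list(floor = 0.25, slope = 0, intercept = 0),
                       gamma = list(frequency = 71.5, amplitude = 0,
                                    window = c(-0.65, 0),
                                    post_window = c(0.05, 0.45),
                                    t_ref = -0.45, preferred_phase = pi / 2,
                                    kappa = 0, amp_depth = 0))
  utils::modifyList(base, args)
}

#' @export
print.osc_truth <- function(x, ...) {
  cat("Synthetic ground truth:\n")
  cat(sprintf("  background: 1/f^%g (scale %g), participant sd (%g, %g)\n",
              x$alpha, x$background_scale, x$participant_alpha_sd,
              x$participant_scale_sd))
  cat(sprintf("  entrainment gain g = %g, duty cycle %g\n",
              x$entrain_gain, x$duty_cycle))
  cat(sprintf("  evoked: %g x background at %g Hz\n",
              x$evoked$amplitude, x$evoked$frequency))
  cat(sprintf("  gamma coupling: %g Hz, kappa %g, amp depth %g, preferred %.2f rad\n",
              x$gamma$frequency, x$gamma$kappa, x$gamma$amp_depth,
              x$gamma$preferred_phase))
  cat(sprintf("  behaviour: P(correct) = %g + %g * clip(%g + %g a, 0, 1); reject rate %g\n",
              x$behaviour$floor, 1 - x$behaviour$floor, x$behaviour$intercept,
              x$behaviour$slope, x$reject_rate))
  invisible(x)
}

# Per-participant generative parameters, reproducible from truth$seed and
# the participant id alone.
participant_params <- function(truth, participant) {
  with_seed(derive_seed(truth$seed, paste0("participant", participant)), {
    alpha <- truth$alpha + stats::rnorm(1, 0, truth$participant_alpha_sd)
    scale <- truth$background_scale * exp(stats::rnorm(1, 0, truth$participant_scale_sd))
    list(participant = participant, alpha = alpha, scale = scale)
  })
}

# Amplitude gain of the background-shaping filter on the epoch FFT grid.
# Floor at 1 Hz keeps very-low-frequency power finite; DC removed.
background_gain <- function(alpha, scale, fs = 1200, n = 1920) {
  fgrid <- fs * (seq_len(n) - 1) / n
  f_phys <- pmin(fgrid, fs - fgrid)
  g <- scale * pmax(f_phys, 1)^(-alpha)
  g[1] <- 0
  g
}

# Expected Hilbert envelope of the background alone at one analysis band:
# sd of the band-filtered background times sqrt(pi/2) (Rayleigh mean).
expected_bg_envelope <- function(alpha, scale, centre, fs = 1200, n = 1920,
                                 bandwidth = 6, order = 3) {
  a <- background_gain(alpha, scale, fs, n)
  fgrid <- fs * (seq_len(n) - 1) / n
  f_phys <- pmin(fgrid, fs - fgrid)
  g <- band_response(f_phys, centre, bandwidth, order)
  sigma2 <- mean((a * g)^2)
  sqrt(sigma2) * sqrt(pi / 2)
}

# Mean of a Rice(nu, sigma) envelope: sigma*sqrt(pi/2)*L_{1/2}(-nu^2/(2 sigma^2)).
rice_mean <- function(nu, sigma) {
  t <- nu^2 / (2 * sigma^2)
  half <- t / 2
  l <- (1 + t) * besselI(half, 0, expon.scaled = TRUE) +
    t * besselI(half, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * l
}

# Unit-amplitude evoked transient waveform on the epoch time axis: a
# Hann-windowed sinusoid starting at stimulus onset.
evoked_waveform <- function(times, evoked) {
  rel <- times - evoked$onset
  w <- ifelse(rel >= 0 & rel < evoked$duration,
              0.5 * (1 - cos(2 * pi * rel / evoked$duration)), 0)
  w * sin(2 * pi * evoked$frequency * rel)
}

# Cosine-ramped gate over `window` (seconds) with `ramp` seconds edges.
tukey_gate <- function(times, window, ramp = 0.05) {
  len <- window[2] - window[1]
  rel <- (times - window[1])
  w <- numeric(length(times))
  inside <- rel >= 0 & rel <= len
  w[inside] <- 1
  up <- inside & rel < ramp
  w[up] <- 0.5 * (1 - cos(pi * rel[up] / ramp))
  down <- inside & rel > len - ramp
  w[down] <- 0.5 * (1 - cos(pi * (len - rel[down]) / ramp))
  w
}

# Band-filtered analytic modulus of a unit deterministic waveform at one
# band centre (vector over the epoch time axis).
det_band_modulus <- function(x, fs, centre, bandwidth = 6, order = 3) {
  z <- analytic_bank(matrix(x, ncol = 1), fs, centre, bandwidth, order)
  as.vector(Mod(z[1, 1, ]))
}

#' Expected measured amplitude profile of a participant
#'
#' Analytic expectation of the active-window (80--430 ms epoch time) mean
#' Hilbert envelope at each presentation frequency, for trials presented at
#' that frequency: the Rice mean combining the 1/f background with the
#' band-filtered evoked and induced deterministic moduli (induced phase is
#' random per trial, so components combine incoherently). This is the
#' spectral profile that behaviour is coupled to.
#'
#' @param truth An `osc_truth`.
#' @param participant Participant id (integer).
#' @param freqs Analysis bands = presentation frequencies (default the 12
#'   task rates).
#' @param weights Prevalence weight of each presentation frequency in the
#'   trial mix (default uniform); the measured spectrum pools all trials,
#'   so each band's expectation is a prevalence-weighted mixture over the
#'   presentation conditions (induced components of nearby presentation
#'   rates, and their burst-gating harmonics, leak into the band).
#' @param active_window Window in epoch seconds (default `c(0.08, 0.43)`).
#' @param fs,n Sampling rate and epoch length.
#' @param base Optional precomputed [expected_profile_base()]; the base
#'   moduli are participant-independent, so callers simulating many
#'   participants compute them once.
#' @return Named numeric vector of expected mean envelopes.
#' @export
expected_profile <- function(truth, participant,
                             freqs = presentation_frequencies,
                             weights = NULL,
                             active_window = c(0.08, 0.43),
                             fs = 1200, n = 1920, base = NULL) {
  pp <- participant_params(truth, participant)
  if (is.null(base)) {
    base <- expected_profile_base(truth, freqs, active_window, fs, n)
  }
  if (is.null(weights)) weights <- rep(1, length(freqs))
  weights <- weights / sum(weights)
  a_ev <- truth$evoked$amplitude *
    expected_bg_envelope(pp$alpha, pp$scale, truth$evoked$frequency, fs, n)
  e_bg <- vapply(freqs, function(f)
    expected_bg_envelope(pp$alpha, pp$scale, f, fs, n), numeric(1))
  a_ind <- truth$entrain_gain * e_bg  # induced amplitude when presented at f
  out <- numeric(length(freqs))
  for (b in seq_along(freqs)) {
    sigma <- e_bg[b] / sqrt(pi / 2)
    ev2 <- (a_ev * base$ev_mod[[b]])^2
    acc <- 0
    for (f in seq_along(freqs)) {
      nu <- sqrt(ev2 + a_ind[f]^2 * base$ind_mod2[[b]][[f]])
      acc <- acc + weights[f] * mean(rice_mean(nu, sigma))
    }
    out[b] <- acc
  }
  names(out) <- freqs
  out
}

# Participant-independent band moduli of the unit-amplitude deterministic
# components inside the active window: the evoked waveform at every band,
# and the burst-gated induced oscillation of every presentation frequency
# filtered through every band (mean squared modulus over 4-7 bursts), so
# cross-band leakage and gating harmonics are accounted for.
expected_profile_base <- function(truth, freqs = presentation_frequencies,
                                  active_window = c(0.08, 0.43),
                                  fs = 1200, n = 1920) {
  times <- epoch_times(fs)
  idx <- window_index(times, active_window)
  nf <- length(freqs)
  waves <- matrix(0, n, 1 + 4 * nf)
  waves[, 1] <- evoked_waveform(times, truth$evoked)
  if (truth$entrain_gain > 0) {
    k <- 1L
    for (f in freqs) {
      for (nb in 4:7) {
        k <- k + 1L
        env <- stimulus_envelope_at(times, f, nb, truth$duty_cycle, onset = 0.03)
        waves[, k] <- env * cos(2 * pi * f * times)
      }
    }
  }
  z <- analytic_bank(waves, fs, freqs)            # [wave, band, time]
  ev_mod <- lapply(seq_len(nf), function(b) Mod(z[1, b, idx]))
  ind_mod2 <- lapply(seq_len(nf), function(b) {
    lapply(seq_len(nf), function(f) {
      if (truth$entrain_gain <= 0) return(0)
      cols <- 1L + (f - 1L) * 4L + 1:4
      m2 <- Mod(z[cols, b, idx])^2
      colMeans(matrix(m2, 4, length(idx)))
    })
  })
  list(ev_mod = ev_mod, ind_mod2 = ind_mod2, freqs = freqs,
       active_window = active_window)
}
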
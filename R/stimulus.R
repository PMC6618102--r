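#' Synthesise a burst-train stimulus envelope
#'
#' Builds the rectangular on/off envelope of a white-noise burst train.
#' Burst k (0-based) starts at `k / frequency` seconds and lasts
#' `duty_cycle / frequency` seconds; the train ends at
#' `(n_bursts - 1 + duty_cycle) / frequency`.
#'
#' @param frequency Presentation rate in Hz (> 0).
#' @param n_bursts Number of bursts, 4--7.
#' @param duty_cycle Fraction of each cycle occupied by noise (0, 1].
#' @param sampling_rate Samples per second for the envelope series.
#' @return An `osc_stimulus` list with `envelope` (0/1 series sampled from
#'   t = 0), `times` (seconds), `onsets` (burst onset times, seconds),
#'   `wavelength`, `duration`, and the call parameters.
#' @examples
#' tr <- synthesize_stimulus_train(6, 5, 0.5, 1200)
#' tr$onsets * 1000  # ms: 0, 166.7, 333.3, 500, 666.7
#' @export
synthesize_stimulus_train <- function(frequency, n_bursts, duty_cycle = 0.5,
                                      sampling_rate = 1200) {
  stopifnot(frequency > 0, n_bursts >= 4, n_bursts <= 7,
            duty_cycle > 0, duty_cycle <= 1, sampling_rate > 0)
  lambda <- 1 / frequency
  onsets <- (seq_len(n_bursts) - 1) * lambda
  duration <- (n_bursts - 1 + duty_cycle) * lambda
  n <- ceiling(duration * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  phase <- (t %% lambda) / lambda
  envelope <- as.numeric(phase < duty_cycle & t < duration)
  structure(list(envelope = envelope, times = t, onsets = onsets,
                 wavelength = lambda, duration = duration,
                 frequency = frequency, n_bursts = n_bursts,
                 duty_cycle = duty_cycle, sampling_rate = sampling_rate),
            class = "osc_stimulus")
}

#' @export
print.osc_stimulus <- function(x, ...) {
  cat(sprintf("Burst train: %g Hz, %d bursts, duty %.2f, %.1f ms total\n",
              x$frequency, x$n_bursts, x$duty_cycle, 1000 * x$duration))
  invisible(x)
}

# Envelope of the train evaluated on an arbitrary time axis (seconds),
# with the train starting at `onset` (default +30 ms audio offset).
stimulus_envelope_at <- function(times, frequency, n_bursts, duty_cycle = 0.5,
                                 onset = 0.03) {
  lambda <- 1 / frequency
  rel <- times - onset
  duration <- (n_bursts - 1 + duty_cycle) * lambda
  phase <- (rel %% lambda) / lambda
  as.numeric(rel >= 0 & rel < duration & phase < duty_cycle)
}
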
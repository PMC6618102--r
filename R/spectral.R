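#' Epoch time axis
#'
#' Half-open epoch window `[-800, 800)` ms sampled at 1,200 Hz: 1,920
#' samples, no duplicated boundary sample.
#'
#' @param fs Sampling rate (Hz).
#' @param start,end Epoch limits in seconds (end exclusive).
#' @return Numeric vector of sample times in seconds.
#' @export
epoch_times <- function(fs = 1200, start = -0.8, end = 0.8) {
  n <- round((end - start) * fs)
  start + (seq_len(n) - 1) / fs
}

# Band edges for a filter-bank centre: centre +/- bandwidth/2, with the
# lower edge clipped at 0.5 Hz so the 3 Hz band keeps a valid high-pass edge.
band_edges <- function(centre, bandwidth = 6, min_edge = 0.5) {
  lo <- max(centre - bandwidth / 2, min_edge)
  hi <- centre + bandwidth / 2
  if (hi <= lo) stop("empty passband for centre ", centre, call. = FALSE)
  c(lo, hi)
}

# Squared-magnitude response (zero phase) of one pass of an order-n analog
# Butterworth band-pass prototype, evaluated at frequencies f (Hz).
# Forward-backward application corresponds to squaring this response.
butter_bp_mag2 <- function(f, lo, hi, order = 3) {
  w02 <- lo * hi
  bw <- hi - lo
  x <- ifelse(f > 0, (f^2 - w02) / (bw * f), Inf)
  1 / (1 + x^(2 * order))
}

# Bidirectional (zero-phase) amplitude response used throughout: |H|^2.
band_response <- function(f, centre, bandwidth = 6, order = 3) {
  e <- band_edges(centre, bandwidth)
  butter_bp_mag2(f, e[1], e[2], order)
}

# Mirror-pad a samples x trials matrix by `pad` samples at each end.
mirror_pad <- function(x, pad) {
  n <- nrow(x)
  if (pad <= 0) return(x)
  if (pad >= n) stop("padding longer than series", call. = FALSE)
  rbind(x[pad:1, , drop = FALSE], x, x[n:(n - pad + 1), , drop = FALSE])
}

# Core engine: analytic signal per band for a samples x trials matrix.
# Applies the zero-phase Butterworth band response in the frequency domain
# (mirror padding against edge distortion) and the analytic-signal weights
# in a single pass; returns a complex array [trial, band, time].
#
# When the decimation factor divides both the padded length and the pad,
# the decimated analytic signal is computed directly on the decimated FFT
# grid by folding the (narrow) band spectrum, which avoids a full-length
# inverse FFT per band. Spectrum bins with a band response below ~1e-7
# are dropped; the truncation error is far below the band's own stopband
# leakage.
analytic_bank <- function(x, fs, centres, bandwidth = 6, order = 3,
                          pad = round(0.1 * fs), decim = 1L) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  decim <- as.integer(decim)
  n <- nrow(x); ntr <- ncol(x)
  xp <- mirror_pad(x, pad)
  np <- nrow(xp)
  X <- stats::mvfft(xp)
  fgrid <- fs * (seq_len(np) - 1) / np
  nyq_bin <- floor(np / 2) + 1
  w <- numeric(np)
  w[1] <- 1
  w[2:(nyq_bin - 1)] <- 2
  if (np %% 2 == 0) w[nyq_bin] <- 1 else w[nyq_bin] <- 2
  keep <- seq(1L, n, by = decim)
  fast <- decim > 1L && np %% decim == 0L && pad %% decim == 0L
  np2 <- np %/% decim
  out <- array(0 + 0i, dim = c(ntr, length(centres), length(keep)))
  for (j in seq_along(centres)) {
    g <- numeric(np)
    g[1:nyq_bin] <- band_response(fgrid[1:nyq_bin], centres[j], bandwidth, order)
    m <- w * g
    kk <- which(m > 1e-7)
    if (fast) {
      tgt <- ((kk - 1L) %% np2) + 1L
      folded <- matrix(0 + 0i, np2, ntr)
      Y <- X[kk, , drop = FALSE] * m[kk]
      if (anyDuplicated(tgt)) {
        re <- rowsum(Re(Y), tgt)
        im <- rowsum(Im(Y), tgt)
        folded[as.integer(rownames(re)), ] <- re + 1i * im
      } else {
        folded[tgt, ] <- Y
      }
      z <- stats::mvfft(folded, inverse = TRUE) / np
      rows <- pad %/% decim + seq_along(keep)
      out[, j, ] <- t(z[rows, , drop = FALSE])
    } else {
      mk <- numeric(np)
      mk[kk] <- m[kk]
      z <- stats::mvfft(X * mk, inverse = TRUE) / np
      z <- z[(pad + 1):(pad + n), , drop = FALSE][keep, , drop = FALSE]
      out[, j, ] <- t(z)
    }
  }
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Band-pass filters a series (or samples-by-trials matrix) with zero phase
#' distortion. The default `"fft"` method applies the squared magnitude
#' response of an order-`order` analog Butterworth band-pass prototype
#' (the steady-state response of forward-backward filtering) in the
#' frequency domain with mirror padding; `"filtfilt"` designs a digital
#' Butterworth filter and applies [signal::filtfilt()]. The passband is
#' `centre_frequency +/- bandwidth/2` with the lower edge clipped at 0.5 Hz.
#'
#' @param x Numeric vector or samples-by-trials matrix.
#' @param fs Sampling rate in Hz.
#' @param centre_frequency Band centre (Hz).
#' @param bandwidth Full passband width (Hz, default 6).
#' @param order Butterworth order per direction (default 3; the
#'   bidirectional magnitude response is effectively 6th order).
#' @param method `"fft"` (default) or `"filtfilt"`.
#' @param pad Mirror-padding length in samples (default 100 ms).
#' @return Filtered series with the same shape as `x`.
#' @export
bandpass <- function(x, fs, centre_frequency, bandwidth = 6, order = 3,
                     method = c("fft", "filtfilt"), pad = round(0.1 * fs)) {
  method <- match.arg(method)
  e <- band_edges(centre_frequency, bandwidth)
  if (e[1] >= fs / 2) stop("empty passband: lower edge at or above Nyquist", call. = FALSE)
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  if (method == "fft") {
    n <- nrow(xm)
    xp <- mirror_pad(xm, pad)
    np <- nrow(xp)
    X <- stats::mvfft(xp)
    fgrid <- fs * (seq_len(np) - 1) / np
    f_phys <- pmin(fgrid, fs - fgrid)  # fold negative-frequency bins
    g <- butter_bp_mag2(f_phys, e[1], e[2], order)
    y <- Re(stats::mvfft(X * g, inverse = TRUE) / np)
    y <- y[(pad + 1):(pad + n), , drop = FALSE]
  } else {
    bf <- signal::butter(order, e / (fs / 2), type = "pass")
    y <- apply(mirror_pad(xm, pad), 2, function(col) signal::filtfilt(bf, col))
    y <- y[(pad + 1):(pad + nrow(xm)), , drop = FALSE]
  }
  if (vec) drop(y) else y
}

#' Hilbert filter-bank time-frequency decomposition
#'
#' Estimates oscillatory amplitude and phase per trial, frequency band and
#' time point: each band is band-passed with a zero-phase Butterworth
#' response (default 3--100 Hz centres, 1 Hz step, 6 Hz bandwidth) and the
#' analytic signal taken, so `amplitude * cos(phase)` reconstructs the
#' band-passed series exactly.
#'
#' @param x Samples-by-trials numeric matrix (or a vector for one trial).
#' @param fs Sampling rate in Hz.
#' @param times Time axis in seconds (defaults to [epoch_times()] when the
#'   trial length matches, otherwise starts at 0).
#' @param freqs Band centres in Hz (default `3:100`, 98 bands).
#' @param bandwidth Band width in Hz (default 6, i.e. centre +/- 3 Hz).
#' @param order Butterworth order per direction (default 3).
#' @param decim Integer time-decimation factor applied to the analytic
#'   signal (default 1 = full rate). Decimation subsamples; amplitude and
#'   phase at the retained instants are unchanged.
#' @return An `osc_tf` list: `amplitude` and `phase` arrays
#'   `[trial, frequency, time]`, `freqs`, `times` (decimated), `fs`,
#'   `bandwidth`, `order`, `decim`, `baselined`.
#' @export
hilbert_tf <- function(x, fs = 1200, times = NULL, freqs = 3:100,
                       bandwidth = 6, order = 3, decim = 1L) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (is.null(times)) {
    times <- if (nrow(x) == round(1.6 * fs)) epoch_times(fs) else (seq_len(nrow(x)) - 1) / fs
  }
  stopifnot(length(times) == nrow(x))
  z <- analytic_bank(x, fs, freqs, bandwidth, order, decim = decim)
  keep <- seq(1L, nrow(x), by = as.integer(decim))
  structure(list(amplitude = Mod(z), phase = Arg(z), freqs = freqs,
                 times = times[keep], fs = fs / decim, bandwidth = bandwidth,
                 order = order, decim = as.integer(decim), baselined = FALSE),
            class = "osc_tf")
}

#' @export
print.osc_tf <- function(x, ...) {
  d <- dim(x$amplitude)
  cat(sprintf("Time-frequency decomposition: %d trial(s) x %d band(s) x %d time point(s)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  bands %g-%g Hz (bw %g), time %.0f..%.0f ms at %g Hz%s\n",
              min(x$freqs), max(x$freqs), x$bandwidth, 1000 * min(x$times),
              1000 * max(x$times), x$fs,
              if (isTRUE(x$baselined)) ", baselined" else ""))
  invisible(x)
}

# Index of time points inside a half-open window [w1, w2) given in seconds.
window_index <- function(times, window) {
  idx <- which(times >= window[1] - 1e-9 & times < window[2] - 1e-9)
  if (!length(idx)) stop("window outside epoch", call. = FALSE)
  idx
}

#' Subtract a prestimulus baseline from a decomposition
#'
#' Per trial and frequency band, subtracts the mean amplitude over the
#' baseline window (subtractive baseline). The default window is the final
#' 350 ms before stimulus onset, shifted with the +30 ms audio offset:
#' `[-320, +30)` ms in epoch time.
#'
#' @param tf An `osc_tf` object.
#' @param baseline_window Two-element window in seconds.
#' @return The decomposition with baselined amplitude (`baselined = TRUE`).
#' @export
apply_baseline <- function(tf, baseline_window = c(-0.32, 0.03)) {
  stopifnot(inherits(tf, "osc_tf"))
  idx <- window_index(tf$times, baseline_window)
  d <- dim(tf$amplitude)
  base <- rowMeans(matrix(tf$amplitude[, , idx, drop = FALSE],
                          d[1] * d[2], length(idx)))
  tf$amplitude <- tf$amplitude - base  # recycles over time (3rd dim)
  tf$baselined <- TRUE
  tf$baseline_window <- baseline_window
  tf
}

#' Mean amplitude over a time window at one band
#'
#' @param tf An `osc_tf` object.
#' @param window Two-element half-open window in seconds.
#' @param frequency Band centre in Hz; matched to the nearest centre of the
#'   decomposition's grid.
#' @return One mean amplitude per trial.
#' @export
window_mean_amplitude <- function(tf, window, frequency) {
  stopifnot(inherits(tf, "osc_tf"))
  fi <- which.min(abs(tf$freqs - frequency))
  idx <- window_index(tf$times, window)
  a <- tf$amplitude[, fi, idx, drop = FALSE]
  apply(a, 1, mean)
}

#' Entrainment analysis windows for one presentation frequency
#'
#' Active window: from the (offset) stimulus onset until 200 ms after the
#' end of the final burst of a seven-burst train, limited to no more than
#' 800 ms of data; the equal-duration baseline ends 50 ms before onset.
#' When the nominal duration cannot fit inside the `[-800, 800)` ms epoch
#' (slow trains), the common duration is further capped so both windows
#' stay in-epoch and remain equal in length.
#'
#' @param presentation_frequency Hz, one of the 12 task rates (other values
#'   are accepted and handled identically).
#' @param duty_cycle Burst duty cycle (default 0.5).
#' @param onset Stimulus onset in epoch time (seconds; +30 ms audio offset).
#' @param epoch Epoch limits in seconds.
#' @param max_duration Cap on window duration in seconds (default 0.8).
#' @param gap Gap between baseline end and onset (seconds, default 0.05).
#' @return List with `active` and `baseline` windows (seconds, half-open),
#'   `duration` (applied) and `nominal_duration`.
#' @examples
#' w <- entrainment_windows(28)   # ~432.1 ms active window
#' diff(w$active) * 1000
#' @export
entrainment_windows <- function(presentation_frequency, duty_cycle = 0.5,
                                onset = 0.03, epoch = c(-0.8, 0.8),
                                max_duration = 0.8, gap = 0.05) {
  stopifnot(presentation_frequency > 0)
  lambda <- 1 / presentation_frequency
  nominal <- (6 + duty_cycle) * lambda + 0.2
  dur <- min(nominal, max_duration,
             epoch[2] - onset,              # active must end inside the epoch
             onset - gap - epoch[1])        # baseline must start inside it
  list(active = c(onset, onset + dur),
       baseline = c(onset - gap - dur, onset - gap),
       duration = dur, nominal_duration = nominal)
}
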
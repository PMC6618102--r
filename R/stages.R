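#' Min-max normalisation of a profile
#'
#' Subtracts the minimum and divides by the range, mapping the minimum to 0
#' and the maximum to 1 (affine in between, and invariant to any affine
#' transform of the input).
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return Normalised values spanning exactly [0, 1].
#' @export
normalize_profile <- function(values) {
  rng <- range(values)
  if (diff(rng) == 0) stop("zero range: cannot normalise", call. = FALSE)
  (values - rng[1]) / diff(rng)
}

# Trials of one participant that enter the analyses (not rejected).
usable_rows <- function(schedule, p) {
  which(schedule$participant == p & !schedule$rejected)
}

# Per-trial window summaries at the 12 presentation bands for one
# participant: raw active-window mean (correlation stage) and the
# baselined entrainment-window mean (entrainment stage), at every band.
trial_band_summaries <- function(x, fs, times, duty_cycle = 0.5,
                                 bands = presentation_frequencies,
                                 active_window = c(0.08, 0.43), decim = 4L,
                                 what = c("both", "raw", "induced")) {
  what <- match.arg(what)
  tf <- hilbert_tf(x, fs, times, freqs = bands, decim = decim)
  ntr <- dim(tf$amplitude)[1]
  wmean <- function(j, window) {
    idx <- window_index(tf$times, window)
    rowMeans(matrix(tf$amplitude[, j, idx], ntr, length(idx)))
  }
  raw <- induced <- NULL
  if (what != "induced") {
    raw <- sapply(seq_along(bands), wmean, window = active_window)
    colnames(raw) <- bands
  }
  if (what != "raw") {
    induced <- sapply(seq_along(bands), function(j) {
      w <- entrainment_windows(bands[j], duty_cycle)
      wmean(j, w$active) - wmean(j, w$baseline)
    })
    colnames(induced) <- bands
  }
  list(raw = raw, induced = induced, bands = bands)
}

#' Correlation stage: amplitude spectra vs counting performance
#'
#' Builds, per participant, the spectral profile (mean raw Hilbert-envelope
#' amplitude over the 50--400 ms active period, +30 ms audio offset, at the
#' band matching each presentation frequency, pooled over all usable trials
#' -- the prevalence of oscillatory activity, so no prestimulus baseline is
#' applied and no trial selection is made) and the behavioural profile
#' (proportion correct per frequency), min-max normalises both per
#' participant, and regresses normalised accuracy on normalised amplitude
#' with participants partialled out ([within_subject_ancova()]), attaching
#' JZS Bayes factors for the slope and the intercept.
#'
#' @param study An `osc_study`.
#' @param active_window Active window in epoch seconds (default
#'   `c(0.08, 0.43)`, i.e. 50--400 ms after the offset stimulus onset).
#' @param decim Time-decimation factor for the filter bank (default 8).
#' @param summaries Optional precomputed per-participant band summaries
#'   (the `decompose` pipeline product); when supplied the filter bank is
#'   not rerun.
#' @return An `osc_correlation` list: `ancova`, `profiles` (long data
#'   frame), `settings`.
#' @export
run_correlation_stage <- function(study, active_window = c(0.08, 0.43),
                                  decim = 8L, summaries = NULL) {
  stopifnot(inherits(study, "osc_study"))
  sched <- study$schedule
  if (all(is.na(sched$response))) {
    stop("behavioural responses missing: simulate or supply behaviour first",
         call. = FALSE)
  }
  participants <- sort(unique(sched$participant))
  prof <- list()
  for (p in participants) {
    rows <- usable_rows(sched, p)
    sub <- sched[rows, ]
    sm <- if (!is.null(summaries)) summaries[[as.character(p)]] else
      trial_band_summaries(study$epochs[[p]][, match(rows, which(sched$participant == p)), drop = FALSE],
                           study$fs, study$times, study$truth$duty_cycle,
                           active_window = active_window, decim = decim,
                           what = "raw")
    stopifnot(nrow(sm$raw) == length(rows))
    amp <- acc <- numeric(length(presentation_frequencies))
    for (j in seq_along(presentation_frequencies)) {
      f <- presentation_frequencies[j]
      tr <- which(sub$frequency == f)
      if (!length(tr)) {
        stop("participant ", p, " has no usable trials at ", f, " Hz", call. = FALSE)
      }
      amp[j] <- mean(sm$raw[, j])   # amplitude spectrum pools all trials
      acc[j] <- mean(sub$correct[tr])
    }
    prof[[length(prof) + 1L]] <- data.frame(
      participant = p, frequency = presentation_frequencies,
      amplitude = amp, accuracy = acc,
      amplitude_norm = normalize_profile(amp),
      accuracy_norm = normalize_profile(acc))
  }
  profiles <- do.call(rbind, prof)
  anc <- within_subject_ancova(profiles$amplitude_norm, profiles$accuracy_norm,
                               profiles$participant)
  structure(list(ancova = anc, profiles = profiles,
                 settings = list(active_window = active_window, decim = decim)),
            class = "osc_correlation")
}

#' @export
print.osc_correlation <- function(x, ...) {
  cat("Correlation stage: normalised accuracy ~ normalised amplitude spectra\n")
  print(x$ancova)
  invisible(x)
}

#' @export
plot.osc_correlation <- function(x, ...) {
  pr <- x$profiles
  fr <- sort(unique(pr$frequency))
  ma <- tapply(pr$amplitude_norm, pr$frequency, mean)
  mb <- tapply(pr$accuracy_norm, pr$frequency, mean)
  graphics::plot(fr, ma, type = "b", log = "x", ylim = c(0, 1), pch = 16,
                 xlab = "frequency (Hz)", ylab = "normalised value", ...)
  graphics::lines(fr, mb, type = "b", pch = 1, lty = 2)
  graphics::legend("topright", c("amplitude", "accuracy"), pch = c(16, 1),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Entrainment stage: matched vs unmatched induced amplitude
#'
#' For every participant and presentation frequency f, the matched value is
#' the mean baselined induced amplitude at band f over the
#' frequency-specific active window ([entrainment_windows()]) across the
#' trials presented at f; the unmatched value is the same measurement on a
#' random equal-size subsample of trials drawn from the other eleven
#' presentation frequencies. Chauvenet's criterion (0.5) is applied to
#' participants' mean matched-unmatched differences; survivors enter a
#' 2 (matched/unmatched) x 12 (frequency) repeated-measures ANOVA with a
#' JZS Bayes factor for the main effect.
#'
#' @param study An `osc_study`.
#' @param seed Integer seed for the unmatched down-sampling (defaults to a
#'   seed derived from the study's master seed).
#' @param decim Time-decimation factor for the filter bank (default 4).
#' @param summaries Optional precomputed per-participant band summaries
#'   (the `decompose` pipeline product).
#' @return An `osc_entrainment` list: `table` (long participant x
#'   condition x frequency amplitudes with trial counts), `anova`,
#'   `excluded` (participants removed by Chauvenet), `seed`.
#' @export
run_entrainment_stage <- function(study, seed = NULL, decim = 4L,
                                  summaries = NULL) {
  stopifnot(inherits(study, "osc_study"))
  if (is.null(seed)) seed <- derive_seed(study$seed, "entrainment")
  sched <- study$schedule
  participants <- sort(unique(sched$participant))
  rows_out <- list()
  with_seed(seed, {
    for (p in participants) {
      rows <- usable_rows(sched, p)
      sub <- sched[rows, ]
      sm <- if (!is.null(summaries)) summaries[[as.character(p)]] else
        trial_band_summaries(study$epochs[[p]][, match(rows, which(sched$participant == p)), drop = FALSE],
                             study$fs, study$times, study$truth$duty_cycle,
                             decim = decim, what = "induced")
      stopifnot(nrow(sm$induced) == length(rows))
      for (j in seq_along(presentation_frequencies)) {
        f <- presentation_frequencies[j]
        tr_m <- which(sub$frequency == f)
        tr_o <- which(sub$frequency != f)
        if (!length(tr_m) || length(tr_o) < length(tr_m)) {
          stop(sprintf("insufficient trials to equalise cell (participant %d, %g Hz)", p, f),
               call. = FALSE)
        }
        tr_u <- sample(tr_o, length(tr_m))
        rows_out[[length(rows_out) + 1L]] <- data.frame(
          participant = p, frequency = f, n_trials = length(tr_m),
          matched = mean(sm$induced[tr_m, j]),
          unmatched = mean(sm$induced[tr_u, j]))
      }
    }
  })
  tab <- do.call(rbind, rows_out)
  diffs <- tapply(tab$matched - tab$unmatched, tab$participant, mean)
  keep_mask <- if (length(diffs) >= 3) chauvenet(as.vector(diffs)) else
    rep(TRUE, length(diffs))
  excluded <- as.numeric(names(diffs))[!keep_mask]
  kept <- tab[!(tab$participant %in% excluded), ]
  long <- rbind(
    data.frame(participant = kept$participant, condition = "matched",
               frequency = kept$frequency, amplitude = kept$matched),
    data.frame(participant = kept$participant, condition = "unmatched",
               frequency = kept$frequency, amplitude = kept$unmatched))
  anova <- rm_anova_2x12(long)
  structure(list(table = tab, anova = anova, excluded = excluded,
                 participant_differences = diffs, seed = seed),
            class = "osc_entrainment")
}

#' @export
print.osc_entrainment <- function(x, ...) {
  a <- x$anova
  cat("Entrainment stage: matched vs unmatched induced amplitude\n")
  cat(sprintf("  main effect F(%d,%d) = %.2f, p = %.3g, BF10 = %.3g (mean diff %.4g)\n",
              a$df_main[1], a$df_main[2], a$f_main, a$p_main, a$bf_main$bf10,
              a$mean_difference))
  cat(sprintf("  interaction F(%d,%d) = %.2f, p = %.3g\n",
              a$df_interaction[1], a$df_interaction[2], a$f_interaction,
              a$p_interaction))
  if (length(x$excluded)) {
    cat("  participants excluded by Chauvenet:",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.osc_entrainment <- function(x, ...) {
  m <- tapply(x$table$matched, x$table$participant, mean)
  u <- tapply(x$table$unmatched, x$table$participant, mean)
  graphics::barplot(c(matched = mean(m), unmatched = mean(u)),
                    ylab = "induced amplitude", ...)
  graphics::points(rep(0.7, length(m)), m, pch = 1)
  graphics::points(rep(1.9, length(u)), u, pch = 1)
  invisible(x)
}

#' Success-contrast stage: successful vs unsuccessful counting
#'
#' Derives, per participant, equal-size successful and unsuccessful trial
#' sets from the high-prevalence (10 and 14 Hz, pooled) trials by one
#' random down-sampling, then runs four mass-cluster-permutation analyses
#' on the full 3--100 Hz x [-800, 800) ms grid: oscillatory amplitude with
#' and without the prestimulus baseline (paired t with per-bin Chauvenet),
#' the across-trial phase-locking-value difference (paired t), and the
#' circular mean phase angle (Watson's U-squared on participant means,
#' within-participant label swaps). Rayleigh maps (across participant mean
#' angles) are returned per condition. Participants without unsuccessful
#' trials are dropped with a warning.
#'
#' @param study An `osc_study`.
#' @param seed Seed for down-sampling and permutations (defaults to a seed
#'   derived from the study's master seed).
#' @param n_permutations Cluster permutations (default 5000).
#' @param decim Filter-bank time decimation (default 12, i.e. the envelope
#'   sampled at 100 Hz).
#' @param alpha_inclusion Per-bin inclusion threshold (default 0.05).
#' @param connectivity Cluster connectivity (default 8).
#' @param freqs Analysis band centres (default `3:100`).
#' @return An `osc_success` list: `clusters` (amplitude_raw,
#'   amplitude_baselined, plv_difference, phase_angle), `rayleigh`
#'   (z and p maps per condition), `counts` (per-participant equal-n trial
#'   counts), `excluded`, `freqs`, `times`, `settings`.
#' @export
run_success_contrast_stage <- function(study, seed = NULL,
                                       n_permutations = 5000, decim = 12L,
                                       alpha_inclusion = 0.05,
                                       connectivity = 8, freqs = 3:100) {
  stopifnot(inherits(study, "osc_study"))
  if (is.null(seed)) seed <- derive_seed(study$seed, "success")
  sched <- study$schedule
  participants <- sort(unique(sched$participant))
  sel <- list(); counts <- list(); excluded <- integer()
  with_seed(seed, {
    for (p in participants) {
      rows <- usable_rows(sched, p)
      sub <- sched[rows, ]
      hp <- which(sub$frequency %in% high_prevalence_frequencies)
      succ <- hp[sub$correct[hp]]
      fail <- hp[!sub$correct[hp]]
      if (!length(succ) || !length(fail)) {
        warning("participant ", p,
                " has no high-prevalence trials in one outcome; excluded from the success contrast",
                call. = FALSE)
        excluded <- c(excluded, p)
        next
      }
      n_eq <- min(length(succ), length(fail))
      sel[[as.character(p)]] <- list(
        success = sample(succ, n_eq), failure = sample(fail, n_eq),
        rows = rows)
      counts[[as.character(p)]] <- n_eq
    }
  })
  keep_p <- as.integer(names(sel))
  if (length(keep_p) < 2) stop("too few participants with both outcomes", call. = FALSE)

  first <- TRUE
  for (i in seq_along(keep_p)) {
    p <- keep_p[i]
    s <- sel[[as.character(p)]]
    prow <- which(sched$participant == p)
    cols <- match(s$rows, prow)
    tf <- hilbert_tf(study$epochs[[p]][, cols, drop = FALSE], study$fs,
                     study$times, freqs = freqs, decim = decim)
    if (first) {
      nf <- length(freqs); ntm <- length(tf$times)
      np <- length(keep_p)
      amp_s <- amp_f <- ampb_s <- ampb_f <- array(NA_real_, c(np, nf, ntm))
      plv_s <- plv_f <- ang_s <- ang_f <- array(NA_real_, c(np, nf, ntm))
      tf_times <- tf$times
      first <- FALSE
    }
    tfb <- apply_baseline(tf)
    cmean <- function(arr, idx) {
      matrix(colMeans(matrix(arr[idx, , , drop = FALSE],
                             length(idx), nf * ntm)), nf, ntm)
    }
    for (cond in c("success", "failure")) {
      idx <- s[[cond]]
      a_mean <- cmean(tf$amplitude, idx)
      ab_mean <- cmean(tfb$amplitude, idx)
      ph <- tf$phase[idx, , , drop = FALSE]
      cs <- matrix(colMeans(matrix(cos(ph), length(idx), nf * ntm)), nf, ntm)
      sn <- matrix(colMeans(matrix(sin(ph), length(idx), nf * ntm)), nf, ntm)
      pl <- sqrt(cs^2 + sn^2)
      an <- atan2(sn, cs)
      if (cond == "success") {
        amp_s[i, , ] <- a_mean; ampb_s[i, , ] <- ab_mean
        plv_s[i, , ] <- pl; ang_s[i, , ] <- an
      } else {
        amp_f[i, , ] <- a_mean; ampb_f[i, , ] <- ab_mean
        plv_f[i, , ] <- pl; ang_f[i, , ] <- an
      }
    }
  }

  cl <- list(
    amplitude_raw = cluster_permutation(amp_s, amp_f, "paired_t",
                                        n_permutations, alpha_inclusion,
                                        connectivity,
                                        seed = derive_seed(seed, "amp_raw"),
                                        freqs = freqs, times = tf_times),
    amplitude_baselined = cluster_permutation(ampb_s, ampb_f, "paired_t",
                                              n_permutations, alpha_inclusion,
                                              connectivity,
                                              seed = derive_seed(seed, "amp_base"),
                                              freqs = freqs, times = tf_times),
    plv_difference = cluster_permutation(plv_s, plv_f, "plv_diff_t",
                                         n_permutations, alpha_inclusion,
                                         connectivity,
                                         seed = derive_seed(seed, "plv"),
                                         freqs = freqs, times = tf_times),
    phase_angle = cluster_permutation(ang_s, ang_f, "watson_u2",
                                      n_permutations, alpha_inclusion,
                                      connectivity,
                                      seed = derive_seed(seed, "phase"),
                                      freqs = freqs, times = tf_times))

  rayleigh_maps <- function(ang) {
    np <- dim(ang)[1]
    cs <- matrix(colMeans(matrix(cos(ang), np, nf * ntm)), nf, ntm)
    sn <- matrix(colMeans(matrix(sin(ang), np, nf * ntm)), nf, ntm)
    r <- sqrt(cs^2 + sn^2)
    z <- np * r^2
    p <- pmin(exp(sqrt(1 + 4 * np + 4 * (np^2 - (np * r)^2)) - (1 + 2 * np)), 1)
    list(z = z, p = p, r = r)
  }

  structure(list(clusters = cl,
                 rayleigh = list(success = rayleigh_maps(ang_s),
                                 failure = rayleigh_maps(ang_f)),
                 counts = unlist(counts), excluded = excluded,
                 participants = keep_p, freqs = freqs, times = tf_times,
                 settings = list(n_permutations = n_permutations,
                                 decim = decim,
                                 alpha_inclusion = alpha_inclusion,
                                 connectivity = connectivity, seed = seed)),
            class = "osc_success")
}

#' @export
print.osc_success <- function(x, ...) {
  cat("Success-contrast stage (equal-n successful vs unsuccessful trials)\n")
  cat(sprintf("  %d participants, mean %.1f trials per condition%s\n",
              length(x$participants), mean(x$counts),
              if (length(x$excluded))
                paste0("; excluded: ", paste(x$excluded, collapse = ", "))
              else ""))
  for (nm in names(x$clusters)) {
    tab <- x$clusters[[nm]]$clusters
    sig <- tab[tab$p <= 0.05, , drop = FALSE]
    cat(sprintf("  %s: %d cluster(s), %d significant at p <= 0.05\n",
                nm, nrow(tab), nrow(sig)))
    if (nrow(sig)) {
      for (i in seq_len(nrow(sig))) {
        cat(sprintf("    %s mass %.1f, %g-%g Hz, %.0f..%.0f ms, p = %.3g\n",
                    sig$sign[i], sig$mass[i], sig$freq_min[i], sig$freq_max[i],
                    1000 * sig$time_min[i], 1000 * sig$time_max[i], sig$p[i]))
      }
    }
  }
  invisible(x)
}
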
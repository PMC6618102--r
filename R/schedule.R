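#' Presentation frequencies of the burst-counting task
#'
#' The twelve burst-train presentation rates (Hz) used throughout the
#' package. 10 and 14 Hz are the high-prevalence frequencies.
#'
#' @format Integer vector of length 12.
#' @export
presentation_frequencies <- c(3, 4, 6, 8, 10, 12, 14, 16, 18, 22, 28, 38)

#' High-prevalence presentation frequencies
#' @format Integer vector of length 2.
#' @export
high_prevalence_frequencies <- c(10, 14)

#' Build a randomised trial schedule for the burst-counting task
#'
#' Constructs the full experimental design: each block presents the ten
#' base-rate frequencies `base_reps` times and the two high-prevalence
#' frequencies (10 and 14 Hz) `high_prev_reps` times, with the four burst
#' counts (4--7) equally prevalent within every frequency. Trial order is
#' randomised independently per block. The defaults reproduce the study
#' design: 4 blocks of 144 trials per participant, 576 trials per
#' participant, 11,520 trials over 20 participants.
#'
#' @param n_participants Number of participants (default 20).
#' @param n_blocks Blocks per participant (default 4).
#' @param base_reps Presentations per block of each base frequency
#'   (default 8); must be divisible by 4.
#' @param high_prev_reps Presentations per block of 10 and 14 Hz
#'   (default 32); must be divisible by 4.
#' @param seed Integer seed for the per-block order randomisation.
#' @return An `osc_schedule` data frame with columns `participant`, `block`,
#'   `trial` (position within block), `frequency` (Hz), `n_bursts`,
#'   `response` (NA until behaviour is simulated or observed), `correct`,
#'   and `rejected`.
#' @examples
#' sched <- build_trial_schedule(2, 1, 8, 32, seed = 1)
#' table(sched$frequency) / 2
#' @export
build_trial_schedule <- function(n_participants = 20, n_blocks = 4,
                                 base_reps = 8, high_prev_reps = 32,
                                 seed = 1) {
  if (base_reps %% 4 != 0 || high_prev_reps %% 4 != 0) {
    stop("invalid design: repetition counts must be divisible by the 4 burst conditions",
         call. = FALSE)
  }
  if (n_participants < 1 || n_blocks < 1) {
    stop("invalid design: need at least one participant and one block", call. = FALSE)
  }
  reps <- ifelse(presentation_frequencies %in% high_prevalence_frequencies,
                 high_prev_reps, base_reps)
  block_freq <- rep(presentation_frequencies, times = reps)
  block_bursts <- unlist(lapply(reps, function(r) rep(4:7, each = r / 4)))
  n_per_block <- length(block_freq)

  out <- vector("list", n_participants * n_blocks)
  with_seed(seed, {
    k <- 0L
    for (p in seq_len(n_participants)) {
      for (b in seq_len(n_blocks)) {
        ord <- sample.int(n_per_block)
        k <- k + 1L
        out[[k]] <- data.frame(
          participant = p, block = b, trial = seq_len(n_per_block),
          frequency = block_freq[ord], n_bursts = block_bursts[ord],
          response = NA_integer_, correct = NA, rejected = FALSE
        )
      }
    }
  })
  sched <- do.call(rbind, out)
  rownames(sched) <- NULL
  attr(sched, "seed") <- seed
  attr(sched, "design") <- list(n_participants = n_participants,
                                n_blocks = n_blocks, base_reps = base_reps,
                                high_prev_reps = high_prev_reps)
  class(sched) <- c("osc_schedule", "data.frame")
  sched
}

#' @export
print.osc_schedule <- function(x, ...) {
  d <- attr(x, "design")
  cat("Trial schedule:", d$n_participants, "participant(s) x", d$n_blocks,
      "block(s) x", nrow(x) / d$n_participants / d$n_blocks, "trials\n")
  cat("  frequencies (Hz):", paste(sort(unique(x$frequency)), collapse = ", "), "\n")
  cat("  responses filled:", sum(!is.na(x$response)), "/", nrow(x),
      " rejected:", sum(x$rejected), "\n")
  invisible(x)
}

# Run `code` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so library code does not disturb user streams.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic child seed from a master seed and a stage label.
# Non-cryptographic; keeps every derived seed inside 32-bit integer range.
derive_seed <- function(master, label) {
  h <- 17
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(master) + h) %% 2147483647)
}
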
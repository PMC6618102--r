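# Schema tags written at the head of every artifact.
SCHEMA <- list(schedule = "oscrep/schedule/1", epochs = "oscrep/epochs/1",
               result = "oscrep/result/1", config = "oscrep/config/1")

#' Write / read a trial schedule as delimited text
#'
#' CSV with a schema-versioned comment header; one row per trial.
#'
#' @param schedule An `osc_schedule`.
#' @param path Output file.
#' @return `read_trial_schedule` returns the `osc_schedule`.
#' @export
write_trial_schedule <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", SCHEMA$schedule, " seed=", attr(schedule, "seed")), con)
  utils::write.csv(as.data.frame(schedule), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_schedule
#' @export
read_trial_schedule <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, paste0("# ", SCHEMA$schedule))) {
    stop("schema mismatch: expected ", SCHEMA$schedule, call. = FALSE)
  }
  seed <- suppressWarnings(as.integer(sub(".*seed=", "", first)))
  sched <- utils::read.csv(path, comment.char = "#")
  sched$correct <- as.logical(sched$correct)
  sched$rejected <- as.logical(sched$rejected)
  sched$frequency <- as.numeric(sched$frequency)
  sched$response <- as.integer(sched$response)
  attr(sched, "seed") <- seed
  attr(sched, "design") <- list(
    n_participants = length(unique(sched$participant)),
    n_blocks = length(unique(sched$block)),
    base_reps = NA, high_prev_reps = NA)
  class(sched) <- c("osc_schedule", "data.frame")
  sched
}

#' Write / read epochs as a chunked array container
#'
#' Stores per-trial virtual-sensor epochs in an Arrow (Feather) chunked
#' columnar container, one dataset per participant, with a JSON metadata
#' sidecar carrying the sampling rate, time axis, audio offset and seeds.
#' Doubles round-trip losslessly.
#'
#' @param study An `osc_study` (or a list with `epochs`, `times`, `fs`,
#'   `seed`).
#' @param dir Container directory (created if needed).
#' @return `read_epochs` returns a list with `epochs`, `times`, `fs`,
#'   `audio_offset`, `seed`.
#' @export
write_epochs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(schema = SCHEMA$epochs, fs = study$fs,
               n_samples = length(study$times),
               t_start = study$times[1], audio_offset = 0.03,
               seed = study$seed,
               participants = seq_along(study$epochs),
               n_trials = vapply(study$epochs, ncol, integer(1)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  for (p in seq_along(study$epochs)) {
    df <- as.data.frame(study$epochs[[p]])
    names(df) <- paste0("trial", seq_len(ncol(df)))
    arrow::write_feather(df, file.path(dir, sprintf("participant%03d.feather", p)))
  }
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("no epoch container at ", dir, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$schema, SCHEMA$epochs)) {
    stop("schema mismatch: expected ", SCHEMA$epochs, call. = FALSE)
  }
  epochs <- lapply(meta$participants, function(p) {
    df <- arrow::read_feather(file.path(dir, sprintf("participant%03d.feather", p)))
    as.matrix(as.data.frame(df))
  })
  times <- meta$t_start + (seq_len(meta$n_samples) - 1) / meta$fs
  list(epochs = epochs, times = times, fs = meta$fs,
       audio_offset = meta$audio_offset, seed = meta$seed)
}

# Strip non-serialisable pieces from stage results and attach schema info.
result_payload <- function(x) {
  type <- class(x)[1]
  payload <- unclass(x)
  if (type == "osc_success") {
    payload$clusters <- lapply(payload$clusters, function(cl) {
      list(statistic = cl$statistic, clusters = cl$clusters,
           members = cl$members,
           null_max_quantiles = as.list(stats::quantile(cl$null_max,
                                                        c(0.5, 0.95, 0.99))),
           settings = cl$settings)
    })
    payload$rayleigh <- lapply(payload$rayleigh, function(r)
      list(max_z = max(r$z), min_p = min(r$p)))
  }
  if (type == "osc_correlation") {
    payload$ancova <- ancova_payload(payload$ancova)
  }
  if (type == "osc_entrainment") {
    payload$anova$bf_main <- unclass(payload$anova$bf_main)
    payload$participant_differences <-
      as.list(payload$participant_differences)
  }
  list(schema = SCHEMA$result, type = type, payload = payload)
}

ancova_payload <- function(a) {
  a <- unclass(a)
  a$slope_bf <- unclass(a$slope_bf)
  if (!is.null(a$intercept_bf)) a$intercept_bf <- unclass(a$intercept_bf)
  a
}

#' Write / read a stage result as JSON
#'
#' Deterministic JSON serialisation (full precision, no timestamps), so a
#' rerun with the same configuration produces byte-identical files.
#'
#' @param x A stage result (`osc_correlation`, `osc_entrainment`,
#'   `osc_success`) or any serialisable list.
#' @param path Output file.
#' @return `read_stage_result` returns the parsed list (with `$type`).
#' @export
write_stage_result <- function(x, path) {
  jsonlite::write_json(result_payload(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_stage_result
#' @export
read_stage_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, SCHEMA$result)) {
    stop("schema mismatch: expected ", SCHEMA$result, call. = FALSE)
  }
  x
}
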
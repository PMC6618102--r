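#' Pipeline run configuration
#'
#' Collects every design, ground-truth, spectral and stage setting plus the
#' master seed; every stochastic step of the pipeline derives its own seed
#' deterministically from the master seed and the stage name, so a rerun
#' with the same configuration reproduces every artifact byte for byte.
#'
#' @param n_participants,n_blocks,base_reps,high_prev_reps Design.
#' @param truth Ground-truth overrides (named list merged into
#'   [ground_truth()] defaults).
#' @param decim_summaries Filter-bank decimation for the correlation and
#'   entrainment stages.
#' @param decim_maps Decimation for the success-contrast maps (default 12,
#'   envelope at 100 Hz).
#' @param n_permutations,alpha_inclusion,connectivity Cluster settings.
#' @param seed Master seed.
#' @return An `osc_config` list.
#' @export
run_config <- function(n_participants = 20, n_blocks = 4, base_reps = 8,
                       high_prev_reps = 32, truth = list(),
                       decim_summaries = 4, decim_maps = 12,
                       n_permutations = 5000, alpha_inclusion = 0.05,
                       connectivity = 8, seed = 1) {
  cfg <- list(design = list(n_participants = n_participants,
                            n_blocks = n_blocks, base_reps = base_reps,
                            high_prev_reps = high_prev_reps),
              truth = truth,
              spectral = list(decim_summaries = decim_summaries,
                              decim_maps = decim_maps),
              stages = list(n_permutations = n_permutations,
                            alpha_inclusion = alpha_inclusion,
                            connectivity = connectivity),
              seed = seed)
  class(cfg) <- "osc_config"
  cfg
}

#' Write / read a run configuration (YAML)
#' @param config An `osc_config`.
#' @param path YAML file path.
#' @return `read_run_config` returns the `osc_config`.
#' @export
write_run_config <- function(config, path) {
  out <- c(list(schema = SCHEMA$config), unclass(config))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!identical(x$schema, SCHEMA$config)) {
    stop("schema mismatch: expected ", SCHEMA$config, call. = FALSE)
  }
  x$schema <- NULL
  class(x) <- "osc_config"
  x
}

# Short non-cryptographic hash of the configuration (FNV-1a over its YAML).
config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config), precision = 15)
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

pipeline_log <- function(out_dir, ...) {
  msg <- paste0(...)
  cat(msg, "\n", sep = "")
  cat(msg, "\n", sep = "", file = file.path(out_dir, "log.txt"), append = TRUE)
}

need_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing upstream artifact ", path, ": run the `", producer,
         "` step first", call. = FALSE)
  }
}

#' Run the synthetic-study pipeline
#'
#' Orchestrates the full pipeline on disk. Steps: `simulate` (schedule CSV
#' + epoch container), `decompose` (the shared spectral product: per-trial
#' band summaries at the 12 presentation bands, in an Arrow container,
#' consumed by `correlate` and `entrain`; the success contrast
#' decomposes its own full-grid maps from the epochs), `correlate`,
#' `entrain`, `contrast` (stage JSON results), `report`
#' (collated summary), or `all`. Each step reads its declared inputs from
#' `out_dir`, writes its declared outputs there, and logs settings and
#' exclusion counts; all outputs carry the configuration hash.
#'
#' @param config An `osc_config` (or path to its YAML).
#' @param step One of `"simulate"`, `"decompose"`, `"correlate"`,
#'   `"entrain"`, `"contrast"`, `"report"`, `"all"`.
#' @param out_dir Output directory.
#' @return Invisibly, the list of artifact paths written.
#' @export
run_pipeline <- function(config, step = "all", out_dir = "oscrep_run") {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "osc_config"))
  step <- match.arg(step, c("simulate", "decompose", "correlate", "entrain",
                            "contrast", "report", "all"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  steps <- if (step == "all") {
    c("simulate", "decompose", "correlate", "entrain", "contrast", "report")
  } else step
  paths <- character()
  for (s in steps) paths <- c(paths, pipeline_step(s, config, out_dir, hash))
  invisible(paths)
}

# Reassemble per-participant band-summary matrices from the decompose
# product.
load_band_summaries <- function(out_dir) {
  sums <- as.data.frame(arrow::read_feather(
    file.path(out_dir, "tf", "band_summaries.feather")))
  out <- list()
  for (p in unique(sums$participant)) {
    sp <- sums[sums$participant == p, ]
    rows <- unique(sp$row)
    bands <- unique(sp$band)
    out[[as.character(p)]] <- list(
      raw = matrix(sp$raw, length(rows), length(bands),
                   dimnames = list(NULL, bands)),
      induced = matrix(sp$induced, length(rows), length(bands),
                       dimnames = list(NULL, bands)),
      rows = rows, bands = bands)
  }
  out
}

# Build the in-memory study from artifacts on disk.
load_study <- function(config, out_dir) {
  sched_path <- file.path(out_dir, "schedule.csv")
  epoch_dir <- file.path(out_dir, "epochs")
  need_artifact(sched_path, "simulate")
  need_artifact(file.path(epoch_dir, "meta.json"), "simulate")
  sched <- read_trial_schedule(sched_path)
  ep <- read_epochs(epoch_dir)
  truth <- do.call(ground_truth, config$truth)
  structure(list(schedule = sched, epochs = ep$epochs, times = ep$times,
                 fs = ep$fs, truth = truth, seed = config$seed),
            class = "osc_study")
}

pipeline_step <- function(s, config, out_dir, hash) {
  d <- config$design
  truth <- do.call(ground_truth, config$truth)
  switch(s,
    simulate = {
      study <- simulate_study(truth, d$n_participants, d$n_blocks,
                              d$base_reps, d$high_prev_reps,
                              seed = config$seed)
      write_trial_schedule(study$schedule, file.path(out_dir, "schedule.csv"))
      write_epochs(study, file.path(out_dir, "epochs"))
      pipeline_log(out_dir, "[simulate] config ", hash, ": ",
                   nrow(study$schedule), " trials, ",
                   sum(study$schedule$rejected), " rejected (",
                   sprintf("%.1f%%", 100 * mean(study$schedule$rejected)), ")")
      c(file.path(out_dir, "schedule.csv"), file.path(out_dir, "epochs"))
    },
    decompose = {
      study <- load_study(config, out_dir)
      tf_dir <- file.path(out_dir, "tf")
      dir.create(tf_dir, showWarnings = FALSE)
      all_sum <- list()
      for (p in sort(unique(study$schedule$participant))) {
        rows <- usable_rows(study$schedule, p)
        cols <- match(rows, which(study$schedule$participant == p))
        sm <- trial_band_summaries(study$epochs[[p]][, cols, drop = FALSE],
                                   study$fs, study$times,
                                   study$truth$duty_cycle,
                                   decim = config$spectral$decim_summaries)
        all_sum[[length(all_sum) + 1L]] <- data.frame(
          participant = p, row = rows,
          frequency = study$schedule$frequency[rows],
          band = rep(sm$bands, each = length(rows)),
          raw = as.vector(sm$raw), induced = as.vector(sm$induced))
      }
      sums <- do.call(rbind, all_sum)
      arrow::write_feather(sums, file.path(tf_dir, "band_summaries.feather"))
      jsonlite::write_json(list(schema = SCHEMA$result, config_hash = hash,
                                decim = config$spectral$decim_summaries),
                           file.path(tf_dir, "meta.json"), auto_unbox = TRUE)
      pipeline_log(out_dir, "[decompose] config ", hash, ": band summaries for ",
                   length(unique(sums$participant)), " participants")
      tf_dir
    },
    correlate = {
      need_artifact(file.path(out_dir, "tf", "meta.json"), "decompose")
      study <- load_study(config, out_dir)
      res <- run_correlation_stage(study,
                                   decim = config$spectral$decim_summaries,
                                   summaries = load_band_summaries(out_dir))
      res$config_hash <- hash
      path <- file.path(out_dir, "correlation.json")
      write_stage_result(res, path)
      pipeline_log(out_dir, "[correlate] config ", hash, ": slope ",
                   sprintf("%.3f", res$ancova$slope), ", r ",
                   sprintf("%.3f", res$ancova$r))
      path
    },
    entrain = {
      need_artifact(file.path(out_dir, "tf", "meta.json"), "decompose")
      study <- load_study(config, out_dir)
      res <- run_entrainment_stage(study,
                                   seed = derive_seed(config$seed, "entrainment"),
                                   decim = config$spectral$decim_summaries,
                                   summaries = load_band_summaries(out_dir))
      res$config_hash <- hash
      path <- file.path(out_dir, "entrainment.json")
      write_stage_result(res, path)
      pipeline_log(out_dir, "[entrain] config ", hash, ": F(",
                   res$anova$df_main[1], ",", res$anova$df_main[2], ") = ",
                   sprintf("%.2f", res$anova$f_main), "; excluded ",
                   length(res$excluded), " participant(s)")
      path
    },
    contrast = {
      need_artifact(file.path(out_dir, "tf", "meta.json"), "decompose")
      study <- load_study(config, out_dir)
      res <- run_success_contrast_stage(
        study, seed = derive_seed(config$seed, "success"),
        n_permutations = config$stages$n_permutations,
        decim = config$spectral$decim_maps,
        alpha_inclusion = config$stages$alpha_inclusion,
        connectivity = config$stages$connectivity)
      res$config_hash <- hash
      path <- file.path(out_dir, "success_contrast.json")
      write_stage_result(res, path)
      pipeline_log(out_dir, "[contrast] config ", hash, ": ",
                   length(res$participants), " participants, ",
                   length(res$excluded), " excluded")
      path
    },
    report = {
      parts <- c(correlation = "correlation.json",
                 entrainment = "entrainment.json",
                 success_contrast = "success_contrast.json")
      for (f in parts) {
        need_artifact(file.path(out_dir, f),
                      c("correlate", "entrain", "contrast")[parts == f])
      }
      rep <- lapply(file.path(out_dir, parts), read_stage_result)
      names(rep) <- names(parts)
      out <- list(schema = SCHEMA$result, type = "report",
                  config_hash = hash,
                  correlation = list(
                    slope = rep$correlation$payload$ancova$slope,
                    r = rep$correlation$payload$ancova$r,
                    intercept_bf10 = rep$correlation$payload$ancova$intercept_bf$bf10),
                  entrainment = list(
                    f_main = rep$entrainment$payload$anova$f_main,
                    p_main = rep$entrainment$payload$anova$p_main,
                    bf10_main = rep$entrainment$payload$anova$bf_main$bf10),
                  success_contrast = lapply(
                    rep$success_contrast$payload$clusters, function(cl) {
                      tab <- cl$clusters
                      if (is.data.frame(tab) && nrow(tab)) {
                        tab[tab$p <= 0.05, , drop = FALSE]
                      } else list()
                    }))
      path <- file.path(out_dir, "report.json")
      jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
      pipeline_log(out_dir, "[report] config ", hash, ": collated")
      path
    })
}

#' Command-line entry point
#'
#' Thin argument parser over [run_pipeline()]:
#' `oscrep.R <step> --config <yaml> [--out <dir>]` with step one of
#' simulate, decompose, correlate, entrain, contrast, report, all.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
oscrep_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: oscrep.R <simulate|decompose|correlate|entrain|contrast|report|all> [--config config.yaml] [--out dir]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  step <- args[1]
  getopt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  cfg_path <- getopt("--config", NA)
  out_dir <- getopt("--out", "oscrep_run")
  config <- if (is.na(cfg_path)) run_config() else read_run_config(cfg_path)
  status <- tryCatch({
    run_pipeline(config, step, out_dir)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
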
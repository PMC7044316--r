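# Pipeline orchestration: configuration, a reproducible generate -> simulate
# -> analyze -> model run, and machine-readable reports.

config_defaults <- function(modality = "auditory") {
  list(
    modality = modality,
    sessions = c("passive", "tracking"),
    preset = switch(modality, auditory = "auditory_8", visual = "visual_8"),
    n_trials = 40L,
    density = 1.0,
    observer = list(),
    model = list(duration = 1000, n_realizations = 10L),
    seeds = list(paradigm = 1L, observer = 2L, model = 3L),
    out_dir = NULL)
}

config_error <- function(pointer, msg) {
  stop(errorCondition(sprintf("config%s: %s", pointer, msg),
                      class = c("beatattn_config_error", "error")))
}

#' Build and validate a pipeline run configuration
#'
#' Unknown fields are rejected (a misspelt key never silently falls back to a
#' default). Defaults: auditory modality, passive + tracking sessions, the
#' modality's standard condition preset, 40 trials per condition, density 1,
#' a 1000 s / 10-realization model sweep, and one independent seed per stage.
#'
#' @param ... Named fields: `modality`, `sessions`, `preset`, `n_trials`,
#'   `density`, `observer` (overrides for [observer_params()]), `model`
#'   (overrides for [model_params()] plus `n_realizations`), `seeds` (named
#'   list `paradigm`, `observer`, `model`), `out_dir`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  fields <- list(...)
  if (length(fields) && (is.null(names(fields)) || any(names(fields) == ""))) {
    config_error("", "all fields must be named")
  }
  modality <- fields$modality %||% "auditory"
  if (!is.character(modality) || length(modality) != 1L ||
      !modality %in% c("auditory", "visual")) {
    config_error("/modality", "must be 'auditory' or 'visual'")
  }
  cfg <- config_defaults(modality)
  unknown <- setdiff(names(fields), names(cfg))
  if (length(unknown)) {
    config_error(paste0("/", unknown[1]), "unknown field")
  }
  cfg[names(fields)] <- fields

  if (!all(cfg$sessions %in% c("passive", "tracking")) ||
      length(cfg$sessions) < 1L || anyDuplicated(cfg$sessions)) {
    config_error("/sessions", "must be a subset of {passive, tracking}")
  }
  if (!is.character(cfg$preset) || length(cfg$preset) != 1L) {
    config_error("/preset", "must be a condition preset name")
  }
  tryCatch(condition_set(cfg$preset),
           error = function(e) config_error("/preset", conditionMessage(e)))
  if (!is_count(cfg$n_trials)) config_error("/n_trials", "must be a positive integer")
  if (!is.numeric(cfg$density) || cfg$density < 0) {
    config_error("/density", "must be >= 0")
  }
  if (!is.list(cfg$observer)) config_error("/observer", "must be an object")
  obs_ok <- setdiff(names(formals(observer_params)), "...")
  bad <- setdiff(names(cfg$observer), obs_ok)
  if (length(bad)) config_error(paste0("/observer/", bad[1]), "unknown field")
  if (!is.list(cfg$model)) config_error("/model", "must be an object")
  mod_ok <- c(names(formals(model_params)), "n_realizations")
  bad <- setdiff(names(cfg$model), mod_ok)
  if (length(bad)) config_error(paste0("/model/", bad[1]), "unknown field")
  if (!is.list(cfg$seeds)) config_error("/seeds", "must be an object")
  bad <- setdiff(names(cfg$seeds), c("paradigm", "observer", "model"))
  if (length(bad)) config_error(paste0("/seeds/", bad[1]), "unknown field")
  for (s in c("paradigm", "observer", "model")) {
    if (is.null(cfg$seeds[[s]])) cfg$seeds[[s]] <- config_defaults()$seeds[[s]]
    if (!is.numeric(cfg$seeds[[s]]) || length(cfg$seeds[[s]]) != 1L ||
        !is.finite(cfg$seeds[[s]])) {
      config_error(paste0("/seeds/", s), "must be a single integer")
    }
    cfg$seeds[[s]] <- as.integer(cfg$seeds[[s]])
  }
  cfg$n_trials <- as.integer(cfg$n_trials)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a run configuration from JSON
#'
#' Strict validation: unknown keys anywhere in the schema are rejected with a
#' JSON-pointer to the offending field; defaults fill the remaining fields.
#' `load_config(write_config(x))` returns a configuration equal to `x`.
#'
#' @param path Path to a JSON configuration file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) {
      stop(errorCondition(paste0("cannot parse config JSON: ",
                                 conditionMessage(e)),
                          class = c("beatattn_config_error", "error")))
    })
  if (!is.list(raw)) config_error("", "top level must be an object")
  for (k in c("observer", "model", "seeds")) {
    if (!is.null(raw[[k]])) raw[[k]] <- as.list(raw[[k]])
  }
  do.call(run_config, raw)
}

#' Write a run configuration to JSON
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a run report to JSON
#' @param report A `run_report` from [run_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

stage_log <- function(stage, seed, t0) {
  message(sprintf("stage=%s seed=%s elapsed=%.2fs",
                  stage, seed, as.numeric(proc.time()[3] - t0)))
}

#' Run the full pipeline: generate, simulate, analyze, model
#'
#' Executes the four stages with one independent seed each: (1) paradigm -
#' generate every trial sequence; (2) observer - draw responses and tracking
#' taps; (3) metrics - performance curves, cubic optimal-tempo fits and tap
#' metrics; (4) model - stimulus-frequency sweeps of the three-oscillator
#' model per session, affine fit to behaviour, and the sign of the
#' tracking-passive PLV difference at 1.7 Hz. All artifacts are CSV/JSON in
#' `out_dir`; a fixed configuration reproduces them byte for byte.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (defaults to `config$out_dir`).
#' @return An object of class `run_report`: schema version, configuration
#'   echo, per-stage status and seeds, output-file MD5 digests, and headline
#'   metrics (optimal tempo alpha per session, PLV-curve peak per session,
#'   model-behaviour R^2 per session, and the signed tracking-passive PLV
#'   difference at 1.7 Hz when both sessions ran).
#' @export
run_all <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) config_error("/out_dir", "must be set to run the pipeline")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  path_of <- function(name) file.path(out_dir, name)
  fail <- function(stage, e) {
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = c("beatattn_stage_error", "error"),
      data = list(stage = stage, files_written = files)))
  }
  freqs <- condition_set(config$preset)
  obs <- do.call(observer_params,
                 c(config$observer, list(modality = config$modality)))

  # stage 1: paradigm ---------------------------------------------------
  t0 <- proc.time()[3]
  sequences <- tryCatch({
    n_seq <- length(config$sessions) * length(freqs) * config$n_trials
    seeds <- derive_seeds(config$seeds$paradigm, 2L * n_seq)
    idx <- 0L
    seqs <- list()
    meta <- list()
    for (sess in config$sessions) {
      for (f in freqs) {
        bs <- beat_spec(f, fraction = switch(config$modality,
                                             auditory = 0.10, visual = 0.18))
        for (k in seq_len(config$n_trials)) {
          idx <- idx + 1L
          on_beat <- with_seed(seeds[2L * idx - 1L], stats::runif(1) < 0.5)
          seqs[[idx]] <- generate_trial(bs, config$density, on_beat,
                                        modality = config$modality,
                                        seed = seeds[2L * idx])
          meta[[idx]] <- data.frame(trial_id = idx, condition_hz = f,
                                    session = sess,
                                    deviant_on_beat = on_beat,
                                    stringsAsFactors = FALSE)
        }
      }
    }
    list(seqs = seqs, meta = do.call(rbind, meta))
  }, error = function(e) fail("paradigm", e))
  write_trial_events(sequences$seqs, path_of("events.csv"))
  files <- c(files, path_of("events.csv"))
  stage_log("paradigm", config$seeds$paradigm, t0)

  # stage 2: observer ---------------------------------------------------
  t0 <- proc.time()[3]
  data <- tryCatch({
    meta <- sequences$meta
    skel <- data.frame(condition_hz = meta$condition_hz,
                       density = config$density,
                       deviant_on_beat = meta$deviant_on_beat)
    trials <- simulate_responses(skel, obs, seed = config$seeds$observer)
    trials$trial_id <- meta$trial_id
    trials$session <- meta$session
    taps <- data.frame(trial_id = integer(0), tap_index = integer(0),
                       tap_time_s = numeric(0))
    tap_records <- list()
    track_idx <- which(meta$session == "tracking")
    if (length(track_idx)) {
      tap_seeds <- derive_seeds(config$seeds$observer, length(track_idx))
      taps_list <- lapply(seq_along(track_idx), function(j) {
        i <- track_idx[j]
        rec <- simulate_taps(sequences$seqs[[i]], obs, seed = tap_seeds[j])
        tap_records[[as.character(meta$trial_id[i])]] <<- rec
        data.frame(trial_id = meta$trial_id[i],
                   tap_index = seq_along(rec$tap_times),
                   tap_time_s = rec$tap_times)
      })
      taps <- do.call(rbind, taps_list)
    }
    list(trials = trials, taps = taps, tap_records = tap_records)
  }, error = function(e) fail("observer", e))
  utils::write.csv(data$trials, path_of("trials.csv"), row.names = FALSE)
  utils::write.csv(data$taps, path_of("taps.csv"), row.names = FALSE)
  files <- c(files, path_of("trials.csv"), path_of("taps.csv"))
  stage_log("observer", config$seeds$observer, t0)

  # stage 3: metrics ----------------------------------------------------
  t0 <- proc.time()[3]
  metrics <- tryCatch({
    per_session <- list()
    curve_rows <- list()
    for (sess in config$sessions) {
      tr <- data$trials[data$trials$session == sess, ]
      curve <- performance_curve(tr, conditions = freqs)
      fit <- fit_cubic_optimal_tempo(curve$condition_hz, curve$prop_correct)
      curve$fitted_value <- predict_cubic(fit, curve$condition_hz)
      curve$session <- sess
      curve_rows[[sess]] <- as.data.frame(curve)
      per_session[[sess]] <- list(
        alpha_hz = if (fit$has_optimum) fit$alpha else NULL,
        alpha_in_range = fit$alpha_in_range,
        cubic_r_squared = fit$r_squared,
        curve = as.data.frame(curve))
    }
    tap_metrics <- NULL
    if (length(data$tap_records)) {
      ids <- names(data$tap_records)
      tap_metrics <- do.call(rbind, lapply(ids, function(id) {
        rec <- data$tap_records[[id]]
        phi <- sensorimotor_simultaneity(rec)
        data.frame(trial_id = as.integer(id),
                   precision_pct = tapping_precision(rec),
                   cv = tapping_cv(rec),
                   phi_signed = phi$phi_signed,
                   phi_abs = phi$phi_abs)
      }))
      tap_metrics <- tap_metrics[order(tap_metrics$trial_id), ]
    }
    list(per_session = per_session,
         curves = do.call(rbind, curve_rows),
         tap_metrics = tap_metrics)
  }, error = function(e) fail("metrics", e))
  utils::write.csv(metrics$curves, path_of("curves.csv"), row.names = FALSE)
  files <- c(files, path_of("curves.csv"))
  if (!is.null(metrics$tap_metrics)) {
    utils::write.csv(metrics$tap_metrics, path_of("tap_metrics.csv"),
                     row.names = FALSE)
    files <- c(files, path_of("tap_metrics.csv"))
  }
  jsonlite::write_json(
    lapply(metrics$per_session, function(m)
      m[c("alpha_hz", "alpha_in_range", "cubic_r_squared")]),
    path_of("metrics.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, path_of("metrics.json"))
  stage_log("metrics", NA, t0)

  # stage 4: model ------------------------------------------------------
  t0 <- proc.time()[3]
  model <- tryCatch({
    model_over <- config$model
    n_real <- model_over$n_realizations %||% 10L
    model_over$n_realizations <- NULL
    sweep_seeds <- derive_seeds(config$seeds$model, length(config$sessions))
    sweeps <- list()
    fits <- list()
    for (si in seq_along(config$sessions)) {
      sess <- config$sessions[si]
      pp <- do.call(preset, c(list(modality = config$modality, session = sess),
                              model_over))
      sw <- frequency_sweep(pp, freqs, n_realizations = n_real,
                            base_seed = sweep_seeds[si],
                            label = paste(config$modality, sess, sep = "_"))
      sweeps[[sess]] <- sw
      fits[[sess]] <- fit_to_behavior(
        sw, metrics$per_session[[sess]]$curve)
    }
    diff_17 <- NULL
    if (all(c("passive", "tracking") %in% config$sessions) &&
        any(abs(freqs - 1.7) < 1e-9)) {
      at <- function(sw) sw$plv_mean[abs(sw$stim_freq_hz - 1.7) < 1e-9]
      diff_17 <- at(sweeps$tracking) - at(sweeps$passive)
    }
    list(sweeps = sweeps, fits = fits, tracking_minus_passive_plv_1p7 = diff_17)
  }, error = function(e) fail("model", e))
  for (sess in names(model$sweeps)) {
    write_sweep(model$sweeps[[sess]],
                runs_path = path_of(sprintf("sweep_%s_runs.csv", sess)),
                summary_path = path_of(sprintf("sweep_%s.csv", sess)))
    files <- c(files, path_of(sprintf("sweep_%s_runs.csv", sess)),
               path_of(sprintf("sweep_%s.csv", sess)))
  }
  stage_log("model", config$seeds$model, t0)

  digests <- tools::md5sum(files)
  headline <- list(
    alpha_hz = lapply(metrics$per_session, `[[`, "alpha_hz"),
    plv_peak_hz = lapply(model$sweeps, function(sw)
      sw$stim_freq_hz[which.max(sw$plv_mean)]),
    model_r_squared = lapply(model$fits, `[[`, "r_squared"),
    tracking_minus_passive_plv_1p7 = model$tracking_minus_passive_plv_1p7,
    motor_modulation_sign =
      if (is.null(model$tracking_minus_passive_plv_1p7)) NULL else
        unname(sign(model$tracking_minus_passive_plv_1p7)))
  report <- structure(
    list(schema_version = "1.0",
         config = unclass(config)[setdiff(names(config), "out_dir")],
         stages = lapply(c(paradigm = "paradigm", observer = "observer",
                           metrics = "metrics", model = "model"),
                         function(s) list(
                           status = "ok",
                           seed = config$seeds[[s]] %||% NA)),
         files = as.list(stats::setNames(unname(digests), basename(files))),
         headline = headline),
    class = "run_report")
  write_report(report, path_of("report.json"))
  report
}
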
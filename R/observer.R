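# Synthetic observer: a statistical emulator of behaviour in the
# beat-discrimination task. Accuracy follows an inverse-U tuning over tempo
# (Gaussian on the log2-frequency axis) scaled down by distractor density;
# tapping carries a modality-typical mean asynchrony, Gaussian jitter, and a
# tempo-dependent rate compression (too fast at slow tempi, too slow at fast
# ones). The emulator is deliberately NOT the cubic used downstream to
# estimate optimal tempi, so parameter recovery is a non-circular test.

#' Parameters of the synthetic observer
#'
#' @param optimal_tempo Tempo of peak accuracy, Hz (~1.4 auditory, ~0.7
#'   visual).
#' @param tuning_width Width (SD) of the accuracy peak on the log2-frequency
#'   axis, in octaves.
#' @param peak_accuracy Probability correct at the optimal tempo with no
#'   distractors, in \[0.5, 1\].
#' @param lapse_rate Proportion of trials answered at chance regardless of
#'   the stimulus, in \[0, 0.5\].
#' @param density_slope Linear accuracy loss per unit distractor density
#'   (the above-chance part of accuracy is scaled by
#'   `max(0, 1 - density_slope * density)`).
#' @param tap_jitter_sd SD of tap timing jitter as a fraction of the beat
#'   period.
#' @param mean_asynchrony Mean signed tap-beat asynchrony in seconds;
#'   negative values are anticipatory (typical in audition), positive
#'   reactive (typical in vision).
#' @param rate_compression Dimensionless slope coupling the produced
#'   inter-tap interval to tempo: ITI = T + rate_compression * (T - T_ref)
#'   with T_ref = 1/1.7 s. Negative values reproduce tapping too fast at
#'   slow tempi and too slow at fast tempi.
#' @param modality Convenience preset: `"auditory"` sets the defaults above;
#'   `"visual"` switches to a 0.7 Hz peak, a reactive (+50 ms) asynchrony and
#'   a shallower density slope (fewer distractors are needed to disrupt
#'   visual performance, so the slope is steeper per distractor; see
#'   vignette). Explicit arguments always override the preset.
#' @return An object of class `observer_params`.
#' @examples
#' observer_params()                     # auditory defaults, peak 1.4 Hz
#' observer_params(modality = "visual")  # peak 0.7 Hz, reactive tapping
#' @export
observer_params <- function(optimal_tempo = NULL,
                            tuning_width = 1.0,
                            peak_accuracy = 0.95,
                            lapse_rate = 0.02,
                            density_slope = NULL,
                            tap_jitter_sd = 0.05,
                            mean_asynchrony = NULL,
                            rate_compression = -0.1,
                            modality = c("auditory", "visual")) {
  modality <- match.arg(modality)
  if (is.null(optimal_tempo)) {
    optimal_tempo <- switch(modality, auditory = 1.4, visual = 0.7)
  }
  if (is.null(mean_asynchrony)) {
    mean_asynchrony <- switch(modality, auditory = -0.03, visual = 0.05)
  }
  if (is.null(density_slope)) {
    density_slope <- switch(modality, auditory = 0.35, visual = 0.6)
  }
  if (optimal_tempo <= 0) stop_invalid("optimal_tempo must be positive")
  if (peak_accuracy < 0.5 || peak_accuracy > 1) {
    stop_invalid("peak_accuracy must lie in [0.5, 1]")
  }
  if (lapse_rate < 0 || lapse_rate > 0.5) {
    stop_invalid("lapse_rate must lie in [0, 0.5]")
  }
  if (tuning_width <= 0) stop_invalid("tuning_width must be positive")
  if (tap_jitter_sd < 0) stop_invalid("tap_jitter_sd must be >= 0")
  if (density_slope < 0) stop_invalid("density_slope must be >= 0")
  structure(
    list(optimal_tempo = optimal_tempo,
         tuning_width = tuning_width,
         peak_accuracy = peak_accuracy,
         lapse_rate = lapse_rate,
         density_slope = density_slope,
         tap_jitter_sd = tap_jitter_sd,
         mean_asynchrony = mean_asynchrony,
         rate_compression = rate_compression,
         modality = modality),
    class = "observer_params")
}

#' Expected accuracy of the synthetic observer
#'
#' Probability of a correct on-/off-beat judgment at beat frequency `f` and
#' distractor density `density`:
#' \deqn{p = 0.5 + (p_{peak} - 0.5)\,
#'       e^{-(\log_2 f - \log_2 f^\star)^2 / (2 w^2)}\,
#'       \max(0, 1 - s \cdot d)}
#' then mixed with a lapse, `p <- (1 - lapse) p + lapse / 2`. The profile is
#' an inverse U, symmetric in log-frequency about the optimal tempo
#' \eqn{f^\star}, with chance level 0.5.
#'
#' @param f Beat frequency in Hz (vectorised; must be positive).
#' @param density Distractor density (per beat).
#' @param params An [observer_params()].
#' @return Probability correct, same length as `f`.
#' @examples
#' p <- observer_params()
#' accuracy_model(p$optimal_tempo, 0, p)  # peak accuracy (minus lapse mixing)
#' @export
accuracy_model <- function(f, density, params) {
  stopifnot(inherits(params, "observer_params"))
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop_invalid("beat frequency must be positive and finite")
  }
  if (any(density < 0)) stop_invalid("density must be >= 0")
  tune <- exp(-(log2(f) - log2(params$optimal_tempo))^2 /
                (2 * params$tuning_width^2))
  p <- 0.5 + (params$peak_accuracy - 0.5) * tune *
    pmax(0, 1 - params$density_slope * density)
  (1 - params$lapse_rate) * p + params$lapse_rate * 0.5
}

#' Invert the accuracy model for the density giving a criterion accuracy
#'
#' Numerically finds the distractor density at which the observer's expected
#' accuracy equals `target` at beat frequency `f` (the quantity the adaptive
#' staircase estimates empirically).
#'
#' @inheritParams accuracy_model
#' @param target Criterion accuracy (default 0.75).
#' @param upper Upper bracket for the search.
#' @return The density, or an error if the target accuracy is unreachable.
#' @export
density_for_accuracy <- function(f, params, target = 0.75, upper = 50) {
  g <- function(d) accuracy_model(f, d, params) - target
  if (g(0) < 0) {
    stop_infeasible("expected accuracy at zero density is already below the target")
  }
  if (g(upper) > 0) {
    stop_infeasible("target accuracy not reached within the density bracket")
  }
  stats::uniroot(g, c(0, upper), tol = 1e-10)$root
}

#' Draw per-trial binary responses from the accuracy model
#'
#' @param sequences Either a list of `trial_sequence` objects or a data.frame
#'   with columns `condition_hz` and `density` (one row per trial); the
#'   data.frame form avoids materialising full event sequences when only
#'   responses are needed.
#' @param params An [observer_params()].
#' @param seed Optional integer seed; the same seed yields an identical
#'   table.
#' @param session Label stored with each trial (`"passive"` or `"tracking"`).
#' @return A trials data.frame: `trial_id`, `condition_hz`, `density`,
#'   `deviant_on_beat`, `response_correct` (0/1), `session`.
#' @export
simulate_responses <- function(sequences, params, seed = NULL,
                               session = "passive") {
  stopifnot(inherits(params, "observer_params"))
  if (is.data.frame(sequences)) {
    skel <- sequences
    if (!all(c("condition_hz", "density") %in% names(skel))) {
      stop_invalid("trial skeleton needs condition_hz and density columns")
    }
    if (is.null(skel$deviant_on_beat)) skel$deviant_on_beat <- NA
  } else {
    if (inherits(sequences, "trial_sequence")) sequences <- list(sequences)
    skel <- data.frame(
      condition_hz = vapply(sequences, function(s) s$beat$frequency, 0),
      density = vapply(sequences, function(s) s$density, 0),
      deviant_on_beat = vapply(sequences, function(s) s$deviant_on_beat, NA))
  }
  n <- nrow(skel)
  p <- accuracy_model(skel$condition_hz, skel$density, params)
  with_seed(seed, {
    data.frame(trial_id = seq_len(n),
               condition_hz = skel$condition_hz,
               density = skel$density,
               deviant_on_beat = skel$deviant_on_beat,
               response_correct = as.integer(stats::runif(n) < p),
               session = session,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a tap series for one tracking trial
#'
#' Taps start at the second reference stimulus and continue to the end of the
#' trial. The produced inter-tap interval follows a rate-compression law,
#' `ITI = T + rate_compression * (T - T_ref)` with reference period
#' `T_ref = 1/1.7` s, so a negative compression yields tapping faster than
#' the beat at slow tempi and slower at fast tempi. Each tap additionally
#' carries the observer's mean asynchrony and independent Gaussian jitter
#' with SD `tap_jitter_sd * T`.
#'
#' @param seq A valid `trial_sequence`.
#' @param params An [observer_params()].
#' @param seed Optional integer seed.
#' @return An object of class `tap_record`: `tap_times` (seconds from trial
#'   start), `beat_times` (the beat grid from the second reference to the
#'   deviant's expected beat) and the beat `period`.
#' @export
simulate_taps <- function(seq, params, seed = NULL) {
  stopifnot(inherits(params, "observer_params"))
  if (!inherits(seq, "trial_sequence")) stop_invalid("seq must be a trial_sequence")
  viol <- validate_sequence(seq)
  if (nrow(viol)) {
    stop_invalid("invalid trial sequence: ", paste(viol$rule, collapse = ", "))
  }
  T <- seq$beat$period
  t_ref <- 1 / 1.7
  iti <- T + params$rate_compression * (T - t_ref)
  start <- T                     # second reference stimulus
  t_end <- max(seq$events$onset)
  n_taps <- max(1L, 1L + as.integer(floor((t_end - start) / iti)))
  with_seed(seed, {
    jitter <- stats::rnorm(n_taps, 0, params$tap_jitter_sd * T)
    taps <- start + (seq_len(n_taps) - 1L) * iti + params$mean_asynchrony + jitter
    beat_grid <- seq(from = T, by = T,
                     to = (3 + seq$n_targets) * T + T / 4)
    structure(list(tap_times = taps, beat_times = beat_grid, period = T),
              class = "tap_record")
  })
}

#' Generate a full synthetic experiment (responses and taps)
#'
#' Builds a complete dataset with the structure of one experimental session
#' set: for each beat-frequency condition in the preset and each requested
#' session, `n_trials_per_condition` trials with binary correct/incorrect
#' responses drawn from [accuracy_model()], plus tap series (from
#' [simulate_taps()]) for tracking-session trials.
#'
#' @param preset A condition preset name for [condition_set()] or a numeric
#'   vector of beat frequencies in Hz.
#' @param n_trials_per_condition Trials per condition per session (the
#'   standard session length is 40, i.e. 320 trials over 8 conditions).
#' @param params An [observer_params()].
#' @param density Distractor density used throughout (a staircase-calibrated
#'   value in the real paradigm).
#' @param sessions Character vector from `c("passive", "tracking")`.
#' @param seed Integer seed; the dataset is deterministic given all
#'   arguments.
#' @return An object of class `synthetic_dataset`: `trials` (data.frame as
#'   in [simulate_responses()]), `taps` (data.frame `trial_id`, `tap_index`,
#'   `tap_time_s`; zero rows when no tracking session), `tap_records` (the
#'   underlying `tap_record` objects keyed by trial id), `params`, `density`,
#'   `conditions`, `seed`.
#' @export
generate_experiment <- function(preset = "auditory_8",
                                n_trials_per_condition = 40L,
                                params = observer_params(),
                                density = 1.0,
                                sessions = "passive",
                                seed = NULL) {
  stopifnot(inherits(params, "observer_params"))
  freqs <- if (is.character(preset)) condition_set(preset) else {
    if (!is.numeric(preset) || any(preset <= 0)) {
      stop_invalid("preset must be a preset name or positive frequencies")
    }
    sort(preset)
  }
  if (!is.numeric(n_trials_per_condition) || n_trials_per_condition < 0) {
    stop_invalid("n_trials_per_condition must be >= 0")
  }
  bad_sessions <- setdiff(sessions, c("passive", "tracking"))
  if (length(bad_sessions)) stop_invalid("unknown session: ", bad_sessions[1])
  n_per <- as.integer(n_trials_per_condition)
  modality <- params$modality

  empty_trials <- data.frame(trial_id = integer(0), condition_hz = numeric(0),
                             density = numeric(0), deviant_on_beat = logical(0),
                             response_correct = integer(0),
                             session = character(0), stringsAsFactors = FALSE)
  empty_taps <- data.frame(trial_id = integer(0), tap_index = integer(0),
                           tap_time_s = numeric(0))
  if (n_per == 0L || length(sessions) == 0L) {
    return(structure(list(trials = empty_trials, taps = empty_taps,
                          tap_records = list(), params = params,
                          density = density, conditions = freqs,
                          seed = seed),
                     class = "synthetic_dataset"))
  }

  seeds <- matrix(derive_seeds(seed, 4L * length(sessions)),
                  nrow = length(sessions))
  trials_list <- list()
  taps_list <- list()
  tap_records <- list()
  next_id <- 1L
  for (si in seq_along(sessions)) {
    sess <- sessions[si]
    skel <- data.frame(
      condition_hz = rep(freqs, each = n_per),
      density = density)
    tr <- simulate_responses(skel, params, seed = seeds[si, 1L], session = sess)
    tr$trial_id <- seq.int(next_id, length.out = nrow(tr))
    tr$deviant_on_beat <- with_seed(seeds[si, 2L],
                                    stats::runif(nrow(tr)) < 0.5)
    if (sess == "tracking") {
      tap_seeds <- derive_seeds(seeds[si, 3L], nrow(tr))
      seq_seeds <- derive_seeds(seeds[si, 4L], nrow(tr))
      for (i in seq_len(nrow(tr))) {
        sq <- generate_trial(beat_spec(tr$condition_hz[i]),
                             density = density,
                             deviant_on_beat = tr$deviant_on_beat[i],
                             modality = modality,
                             seed = seq_seeds[i])
        rec <- simulate_taps(sq, params, seed = tap_seeds[i])
        tap_records[[as.character(tr$trial_id[i])]] <- rec
        taps_list[[length(taps_list) + 1L]] <- data.frame(
          trial_id = tr$trial_id[i],
          tap_index = seq_along(rec$tap_times),
          tap_time_s = rec$tap_times)
      }
    }
    trials_list[[si]] <- tr
    next_id <- next_id + nrow(tr)
  }
  structure(
    list(trials = do.call(rbind, trials_list),
         taps = if (length(taps_list)) do.call(rbind, taps_list) else empty_taps,
         tap_records = tap_records,
         params = params, density = density, conditions = freqs, seed = seed),
    class = "synthetic_dataset")
}
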
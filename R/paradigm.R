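# Beat-discrimination paradigm: stimulus sequence generation, validation,
# condition presets and the adaptive distractor-density staircase.

#' Define the beat of a stimulus sequence
#'
#' A beat specification fixes the tempo of an isochronous stream and the rule
#' used to derive the duration of the individual stimuli. In the auditory
#' paradigm stimuli last a fraction (default 10%) of the inter-stimulus
#' interval; in the visual paradigm the fraction is 18%; an alternative rule
#' fixes the stimulus length across tempi (default 22.5 ms), which decouples
#' stimulus duration from tempo.
#'
#' @param frequency Beat frequency (tempo) in Hz. Must be positive.
#' @param duration_rule Either `"fraction_of_isi"` (stimulus duration =
#'   `fraction` times the beat period) or `"fixed"` (constant
#'   `fixed_length` seconds across tempi).
#' @param fraction Fraction of the beat period a stimulus lasts, in (0, 1).
#' @param fixed_length Stimulus duration in seconds under the `"fixed"` rule.
#' @return An object of class `beat_spec` with fields `frequency`, `period`,
#'   `duration_rule` and `stimulus_duration` (seconds).
#' @examples
#' beat_spec(1)                       # 1 Hz, 100 ms tones
#' beat_spec(2, fraction = 0.18)      # visual-style gratings
#' beat_spec(2, "fixed")              # 22.5 ms tones at any tempo
#' @export
beat_spec <- function(frequency,
                      duration_rule = c("fraction_of_isi", "fixed"),
                      fraction = 0.10,
                      fixed_length = 0.0225) {
  duration_rule <- match.arg(duration_rule)
  if (!is.numeric(frequency) || length(frequency) != 1L ||
      !is.finite(frequency) || frequency <= 0) {
    stop_invalid("beat frequency must be a single positive finite number")
  }
  if (duration_rule == "fraction_of_isi") {
    if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
      stop_invalid("fraction must lie in (0, 1)")
    }
    stim_dur <- fraction / frequency
  } else {
    if (!is.numeric(fixed_length) || fixed_length <= 0) {
      stop_invalid("fixed stimulus length must be positive")
    }
    stim_dur <- fixed_length
  }
  structure(
    list(frequency = frequency,
         period = 1 / frequency,
         duration_rule = duration_rule,
         fraction = if (duration_rule == "fraction_of_isi") fraction else NA_real_,
         fixed_length = if (duration_rule == "fixed") fixed_length else NA_real_,
         stimulus_duration = stim_dur),
    class = "beat_spec")
}

default_duration_bounds <- function(modality) {
  switch(modality, auditory = c(2, 12), visual = c(2, 20))
}

# Minimum relative inter-onset interval: every ISI must be at least this
# fraction of the beat period, so no two stimuli appear concomitantly.
ISI_FLOOR_FRACTION <- 0.09

#' Generate one beat-discrimination trial sequence
#'
#' A trial is a timestamped list of stimulus events: three reference stimuli
#' establishing the beat (onsets 0, T, 2T for beat period T), at least four
#' on-beat targets, off-beat distractors placed at random between the first
#' target and the final event, and a single closing deviant judged on- versus
#' off-beat. Distractor placement respects a hard inter-onset floor of 9% of
#' the beat period. An off-beat deviant is displaced uniformly within half a
#' beat period of its expected beat, with a minimum displacement equal to the
#' same 9% floor so the judgment stays discriminable in principle.
#'
#' @param beat A [beat_spec()].
#' @param density Expected number of distractors per beat (>= 0); the task's
#'   difficulty knob.
#' @param deviant_on_beat Logical; does the deviant fall exactly on the beat?
#' @param duration_bounds Length-2 numeric, soft bounds (seconds) on trial
#'   duration; defaults to c(2, 12) for auditory, c(2, 20) for visual trials.
#'   The lower bound and the minimum of four targets are hard constraints;
#'   when the minimum target count alone exceeds the upper bound (very slow
#'   tempi) the target minimum takes precedence.
#' @param modality `"auditory"` or `"visual"` (metadata and default bounds).
#' @param n_targets Optional fixed number of on-beat targets in \[4, 22\];
#'   drawn uniformly from the feasible range when `NULL`.
#' @param seed Optional integer seed; generation is bit-reproducible given
#'   identical parameters and seed.
#' @param max_attempts Rejection-sampling budget per distractor before the
#'   density is declared infeasible.
#' @return An object of class `trial_sequence`: the `beat`, an `events`
#'   data.frame (`onset`, `role`, `duration`), `density`, `deviant_on_beat`,
#'   `deviant_offset` (seconds, signed, 0 when on-beat), `n_targets` and
#'   `modality`.
#' @examples
#' tr <- generate_trial(beat_spec(1), density = 1, deviant_on_beat = FALSE,
#'                      seed = 1)
#' validate_sequence(tr)   # empty: the sequence satisfies all constraints
#' @export
generate_trial <- function(beat, density, deviant_on_beat,
                           duration_bounds = NULL,
                           modality = c("auditory", "visual"),
                           n_targets = NULL,
                           seed = NULL,
                           max_attempts = 1000L) {
  modality <- match.arg(modality)
  if (!inherits(beat, "beat_spec")) beat <- beat_spec(beat)
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density < 0) {
    stop_invalid("density must be a single non-negative number")
  }
  if (!is.logical(deviant_on_beat) || length(deviant_on_beat) != 1L ||
      is.na(deviant_on_beat)) {
    stop_invalid("deviant_on_beat must be TRUE or FALSE")
  }
  if (is.null(duration_bounds)) duration_bounds <- default_duration_bounds(modality)
  if (length(duration_bounds) != 2L || any(!is.finite(duration_bounds)) ||
      duration_bounds[1] < 0 || diff(duration_bounds) <= 0) {
    stop_invalid("duration_bounds must be an increasing pair of seconds")
  }

  T <- beat$period
  floor_isi <- ISI_FLOOR_FRACTION * T

  # Feasible target counts: the deviant's expected beat sits at (3 + n) * T.
  # The >= 2 s duration floor must hold even for the earliest off-beat
  # deviant (offset -T/2); the upper duration bound caps n softly.
  n_min <- max(4L, as.integer(ceiling((duration_bounds[1] + 0.5 * T) / T - 3)))
  n_max <- max(n_min, min(22L, as.integer(floor(duration_bounds[2] / T - 3))))
  if (n_min > 22L) {
    stop_infeasible("duration lower bound requires more than 22 targets at ",
                    beat$frequency, " Hz")
  }

  with_seed(seed, {
    n <- if (is.null(n_targets)) {
      if (n_min == n_max) n_min else
        sample(seq.int(n_min, n_max), 1L)
    } else {
      if (!is_count(n_targets) || n_targets < 4 || n_targets > 22) {
        stop_invalid("n_targets must be an integer in [4, 22]")
      }
      as.integer(n_targets)
    }

    ref_onsets <- c(0, T, 2 * T)
    target_onsets <- (3:(2 + n)) * T

    if (deviant_on_beat) {
      offset <- 0
    } else {
      repeat {
        offset <- stats::runif(1, -T / 2, T / 2)
        if (abs(offset) >= floor_isi) break
      }
    }
    deviant_onset <- (3 + n) * T + offset

    # Independent uniform placement over the span from the first target to
    # the deviant; each distractor is redrawn until it clears the inter-onset
    # floor against every event already placed.
    n_beats <- n
    n_distractors <- stats::rpois(1, density * n_beats)
    fixed_onsets <- c(ref_onsets, target_onsets, deviant_onset)
    span <- c(3 * T, deviant_onset)
    distractor_onsets <- numeric(0)
    for (k in seq_len(n_distractors)) {
      placed <- FALSE
      occupied <- c(fixed_onsets, distractor_onsets)
      for (a in seq_len(max_attempts)) {
        cand <- stats::runif(1, span[1], span[2])
        if (min(abs(occupied - cand)) >= floor_isi) {
          distractor_onsets <- c(distractor_onsets, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop_infeasible(
          "cannot place distractor ", k, " of ", n_distractors,
          " without violating the minimum inter-onset interval (",
          signif(floor_isi, 3), " s) at density ", density,
          "; binding constraint: ISI floor",
          data = list(density = density, n_targets = n,
                      placed = length(distractor_onsets)))
      }
    }

    events <- data.frame(
      onset = c(ref_onsets, target_onsets, distractor_onsets, deviant_onset),
      role = c(rep("reference", 3L), rep("target", n),
               rep("distractor", length(distractor_onsets)), "deviant"),
      stringsAsFactors = FALSE)
    events <- events[order(events$onset), , drop = FALSE]
    rownames(events) <- NULL
    events$duration <- beat$stimulus_duration

    structure(
      list(beat = beat,
           events = events,
           density = density,
           deviant_on_beat = deviant_on_beat,
           deviant_offset = offset,
           n_targets = n,
           modality = modality,
           seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
      class = "trial_sequence")
  })
}

#' Check a trial sequence against the paradigm's structural constraints
#'
#' Verifies every rule a generated sequence must satisfy: strictly increasing
#' onsets; three opening references on the beat grid; a unique, final deviant;
#' 4--22 targets; the 9%-of-period inter-onset floor on every interval; a
#' total duration of at least 2 s; and the off-beat deviant displacement
#' window.
#'
#' @param seq A `trial_sequence`.
#' @return A data.frame of violations with columns `rule`, `detail` and
#'   `indices` (comma-separated offending event indices); zero rows iff the
#'   sequence is valid.
#' @export
validate_sequence <- function(seq) {
  if (!inherits(seq, "trial_sequence")) {
    stop_invalid("validate_sequence expects a trial_sequence")
  }
  ev <- seq$events
  T <- seq$beat$period
  floor_isi <- ISI_FLOOR_FRACTION * T
  bad <- list()
  flag <- function(rule, detail, idx = integer(0)) {
    bad[[length(bad) + 1L]] <<- data.frame(
      rule = rule, detail = detail,
      indices = paste(idx, collapse = ","), stringsAsFactors = FALSE)
  }

  n_ev <- nrow(ev)
  if (n_ev < 5L) flag("event_count", "fewer than 3 references + 1 target + deviant")
  d_onset <- diff(ev$onset)
  if (any(d_onset <= 0)) {
    flag("onsets_increasing", "onsets not strictly increasing",
         which(d_onset <= 0) + 1L)
  }
  if (any(ev$onset < 0)) flag("onset_nonnegative", "negative onset", which(ev$onset < 0))
  if (any(ev$duration <= 0)) flag("duration_positive", "non-positive duration",
                                  which(ev$duration <= 0))

  ref_idx <- seq_len(min(3L, n_ev))
  expected_ref <- (ref_idx - 1L) * T
  if (!all(ev$role[ref_idx] == "reference") ||
      any(abs(ev$onset[ref_idx] - expected_ref) > 1e-9)) {
    flag("reference_grid", "first three events must be references at 0, T, 2T",
         ref_idx)
  }
  dev_idx <- which(ev$role == "deviant")
  if (length(dev_idx) != 1L || dev_idx != n_ev) {
    flag("deviant_last", "sequence must end with a unique deviant", dev_idx)
  }
  n_targets <- sum(ev$role == "target")
  if (n_targets < 4L || n_targets > 22L) {
    flag("target_count", sprintf("%d targets outside [4, 22]", n_targets))
  }
  isi_bad <- which(d_onset < floor_isi)
  if (length(isi_bad)) {
    flag("isi_floor", sprintf("inter-onset interval below %.4g s", floor_isi),
         c(isi_bad, isi_bad + 1L))
  }
  total <- ev$onset[n_ev] + ev$duration[n_ev]
  if (length(total) && total < 2) flag("min_duration", "trial shorter than 2 s")

  if (seq$deviant_on_beat) {
    if (seq$deviant_offset != 0) flag("deviant_offset", "on-beat deviant with nonzero offset")
  } else {
    a <- abs(seq$deviant_offset)
    if (a < floor_isi || a > T / 2) {
      flag("deviant_offset",
           sprintf("off-beat offset %.4g s outside [%.4g, %.4g]",
                   seq$deviant_offset, floor_isi, T / 2))
    }
  }
  if (seq$density < 0) flag("density_nonnegative", "negative density")

  if (length(bad)) do.call(rbind, bad) else
    data.frame(rule = character(0), detail = character(0),
               indices = character(0), stringsAsFactors = FALSE)
}

#' Beat-frequency condition presets
#'
#' The tempo sets used in the auditory and visual beat-discrimination
#' experiments: eight auditory tempi spanning 0.6--3.8 Hz, and visual variants
#' with ten (adding 0.3 and 0.4 Hz, where visual attention samples more
#' slowly) or eight conditions.
#'
#' @param preset One of `"auditory_8"`, `"visual_10"`, `"visual_8"`.
#' @return Numeric vector of beat frequencies in Hz, strictly increasing.
#' @examples
#' condition_set("auditory_8")
#' @export
condition_set <- function(preset) {
  sets <- list(
    auditory_8 = c(0.6, 0.7, 1, 1.3, 1.7, 2.2, 2.9, 3.8),
    visual_10  = c(0.3, 0.4, 0.6, 0.7, 1, 1.3, 1.7, 2.2, 2.9, 3.8),
    visual_8   = c(0.4, 0.7, 1, 1.3, 1.7, 2.2, 2.9, 3.8))
  if (!is.character(preset) || length(preset) != 1L || !preset %in% names(sets)) {
    stop_invalid("unknown condition preset: ", paste(preset, collapse = ", "),
                 " (expected auditory_8, visual_10 or visual_8)")
  }
  sets[[preset]]
}

#' Initialise the state of the distractor-density staircase
#'
#' A weighted up-down staircase (Kaernbach-style): a correct response raises
#' the density by `step_up` (harder), an error lowers it by `step_down`
#' (easier). At equilibrium the expected drift is zero, which pins accuracy at
#' `step_down / (step_up + step_down)`; the default 1 : 3 step ratio targets
#' 75% correct. Steps shrink geometrically after each reversal down to
#' `min_step`, so the track tightens around threshold.
#'
#' @param initial_density Starting distractor density.
#' @param step_up Density increment after a correct response.
#' @param step_down Density decrement after an error; defaults to
#'   `step_up * target_accuracy / (1 - target_accuracy)`.
#' @param target_accuracy Accuracy level the staircase converges to.
#' @param shrink Multiplicative step shrinkage applied at each reversal.
#' @param min_step Lower bound on `step_up` after shrinkage.
#' @return An object of class `staircase_state`.
#' @export
staircase_state <- function(initial_density = 0.4,
                            step_up = 0.10,
                            step_down = NULL,
                            target_accuracy = 0.75,
                            shrink = 0.8,
                            min_step = 0.01) {
  if (initial_density < 0) stop_invalid("initial density must be >= 0")
  if (step_up <= 0) stop_invalid("step_up must be positive")
  if (target_accuracy <= 0 || target_accuracy >= 1) {
    stop_invalid("target_accuracy must lie in (0, 1)")
  }
  if (is.null(step_down)) {
    step_down <- step_up * target_accuracy / (1 - target_accuracy)
  }
  if (step_down <= 0) stop_invalid("step_down must be positive")
  if (shrink <= 0 || shrink > 1) stop_invalid("shrink must lie in (0, 1]")
  structure(
    list(current_density = initial_density,
         step_up = step_up, step_down = step_down,
         target_accuracy = target_accuracy,
         shrink = shrink, min_step = min_step,
         reversal_count = 0L,
         history = data.frame(density = numeric(0), correct = logical(0))),
    class = "staircase_state")
}

#' Run the adaptive distractor-density staircase
#'
#' Titrates the distractor density at a fixed 2 Hz beat so the responder's
#' accuracy converges on the staircase's target level (default 75%). Each
#' trial a fresh sequence is generated at the current density (on-/off-beat
#' deviant balanced at random), the responder judges it, and the density
#' moves up on a correct response and down on an error with the weighted
#' step sizes held in `state`.
#'
#' @param responder A function taking a `trial_sequence` and returning TRUE
#'   (correct) or FALSE. Should be deterministic or internally seeded if
#'   exact reproducibility is required beyond `seed`.
#' @param beat A [beat_spec()]; default 2 Hz as used for titration.
#' @param state A [staircase_state()].
#' @param max_trials Maximum staircase trials.
#' @param n_reversals_avg Number of final reversals whose densities are
#'   averaged into the converged estimate (fewer are used if fewer occurred).
#' @param seed Optional integer seed for sequence generation and deviant
#'   randomisation.
#' @param modality Passed to [generate_trial()].
#' @return A list of class `staircase_result`: `density` (converged
#'   estimate), `reversal_densities`, `trajectory` (per-trial density and
#'   response) and the final `state`.
#' @export
run_staircase <- function(responder,
                          beat = beat_spec(2),
                          state = staircase_state(),
                          max_trials = 200L,
                          n_reversals_avg = 6L,
                          seed = NULL,
                          modality = "auditory") {
  if (!is.function(responder)) stop_invalid("responder must be a function")
  if (!is_count(max_trials)) stop_invalid("max_trials must be a positive integer")
  with_seed(seed, {
    density <- state$current_density
    step_up <- state$step_up
    step_down <- state$step_down
    ratio <- step_down / step_up
    traj <- data.frame(trial = integer(0), density = numeric(0),
                       correct = logical(0))
    last_dir <- 0L
    reversal_densities <- numeric(0)
    for (i in seq_len(max_trials)) {
      seq_i <- generate_trial(beat, density,
                              deviant_on_beat = stats::runif(1) < 0.5,
                              modality = modality)
      correct <- isTRUE(responder(seq_i))
      traj <- rbind(traj, data.frame(trial = i, density = density,
                                     correct = correct))
      dir <- if (correct) 1L else -1L
      if (last_dir != 0L && dir != last_dir) {
        reversal_densities <- c(reversal_densities, density)
        step_up <- max(state$min_step, step_up * state$shrink)
        step_down <- step_up * ratio
      }
      last_dir <- dir
      density <- max(0, density + if (correct) step_up else -step_down)
    }
    if (length(reversal_densities) == 0L) {
      stop(errorCondition(
        "staircase did not reverse before max_trials",
        class = c("beatattn_nonconvergence", "error"),
        data = list(trajectory = traj)))
    }
    k <- min(n_reversals_avg, length(reversal_densities))
    est <- mean(utils::tail(reversal_densities, k))
    structure(list(density = est,
                   reversal_densities = reversal_densities,
                   trajectory = traj),
              class = "staircase_result")
  })
}

#' Flatten trial sequences into a tidy per-event table
#'
#' @param sequences A list of `trial_sequence` objects (or a single one).
#' @return A data.frame with one row per stimulus event: `trial_id`,
#'   `condition_hz`, `event_index`, `onset_s`, `role`, `duration_s`,
#'   `deviant_on_beat`, `deviant_offset_s`, `density`, `modality`, `seed`.
#' @export
trial_events_table <- function(sequences) {
  if (inherits(sequences, "trial_sequence")) sequences <- list(sequences)
  rows <- lapply(seq_along(sequences), function(i) {
    s <- sequences[[i]]
    ev <- s$events
    data.frame(trial_id = i,
               condition_hz = s$beat$frequency,
               event_index = seq_len(nrow(ev)),
               onset_s = ev$onset,
               role = ev$role,
               duration_s = ev$duration,
               deviant_on_beat = s$deviant_on_beat,
               deviant_offset_s = s$deviant_offset,
               density = s$density,
               modality = s$modality,
               seed = s$seed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write trial sequences to CSV (one row per event)
#'
#' @inheritParams trial_events_table
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_events <- function(sequences, path) {
  utils::write.csv(trial_events_table(sequences), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat(sprintf("<trial_sequence> %.3g Hz %s, %d events (%d targets, %d distractors), deviant %s\n",
              x$beat$frequency, x$modality, nrow(x$events), x$n_targets,
              sum(x$events$role == "distractor"),
              if (x$deviant_on_beat) "on-beat"
              else sprintf("off-beat (%+.3f s)", x$deviant_offset)))
  invisible(x)
}
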
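# Beat-discrimination sequence generation, validation and the staircase.

test_that("beat_spec enforces its invariants and duration rules", {
  b <- beat_spec(1.3)
  expect_equal(b$period * b$frequency, 1, tolerance = 1e-12)
  expect_equal(b$stimulus_duration, 0.10 / 1.3)
  expect_equal(beat_spec(2, fraction = 0.18)$stimulus_duration, 0.09)
  expect_equal(beat_spec(3.8, "fixed")$stimulus_duration, 0.0225)
  expect_error(beat_spec(0), class = "beatattn_invalid_parameter")
  expect_error(beat_spec(-1), class = "beatattn_invalid_parameter")
  expect_error(beat_spec(1, fraction = 1.2), class = "beatattn_invalid_parameter")
})

test_that("zero-density trial is a pure isochronous grid", {
  tr <- generate_trial(beat_spec(1), density = 0, deviant_on_beat = TRUE,
                       n_targets = 8, seed = 11)
  expect_equal(nrow(tr$events), 3 + 8 + 1)
  expect_equal(tr$events$onset, 0:11)
  expect_true(all(diff(tr$events$onset) == 1))
  expect_false(any(tr$events$role == "distractor"))
  expect_equal(nrow(validate_sequence(tr)), 0)
})

test_that("minimum-target trial spans at least 6 s at 1 Hz with deviant after", {
  tr <- generate_trial(beat_spec(1), density = 0.5, deviant_on_beat = FALSE,
                       n_targets = 4, seed = 3)
  last_target <- max(tr$events$onset[tr$events$role == "target"])
  expect_gte(last_target, 6)
  dev_onset <- tr$events$onset[tr$events$role == "deviant"]
  expect_gt(dev_onset, last_target)
  expect_gte(dev_onset + tr$events$duration[nrow(tr$events)], 2)
  expect_equal(nrow(validate_sequence(tr)), 0)
})

test_that("invalid generation parameters raise classed errors", {
  expect_error(generate_trial(beat_spec(1), density = -0.1, deviant_on_beat = TRUE),
               class = "beatattn_invalid_parameter")
  expect_error(generate_trial(0, density = 1, deviant_on_beat = TRUE),
               class = "beatattn_invalid_parameter")
  # a density this extreme cannot respect the inter-onset floor
  expect_error(
    generate_trial(beat_spec(1), density = 50, deviant_on_beat = TRUE,
                   seed = 1, max_attempts = 50),
    class = "beatattn_infeasible")
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- generate_trial(beat_spec(1.7), 1.2, FALSE, seed = 99)
  b <- generate_trial(beat_spec(1.7), 1.2, FALSE, seed = 99)
  expect_identical(a, b)
  c <- generate_trial(beat_spec(1.7), 1.2, FALSE, seed = 100)
  expect_false(identical(a$events, c$events))
})

test_that("validator flags planted violations with the offending rule", {
  tr <- generate_trial(beat_spec(1), 1, TRUE, seed = 5)
  # two events 0.05 T apart
  bad <- tr
  i <- which(bad$events$role == "target")[2]
  bad$events$onset[i] <- bad$events$onset[i - 1] + 0.05
  bad$events <- bad$events[order(bad$events$onset), ]
  v <- validate_sequence(bad)
  expect_true("isi_floor" %in% v$rule)
  # deviant not last
  bad2 <- tr
  bad2$events$role[nrow(bad2$events)] <- "distractor"
  bad2$events$role[i] <- "deviant"
  v2 <- validate_sequence(bad2)
  expect_true("deviant_last" %in% v2$rule)
  # broken reference grid
  bad3 <- tr
  bad3$events$onset[2] <- bad3$events$onset[2] + 1e-6
  v3 <- validate_sequence(bad3)
  expect_true("reference_grid" %in% v3$rule)
})

test_that("every generated sequence passes the validator across a grid", {
  for (f in c(0.3, 0.6, 1, 1.7, 3.8)) {
    for (d in c(0, 0.5, 1.5)) {
      for (s in 1:5) {
        tr <- generate_trial(beat_spec(f), d, s %% 2 == 0,
                             modality = if (f < 0.5) "visual" else "auditory",
                             seed = s)
        v <- validate_sequence(tr)
        expect_equal(nrow(v), 0,
                     info = sprintf("f=%g d=%g seed=%d: %s", f, d, s,
                                    paste(v$rule, collapse = ",")))
        isi <- diff(tr$events$onset)
        expect_true(all(isi >= 0.09 / f))
      }
    }
  }
})

test_that("realised distractor counts match density x beats on average", {
  d <- 1.2
  n_rep <- 1000
  counts <- vapply(seq_len(n_rep), function(s) {
    tr <- generate_trial(beat_spec(1.3), d, TRUE, n_targets = 10, seed = s)
    sum(tr$events$role == "distractor")
  }, 0)
  expected <- d * 10
  se <- sqrt(expected / n_rep)   # Poisson counts
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("condition presets return the exact published tempo sets", {
  expect_equal(condition_set("auditory_8"),
               c(0.6, 0.7, 1, 1.3, 1.7, 2.2, 2.9, 3.8))
  v10 <- condition_set("visual_10")
  expect_length(v10, 10)
  expect_true(all(c(0.3, 0.4) %in% v10))
  expect_equal(v10, c(0.3, 0.4, 0.6, 0.7, 1, 1.3, 1.7, 2.2, 2.9, 3.8))
  expect_equal(condition_set("visual_8"),
               c(0.4, 0.7, 1, 1.3, 1.7, 2.2, 2.9, 3.8))
  expect_error(condition_set("visual_12"), class = "beatattn_invalid_parameter")
})

test_that("staircase drifts to the ceiling for an always-correct responder", {
  err <- tryCatch(
    run_staircase(function(seq) TRUE, max_trials = 50, seed = 1),
    error = function(e) e)
  # monotone climb, no reversal: non-convergence carrying the trajectory
  expect_s3_class(err, "beatattn_nonconvergence")
  traj <- err$data$trajectory
  expect_true(all(diff(traj$density) > 0))
})

test_that("staircase hits the zero floor for an always-wrong responder", {
  err <- tryCatch(
    run_staircase(function(seq) FALSE, max_trials = 50, seed = 1),
    error = function(e) e)
  expect_s3_class(err, "beatattn_nonconvergence")
  expect_equal(min(err$data$trajectory$density), 0)
})

test_that("staircase converges near the 75%-accuracy density of a known observer", {
  obs <- observer_params(lapse_rate = 0)
  target_density <- density_for_accuracy(2, obs, target = 0.75)
  set.seed(42)
  res <- run_staircase(function(sq) runif(1) < accuracy_model(2, sq$density, obs),
                       state = staircase_state(initial_density = 0.4,
                                               step_up = 0.08),
                       max_trials = 400, seed = NULL)
  expect_lt(abs(res$density - target_density) / target_density, 0.15)
})

test_that("trial event tables round-trip through CSV with the full schema", {
  trs <- list(generate_trial(beat_spec(1), 1, TRUE, seed = 1),
              generate_trial(beat_spec(2), 0.5, FALSE, seed = 2))
  tab <- trial_events_table(trs)
  expect_setequal(names(tab),
                  c("trial_id", "condition_hz", "event_index", "onset_s",
                    "role", "duration_s", "deviant_on_beat",
                    "deviant_offset_s", "density", "modality", "seed"))
  f <- tempfile(fileext = ".csv")
  write_trial_events(trs, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$onset_s, tab$onset_s)
  unlink(f)
})
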
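# Behavioural estimators: curves, cubic optimum, tapping metrics, splits, BF.

test_that("performance_curve computes exact proportions with trial counts", {
  tr <- data.frame(condition_hz = c(1, 1, 1, 1, 2, 2),
                   response_correct = c(1, 1, 1, 0, 1, 1))
  pc <- performance_curve(tr)
  expect_equal(pc$prop_correct, c(0.75, 1))
  expect_equal(pc$n, c(4L, 2L))
  expect_true(all(diff(pc$condition_hz) > 0))
  expect_error(performance_curve(tr, conditions = c(1, 2, 3)),
               class = "beatattn_invalid_parameter")
  expect_error(performance_curve(tr[0, ]), class = "beatattn_invalid_parameter")
})

test_that("cubic fit recovers exact polynomials and their local maximum", {
  x <- c(-2, -1, 0, 1, 2)
  fit <- fit_cubic_optimal_tempo(x, -x^3 + 3 * x)
  expect_equal(c(fit$a, fit$b, fit$c, fit$d), c(-1, 0, 3, 0), tolerance = 1e-9)
  expect_equal(fit$delta, 9, tolerance = 1e-8)
  expect_equal(fit$alpha, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  x2 <- c(0, 1, 2, 3, 4)
  fit2 <- fit_cubic_optimal_tempo(x2, x2^3 - 6 * x2^2 + 9 * x2)
  expect_equal(fit2$alpha, 1, tolerance = 1e-9)   # max of the two critical points
  expect_equal(fit2$beta, 3, tolerance = 1e-9)
})

test_that("alpha always matches the dense-grid argmax of the fitted cubic", {
  set.seed(101)
  freqs <- c(0.3, 0.4, 0.6, 0.7, 1, 1.3, 1.7, 2.2, 2.9, 3.8)
  grid <- seq(min(freqs), max(freqs), length.out = 1e5)
  checked <- 0
  for (i in 1:200) {
    fit <- fit_cubic_optimal_tempo(freqs, runif(10))
    if (fit$has_optimum && isTRUE(fit$alpha_in_range)) {
      argmax <- grid[which.max(predict_cubic(fit, grid))]
      # grid argmax can sit at an endpoint when the boundary beats the
      # interior maximum; restrict to interior maxima
      if (argmax > min(freqs) && argmax < max(freqs)) {
        expect_lt(abs(fit$alpha - argmax), diff(grid[1:2]) + 1e-12)
        checked <- checked + 1
      }
    }
  }
  expect_gt(checked, 20)
})

test_that("straight-line data yield a no-optimum signal, not an error", {
  x <- c(1, 2, 3, 4, 5)
  fit <- fit_cubic_optimal_tempo(x, 2 * x + 1)
  expect_false(fit$has_optimum)
  expect_true(is.na(fit$alpha))
  expect_error(fit_cubic_optimal_tempo(c(1, 2, 3), c(1, 2, 3)),
               class = "beatattn_invalid_parameter")
})

test_that("log-axis fitting maps the optimum back to Hz", {
  f <- c(0.5, 1, 2, 4, 8)
  u <- log2(f)
  vals <- -u^3 + 3 * u              # local max at u = 1, i.e. 2 Hz
  fit <- fit_cubic_optimal_tempo(f, vals, log_axis = TRUE)
  expect_true(fit$has_optimum)
  expect_equal(fit$alpha, 2, tolerance = 1e-9)
})

test_that("tapping precision is the tap-rate-to-tempo ratio in percent", {
  expect_equal(tapping_precision(c(0, 1, 2, 3), period = 1), 100)
  expect_equal(tapping_precision(c(0, 0.5, 1), period = 1), 200)
  expect_error(tapping_precision(c(0), period = 1),
               class = "beatattn_invalid_parameter")
})

test_that("tapping CV uses the sample SD of intervals over the period", {
  expect_equal(tapping_cv(c(0, 1, 2, 3, 4), period = 1), 0)
  # ITIs {0.9, 1.1}: two-sample SD = sqrt(0.02)
  expect_equal(tapping_cv(c(0, 0.9, 2), period = 1), sqrt(0.02),
               tolerance = 1e-12)
  expect_error(tapping_cv(c(0, 1), period = 1),
               class = "beatattn_invalid_parameter")
})

test_that("CV is translation invariant and scales as 1/T under dilation", {
  set.seed(7)
  taps <- cumsum(abs(rnorm(30, 1, 0.1)))
  expect_equal(tapping_cv(taps, 1), tapping_cv(taps + 100, 1))
  # dilating both taps and period by s leaves CV unchanged;
  # dilating taps only scales CV by s
  s <- 3
  expect_equal(tapping_cv(taps * s, s), tapping_cv(taps, 1))
  expect_equal(tapping_cv(taps * s, 1), s * tapping_cv(taps, 1))
})

test_that("tap-beat phase matches the brute-force nearest-beat oracle", {
  period <- 1
  beats <- 0:10
  expect_equal(sensorimotor_simultaneity(5, beats, period)$phi_signed, 0)
  expect_equal(sensorimotor_simultaneity(5.25, beats, period)$phi_signed,
               pi / 2)
  # 3T/4 after beat 5: nearest beat is 6, phi = -pi/2
  res <- sensorimotor_simultaneity(5.75, beats, period)
  expect_equal(res$nearest_beat, 7L)       # index into beats (beat time 6)
  expect_equal(res$phi_signed, -pi / 2)
  set.seed(21)
  taps <- runif(200, 0, 10)
  got <- sensorimotor_simultaneity(taps, beats, period)$phi
  want <- vapply(taps, phi_bruteforce, 0, beats = beats, period = period)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("phi is invariant to shifting taps by whole periods", {
  period <- 0.5
  beats <- seq(0, 20, by = period)
  set.seed(3)
  taps <- runif(50, 2, 8)
  a <- sensorimotor_simultaneity(taps, beats, period)$phi
  b <- sensorimotor_simultaneity(taps + 4 * period, beats, period)$phi
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("median split obeys the stated odd/even and tie rules", {
  df <- data.frame(k = c(1, 2, 3, 4))
  sp <- median_split(df, "k")
  expect_equal(sp$low$k, c(1, 2))
  expect_equal(sp$high$k, c(3, 4))
  sp3 <- median_split(data.frame(k = c(1, 2, 3)), "k")
  expect_equal(sp3$low$k, c(1, 2))   # median joins the low group
  expect_equal(sp3$high$k, 3)
  expect_error(median_split(data.frame(k = rep(5, 4)), "k"),
               class = "beatattn_degenerate")
})

test_that("AIC Bayes factor follows the closed form and the 1/3 criterion", {
  expect_equal(bayes_factor_aic(100, 100)$bf, 1)
  b2 <- bayes_factor_aic(100, 102)
  expect_equal(b2$bf, exp(-1), tolerance = 1e-12)
  expect_false(b2$evidence_for_null)     # 0.3679 is not below 1/3
  b4 <- bayes_factor_aic(100, 104)
  expect_equal(b4$bf, exp(-2), tolerance = 1e-12)
  expect_true(b4$evidence_for_null)
  expect_error(bayes_factor_aic(NA, 1), class = "beatattn_invalid_parameter")
})
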
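# Three-oscillator model: integrator, PLV, presets, sweeps, behaviour fit.

test_that("uncoupled noiseless oscillators rotate freely at their natural rates", {
  p <- noiseless(omega_s = 1, omega_a = 1.5, omega_m = 1.7, k_as = 0,
                 tau_as = 0, duration = 10, burn_in = 0)
  tr <- simulate_model(p, seed = 1)
  dt <- p$dt
  expect_equal(diff(tr$theta_s), rep(2 * pi * 1.0 * dt, length(tr$time) - 1),
               tolerance = 1e-9)
  expect_equal(diff(tr$theta_a), rep(2 * pi * 1.5 * dt, length(tr$time) - 1),
               tolerance = 1e-9)
  expect_equal(diff(tr$theta_m), rep(2 * pi * 1.7 * dt, length(tr$time) - 1),
               tolerance = 1e-9)
})

test_that("stimulus phase is exactly linear even in a noisy coupled run", {
  p <- preset("auditory", "tracking", omega_s = 1.3, duration = 50, burn_in = 0)
  tr <- simulate_model(p, seed = 2)
  expect_equal(tr$theta_s, tr$theta_s[1] + 2 * pi * 1.3 * tr$time,
               tolerance = 1e-9)
})

test_that("a sine-coupled pair locks iff |2 pi dOmega| < K (noise-free)", {
  # |2*pi*0.1| = 0.63 < K = 2: locked
  locked <- noiseless(omega_s = 1.5, omega_a = 1.4, k_as = 2, tau_as = 0,
                      duration = 300, burn_in = 100)
  expect_equal(trace_plv(simulate_model(locked, seed = 3)), 1,
               tolerance = 1e-6)
  # |2*pi*0.5| = 3.14 > K = 2: phase slips
  slipping <- noiseless(omega_s = 1.5, omega_a = 1.0, k_as = 2, tau_as = 0,
                        duration = 1100, burn_in = 100)
  expect_lt(trace_plv(simulate_model(slipping, seed = 3)), 0.9)
})

test_that("plv matches direct complex-mean modulus and its invariances", {
  expect_equal(plv(rep(1.3, 50), rep(0.9, 50)), 1, tolerance = 1e-12)
  expect_equal(plv(c(0, pi / 2, pi, 3 * pi / 2), rep(0, 4)), 0,
               tolerance = 1e-12)
  expect_equal(plv(c(0, 0, pi / 2), c(0, 0, 0)), sqrt(5) / 3,
               tolerance = 1e-12)
  set.seed(4)
  x <- cumsum(rnorm(500)); y <- cumsum(rnorm(500))
  direct <- Mod(mean(exp(1i * (x - y))))
  expect_equal(plv(x, y), direct, tolerance = 1e-12)
  expect_equal(plv(x, y), plv(y, x))
  expect_equal(plv(x + 0.7, y + 0.7), plv(x, y), tolerance = 1e-12)
  expect_true(plv(x, y) >= 0 && plv(x, y) <= 1)
  expect_error(plv(x, y[-1]), class = "beatattn_invalid_parameter")
  expect_error(plv(numeric(0), numeric(0)), class = "beatattn_invalid_parameter")
})

test_that("identical-frequency uncoupled pair stays at PLV 1; detuned pair decays", {
  base <- noiseless(omega_s = 1.2, omega_a = 1.2, k_as = 0, burn_in = 0)
  for (dur in c(10, 100, 1000)) {
    b <- base; b$duration <- dur
    expect_equal(trace_plv(simulate_model(b, seed = 5)), 1, tolerance = 1e-9)
  }
  # incommensurate frequencies: PLV decays toward 0 as duration grows
  det <- noiseless(omega_s = 1.2, omega_a = 1.2 + sqrt(2) / 10, k_as = 0,
                   burn_in = 0)
  plvs <- vapply(c(10, 100, 1000), function(dur) {
    d <- det; d$duration <- dur
    trace_plv(simulate_model(d, seed = 5))
  }, 0)
  expect_true(all(diff(plvs) < 0))
  expect_lt(plvs[3], 0.05)
})

test_that("presets carry the published parameter values", {
  at <- preset("auditory", "tracking")
  expect_equal(at$k_am, 10)
  expect_equal(at$k_ma, 10)
  expect_equal(at$k_as, 10)
  expect_equal(at$k_ms, 8)
  expect_equal(at$tau_ms, 0.1)
  expect_equal(at$tau_as, 0.1)
  expect_equal(at$omega_a, 1.5)
  expect_equal(at$omega_m, 1.7)
  expect_equal(at$d_a, 5)
  expect_equal(at$d_m, 10)
  expect_equal(at$dt, 0.025)
  expect_equal(at$duration, 1e4)

  vp <- preset("visual", "passive")
  expect_equal(vp$omega_a, 0.7)
  expect_equal(vp$tau_ms, 0.35)
  expect_equal(vp$k_am, 2)
  expect_equal(vp$tau_am, 0)
  expect_equal(vp$tau_ma, 0)

  ap <- preset("auditory", "passive")
  differing <- names(at)[!mapply(identical, at, ap)]
  expect_equal(differing, "k_am")   # the only session-varying parameter
  expect_error(preset("tactile"), "arg")
})

test_that("frequency sweeps are deterministic and shaped as requested", {
  p <- preset("auditory", "passive", duration = 120)
  freqs <- c(0.6, 1, 1.7, 2.9, 3.8)
  sw1 <- frequency_sweep(p, freqs, n_realizations = 5, base_seed = 10)
  sw2 <- frequency_sweep(p, freqs, n_realizations = 5, base_seed = 10)
  expect_equal(nrow(sw1), 5)
  expect_equal(unique(sw1$n), 5)
  expect_equal(nrow(attr(sw1, "runs")), 25)
  expect_identical(as.data.frame(sw1), as.data.frame(sw2))
  expect_true(all(sw1$plv_mean >= 0 & sw1$plv_mean <= 1))
  expect_error(frequency_sweep(p, numeric(0)), class = "beatattn_invalid_parameter")
})

test_that("resonant noise-free preset locks near-perfectly", {
  p <- preset("auditory", "passive", omega_s = 1.5, duration = 300,
              d_a = 0, d_m = 0)
  sw <- frequency_sweep(p, 1.5, n_realizations = 2, base_seed = 6)
  expect_gte(sw$plv_mean, 0.99)
})

test_that("mean rotation frequency reads the unwrapped phase slope", {
  t <- seq(0, 100, by = 0.025)
  expect_equal(mean_rotation_frequency(2 * pi * 1.7 * t, 0.025), 1.7,
               tolerance = 1e-12)
  expect_equal(mean_rotation_frequency(rep(2.2, 100), 0.025), 0)
  expect_error(mean_rotation_frequency(1.0, 0.025),
               class = "beatattn_invalid_parameter")
  # noisy free rotation: endpoint diffusion bound
  d_m <- 10; total <- 1e4
  p <- model_params(k_as = 0, k_am = 0, k_ma = 0, k_ms = 0,
                    d_a = 0, d_m = d_m, duration = total, burn_in = 0)
  tr <- simulate_model(p, seed = 8)
  est <- mean_rotation_frequency(tr$theta_m, p$dt)
  expect_lt(abs(est - p$omega_m), 3 * sqrt(2 * d_m / total) / (2 * pi))
})

test_that("halving dt barely changes the PLV of a noiseless locked pair", {
  p1 <- noiseless(omega_s = 1.5, omega_a = 1.4, k_as = 5, duration = 300,
                  burn_in = 100)
  p2 <- p1; p2$dt <- p1$dt / 2
  v1 <- trace_plv(simulate_model(p1, seed = 9))
  v2 <- trace_plv(simulate_model(p2, seed = 9))
  expect_lt(abs(v1 - v2), 1e-3)
})

test_that("behaviour fit returns R^2 of the affine PLV-to-performance map", {
  sw <- data.frame(stim_freq_hz = c(0.6, 1, 1.7, 2.9),
                   plv_mean = c(0.4, 0.6, 0.7, 0.3))
  perf <- data.frame(condition_hz = c(0.6, 1, 1.7, 2.9),
                     prop_correct = 0.5 + 0.4 * sw$plv_mean)
  fit <- fit_to_behavior(sw, perf)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 0.4, tolerance = 1e-12)
  # constant PLV: undefined fit
  swc <- data.frame(stim_freq_hz = sw$stim_freq_hz, plv_mean = 0.5)
  expect_warning(res <- fit_to_behavior(swc, perf),
                 class = "beatattn_undefined_fit")
  expect_true(is.na(res$r_squared))
  # mismatched grids
  bad <- perf; bad$condition_hz[1] <- 0.7
  expect_error(fit_to_behavior(sw, bad), class = "beatattn_invalid_parameter")
})

test_that("R^2 of unrelated random curves averages 1/(n-1)", {
  set.seed(11)
  n <- 8
  r2 <- replicate(1000, {
    sw <- data.frame(stim_freq_hz = 1:n, plv_mean = rnorm(n))
    perf <- data.frame(condition_hz = 1:n, prop_correct = rnorm(n))
    fit_to_behavior(sw, perf)$r_squared
  })
  # R^2 ~ Beta(1/2, (n-2)/2): mean 1/(n-1), sd ~ 0.165
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 3 * 0.165 / sqrt(1000))
})
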
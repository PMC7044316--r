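# Shared fixtures: small deterministic objects used across test files.

quiet_obs <- function(...) {
  # low-noise observer for sharp recovery checks
  args <- list(lapse_rate = 0, tap_jitter_sd = 0, rate_compression = 0,
               mean_asynchrony = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(observer_params, args)
}

# Independent brute-force oracle for tap-beat phase distance: try every beat,
# keep the smallest absolute wrapped phase (sign preserved).
phi_bruteforce <- function(tap, beats, period) {
  phis <- vapply(beats, function(b) {
    d <- 2 * pi * (tap - b) / period
    pi - ((pi - d) %% (2 * pi))
  }, 0)
  phis[which.min(abs(phis))]
}

# Deterministic noiseless model: coupled but noise-free, for locking checks.
noiseless <- function(...) {
  model_params(k_am = 0, k_ma = 0, k_ms = 0, d_a = 0, d_m = 0, ...)
}
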
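# Three-oscillator model of periodic temporal attention: an external periodic
# stimulus S entrains a sensory-specific attention oscillator A, which is
# reciprocally coupled to a motor oscillator M, with delayed sine coupling and
# additive white phase noise. Stimulus-attention phase locking (PLV) stands
# in for behavioural performance.

#' Parameters of the three-oscillator model
#'
#' Phase dynamics, integrated by the Euler-Maruyama scheme:
#' \deqn{\dot\theta_S = \omega_S}
#' \deqn{\dot\theta_A = \omega_A + K_{AM}\sin[\theta_M(t-\tau_{AM})-\theta_A]
#'       + K_{AS}\sin[\theta_S(t-\tau_{AS})-\theta_A] + \xi_A(t)}
#' \deqn{\dot\theta_M = \omega_M + K_{MA}\sin[\theta_A(t-\tau_{MA})-\theta_M]
#'       + K_{MS}\sin[\theta_S(t-\tau_{MS})-\theta_M] + \xi_M(t)}
#' with white Gaussian noise of intensity D,
#' \eqn{\langle\xi_i(t)\xi_j(t')\rangle = 2 D_i \delta(t-t')\delta_{ij}}.
#' Subscript convention: `k_xy`/`tau_xy` is the coupling from source y onto
#' target x (so `k_as` is the stimulus drive on attention).
#'
#' Natural frequencies are entered in Hz and multiplied by 2*pi inside the
#' integrator; K is in rad/s and D in rad^2/s. Delays are rounded internally
#' to whole steps of `dt`.
#'
#' @param omega_s,omega_a,omega_m Natural frequencies in Hz.
#' @param k_as,k_am,k_ma,k_ms Coupling strengths in rad/s (target,source).
#' @param tau_as,tau_am,tau_ma,tau_ms Coupling delays in seconds.
#' @param d_a,d_m Noise intensities in rad^2/s (the stimulus is noiseless).
#' @param dt Integration step, seconds (default 0.025, i.e. 25 ms sampling).
#' @param duration Simulated time, seconds (default 1e4).
#' @param burn_in Initial interval discarded from downstream statistics so
#'   the coupled dynamics reach equilibrium; defaults to 10% of `duration`,
#'   capped at 100 s (so the canonical 1e4 s run discards its first 100 s).
#' @return An object of class `model_params`.
#' @export
model_params <- function(omega_s = 1.0, omega_a = 1.5, omega_m = 1.7,
                         k_as = 10, k_am = 2, k_ma = 10, k_ms = 8,
                         tau_as = 0.1, tau_am = 0, tau_ma = 0, tau_ms = 0.1,
                         d_a = 5, d_m = 10,
                         dt = 0.025, duration = 1e4, burn_in = NULL) {
  if (dt <= 0) stop_invalid("dt must be positive")
  if (is.null(burn_in)) burn_in <- min(100, 0.1 * duration)
  if (burn_in < 0 || duration <= burn_in) {
    stop_invalid("need duration > burn_in >= 0")
  }
  ks <- c(k_as = k_as, k_am = k_am, k_ma = k_ma, k_ms = k_ms)
  taus <- c(tau_as = tau_as, tau_am = tau_am, tau_ma = tau_ma, tau_ms = tau_ms)
  ds <- c(d_a = d_a, d_m = d_m)
  if (any(ks < 0)) stop_invalid("coupling strengths must be >= 0")
  if (any(taus < 0)) stop_invalid("delays must be >= 0")
  if (any(ds < 0)) stop_invalid("noise intensities must be >= 0")
  for (w in c(omega_s, omega_a, omega_m)) {
    if (!is.finite(w)) stop_invalid("natural frequencies must be finite")
  }
  structure(
    list(omega_s = omega_s, omega_a = omega_a, omega_m = omega_m,
         k_as = k_as, k_am = k_am, k_ma = k_ma, k_ms = k_ms,
         tau_as = tau_as, tau_am = tau_am, tau_ma = tau_ma, tau_ms = tau_ms,
         d_a = d_a, d_m = d_m,
         dt = dt, duration = duration, burn_in = burn_in),
    class = "model_params")
}

#' Published parameter presets of the three-oscillator model
#'
#' The attention oscillator's natural frequency and the stimulus-to-motor
#' delay are modality-specific (auditory: 1.5 Hz, 0.1 s; visual: 0.7 Hz,
#' 0.35 s); the motor natural frequency is 1.7 Hz (the spontaneous tapping
#' rate); the motor-onto-attention coupling is the only parameter varying
#' between sessions (2 rad/s passive, 10 rad/s tracking). All other couplings
#' and noise intensities are shared: stimulus->attention 10 rad/s with 0.1 s
#' delay, attention->motor 10 rad/s, stimulus->motor 8 rad/s, internal delays
#' 0, noise 5 (attention) and 10 (motor) rad^2/s.
#'
#' @param modality `"auditory"` or `"visual"`.
#' @param session `"passive"` or `"tracking"`.
#' @param ... Overrides passed to [model_params()] (e.g. `omega_s`,
#'   `duration`).
#' @return A `model_params` object.
#' @examples
#' preset("auditory", "tracking")$k_am   # 10
#' preset("visual", "passive")$tau_ms    # 0.35
#' @export
preset <- function(modality = c("auditory", "visual"),
                   session = c("passive", "tracking"), ...) {
  modality <- match.arg(modality)
  session <- match.arg(session)
  args <- list(
    omega_a = switch(modality, auditory = 1.5, visual = 0.7),
    omega_m = 1.7,
    tau_ms = switch(modality, auditory = 0.1, visual = 0.35),
    k_am = switch(session, passive = 2, tracking = 10),
    k_as = 10, k_ma = 10, k_ms = 8,
    tau_as = 0.1, tau_am = 0, tau_ma = 0,
    d_a = 5, d_m = 10)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_params, args)
}

#' Simulate the three-oscillator model
#'
#' Integrates the stochastic delay-coupled phase equations with the
#' Euler-Maruyama scheme at step `dt`. The stimulus phase is integrated
#' exactly (it is deterministic and uncoupled); delays act through whole-step
#' ring-buffer lookups with pre-history extrapolated backwards at each
#' oscillator's natural frequency from uniformly random initial phases. The
#' run is deterministic given `seed`.
#'
#' @param params A [model_params()] (or [preset()]) object.
#' @param seed Optional integer seed (initial phases and noise).
#' @return An object of class `phase_trace`: `time` (seconds), unwrapped
#'   phases `theta_s`, `theta_a`, `theta_m` (radians), `params`, `retained`
#'   (logical index of post-burn-in samples) and `n_retained`.
#' @export
simulate_model <- function(params, seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  n_steps <- as.integer(round(params$duration / params$dt))
  lag <- function(tau) as.integer(round(tau / params$dt))
  with_seed(seed, {
    th0 <- stats::runif(3, 0, 2 * pi)
    raw <- simulate_phases_cpp(
      params$omega_s, params$omega_a, params$omega_m,
      params$k_as, params$k_am, params$k_ma, params$k_ms,
      lag(params$tau_as), lag(params$tau_am),
      lag(params$tau_ma), lag(params$tau_ms),
      params$d_a, params$d_m,
      params$dt, n_steps,
      th0[1], th0[2], th0[3])
    time <- seq(0, by = params$dt, length.out = n_steps + 1L)
    retained <- time >= params$burn_in
    structure(list(time = time,
                   theta_s = raw$theta_s,
                   theta_a = raw$theta_a,
                   theta_m = raw$theta_m,
                   params = params,
                   retained = retained,
                   n_retained = sum(retained)),
              class = "phase_trace")
  })
}

#' Phase-locking value of two phase series
#'
#' Modulus of the time-averaged unit phasor of the phase difference,
#' \eqn{PLV = |\frac{1}{N}\sum_t e^{i(\theta_x(t) - \theta_y(t))}|}:
#' 1 for a constant phase relation, 0 for a uniformly drifting one. Symmetric
#' in its arguments and invariant to a common constant phase offset.
#'
#' @param theta_x,theta_y Phase series in radians, equal positive length.
#' @return PLV in \[0, 1\].
#' @examples
#' plv(c(0, 0, pi / 2), c(0, 0, 0))  # sqrt(5)/3
#' @export
plv <- function(theta_x, theta_y) {
  if (length(theta_x) != length(theta_y)) {
    stop_invalid("phase series must have equal length")
  }
  if (length(theta_x) == 0L) stop_invalid("empty phase series")
  plv_cpp(as.numeric(theta_x), as.numeric(theta_y))
}

#' Stimulus-attention PLV of a simulated trace (post burn-in)
#'
#' @param trace A `phase_trace`.
#' @param x,y Which oscillators to compare, from `c("s", "a", "m")`.
#' @return PLV in \[0, 1\] over the retained (post-burn-in) samples.
#' @export
trace_plv <- function(trace, x = "s", y = "a") {
  stopifnot(inherits(trace, "phase_trace"))
  pick <- function(w) switch(match.arg(w, c("s", "a", "m")),
                             s = trace$theta_s, a = trace$theta_a,
                             m = trace$theta_m)
  plv(pick(x)[trace$retained], pick(y)[trace$retained])
}

#' Mean rotation frequency of a phase series
#'
#' Slope of the unwrapped phase over the whole series, divided by 2*pi.
#'
#' @param theta Unwrapped phase series in radians (>= 2 samples).
#' @param dt Sampling step in seconds.
#' @return Mean rotation frequency in Hz.
#' @export
mean_rotation_frequency <- function(theta, dt) {
  if (length(theta) < 2L) stop_invalid("need at least 2 samples")
  if (dt <= 0) stop_invalid("dt must be positive")
  span <- (length(theta) - 1L) * dt
  (theta[length(theta)] - theta[1L]) / (2 * pi * span)
}

#' Sweep the stimulus frequency and measure stimulus-attention locking
#'
#' For each stimulus frequency, runs `n_realizations` independent noise
#' realizations of the model and records the mean and SD of the
#' stimulus-attention PLV (post burn-in). Per-run seeds are derived
#' deterministically from `base_seed`.
#'
#' @param params A `model_params` preset; its `omega_s` is overridden per
#'   sweep point.
#' @param stim_freqs Stimulus frequencies in Hz (non-empty).
#' @param n_realizations Independent runs per frequency (>= 1).
#' @param base_seed Integer seed for the whole sweep.
#' @param label Optional preset label stored with the curve.
#' @return An object of class `plv_curve`: data.frame `stim_freq_hz`,
#'   `plv_mean`, `plv_sd`, `n`, with attributes `label` and `runs` (the
#'   per-realization long table: `stim_freq_hz`, `realization`, `seed`,
#'   `plv`).
#' @export
frequency_sweep <- function(params, stim_freqs, n_realizations = 10L,
                            base_seed = NULL, label = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (length(stim_freqs) == 0L) stop_invalid("empty frequency list")
  if (!is_count(n_realizations)) stop_invalid("n_realizations must be >= 1")
  nf <- length(stim_freqs)
  nr <- as.integer(n_realizations)
  seeds <- matrix(derive_seeds(base_seed, nf * nr), nrow = nf)
  runs <- vector("list", nf)
  for (i in seq_len(nf)) {
    p_i <- params
    p_i$omega_s <- stim_freqs[i]
    plvs <- vapply(seq_len(nr), function(j) {
      trace_plv(simulate_model(p_i, seed = seeds[i, j]), "s", "a")
    }, 0)
    runs[[i]] <- data.frame(stim_freq_hz = stim_freqs[i],
                            realization = seq_len(nr),
                            seed = seeds[i, ],
                            plv = plvs)
  }
  runs <- do.call(rbind, runs)
  curve <- data.frame(
    stim_freq_hz = stim_freqs,
    plv_mean = tapply(runs$plv, runs$stim_freq_hz, mean)[as.character(stim_freqs)],
    plv_sd = tapply(runs$plv, runs$stim_freq_hz, stats::sd)[as.character(stim_freqs)],
    n = nr)
  rownames(curve) <- NULL
  structure(curve, class = c("plv_curve", "data.frame"),
            label = label, runs = runs)
}

#' Score the model against a behavioural performance curve
#'
#' Least-squares affine map from PLV to proportion correct over matched
#' conditions; returns its coefficient of determination, equal to the squared
#' Pearson correlation.
#'
#' @param plv_curve A `plv_curve` (or data.frame with `stim_freq_hz`,
#'   `plv_mean`).
#' @param perf_curve A [performance_curve()] (or data.frame with
#'   `condition_hz`, `prop_correct`) on the same frequency grid.
#' @return A list of class `behavior_fit`: `r_squared`, `intercept`, `slope`.
#'   A zero-variance PLV is an undefined fit: `r_squared` is `NA` and a
#'   warning of class `beatattn_undefined_fit` is signalled.
#' @export
fit_to_behavior <- function(plv_curve, perf_curve) {
  if (!all(c("stim_freq_hz", "plv_mean") %in% names(plv_curve)) ||
      !all(c("condition_hz", "prop_correct") %in% names(perf_curve))) {
    stop_invalid("curves must carry stim_freq_hz/plv_mean and condition_hz/prop_correct")
  }
  p <- plv_curve[order(plv_curve$stim_freq_hz), ]
  b <- perf_curve[order(perf_curve$condition_hz), ]
  if (nrow(p) != nrow(b) ||
      any(abs(p$stim_freq_hz - b$condition_hz) > 1e-9)) {
    stop_invalid("condition grids of the two curves do not match")
  }
  if (stats::sd(p$plv_mean) == 0) {
    warning(warningCondition("constant PLV: affine fit undefined",
                             class = "beatattn_undefined_fit"))
    return(structure(list(r_squared = NA_real_, intercept = NA_real_,
                          slope = NA_real_), class = "behavior_fit"))
  }
  fit <- stats::lm(b$prop_correct ~ p$plv_mean)
  structure(list(r_squared = stats::cor(p$plv_mean, b$prop_correct)^2,
                 intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2])),
            class = "behavior_fit")
}

#' Write a frequency sweep to CSV
#'
#' Two files: the per-realization long table and the per-frequency summary.
#'
#' @param curve A `plv_curve`.
#' @param runs_path,summary_path Output CSV paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
write_sweep <- function(curve, runs_path = NULL, summary_path = NULL) {
  stopifnot(inherits(curve, "plv_curve"))
  out <- character(0)
  if (!is.null(runs_path)) {
    runs <- attr(curve, "runs")
    runs$preset <- if (is.null(attr(curve, "label"))) NA_character_ else
      attr(curve, "label")
    utils::write.csv(runs[, c("preset", "stim_freq_hz", "realization",
                              "seed", "plv")],
                     runs_path, row.names = FALSE)
    out <- c(out, runs_path)
  }
  if (!is.null(summary_path)) {
    utils::write.csv(as.data.frame(curve), summary_path, row.names = FALSE)
    out <- c(out, summary_path)
  }
  invisible(out)
}
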
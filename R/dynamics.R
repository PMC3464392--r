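# Temporal dynamics of the simulated angiography: tracer filling (with an
# optional vascular lock), per-class vasoconstriction profiles, tissue
# leakage and photobleaching. All times are seconds relative to the electric
# pulse (EP); the injection time may be negative.

#' Per-class vasoconstriction profile
#'
#' At EP the vessel diameter drops instantaneously to
#' `(1 - amplitude) * baseline` after `onset_lag_s`, then recovers to baseline
#' over `recovery_s` either linearly or exponentially. `recovery_s = Inf`
#' models a constriction that does not recover within the observation window.
#'
#' @param amplitude Fraction of baseline diameter lost, in `[0, 1)`.
#' @param onset_lag_s Delay between EP and the diameter drop (s).
#' @param recovery_s Recovery time (s). For `shape = "linear"` the diameter is
#'   back at baseline exactly `recovery_s` after onset; for
#'   `shape = "exponential"` it is the time constant.
#' @param shape `"linear"` or `"exponential"`.
#' @return A list of class `constriction_profile`.
#' @export
constriction_profile <- function(amplitude = 0, onset_lag_s = 0,
                                 recovery_s = Inf,
                                 shape = c("linear", "exponential")) {
  shape <- match.arg(shape)
  if (amplitude < 0 || amplitude >= 1) abort("`amplitude` must lie in [0, 1).")
  structure(list(amplitude = amplitude, onset_lag_s = onset_lag_s,
                 recovery_s = recovery_s, shape = shape),
            class = "constriction_profile")
}

constriction_factor <- function(profile, t, ep_time = 0) {
  # the frame acquired at the EP time itself is the last pre-EP frame, so
  # the drop applies strictly after ep_time + onset_lag_s
  dt <- t - ep_time - profile$onset_lag_s
  out <- rep(1, length(t))
  hit <- dt > 0
  if (profile$amplitude == 0 || !any(hit)) return(out)
  if (profile$shape == "linear") {
    rec <- if (is.finite(profile$recovery_s)) {
      pmin(dt[hit] / profile$recovery_s, 1)
    } else 0
    out[hit] <- 1 - profile$amplitude * (1 - rec)
  } else {
    out[hit] <- 1 - profile$amplitude * exp(-dt[hit] / profile$recovery_s)
  }
  out
}

#' Dynamics model for the synthetic angiography
#'
#' @param tau_fill_s Single-exponential filling time constant of the vascular
#'   compartment after tracer injection (s).
#' @param lock_release_s Duration of the vascular lock: tracer filling is
#'   suspended from EP until `lock_release_s` after EP (0 = no lock).
#' @param constriction Named list with `arteriole` and `venule`
#'   [constriction_profile()] entries.
#' @param leak_rate_per_min Extravasation rate: increase of the tissue mean
#'   per minute during the linear phase, as a fraction of the pre-leak tissue
#'   intensity (1/min).
#' @param leak_linear_s Duration of the linear leakage phase (s); afterwards
#'   the tissue intensity plateaus.
#' @param background Tissue background intensity (fraction of full scale).
#' @param vascular_plateau Plateau vascular intensity (fraction of full
#'   scale).
#' @param bleach_per_min Photobleaching rate (fraction per minute, applied to
#'   both compartments; default 0).
#' @param tone_factor Multiplicative vasomotor-tone factor applied to all
#'   diameters after EP (models slow per-animal tone drift; default 1).
#' @return A list of class `dynamics_model`.
#' @export
dynamics_model <- function(tau_fill_s = 35, lock_release_s = 0,
                           constriction = list(
                             arteriole = constriction_profile(),
                             venule = constriction_profile()),
                           leak_rate_per_min = 0, leak_linear_s = 480,
                           background = 0.15, vascular_plateau = 0.75,
                           bleach_per_min = 0, tone_factor = 1) {
  if (tau_fill_s <= 0) abort("`tau_fill_s` must be positive.")
  if (leak_rate_per_min < 0) abort("`leak_rate_per_min` must be >= 0.")
  if (lock_release_s < 0) abort("`lock_release_s` must be >= 0.")
  if (vascular_plateau <= background) {
    abort("`vascular_plateau` must exceed `background`.")
  }
  structure(list(tau_fill_s = tau_fill_s, lock_release_s = lock_release_s,
                 constriction = constriction,
                 leak_rate_per_min = leak_rate_per_min,
                 leak_linear_s = leak_linear_s, background = background,
                 vascular_plateau = vascular_plateau,
                 bleach_per_min = bleach_per_min, tone_factor = tone_factor),
            class = "dynamics_model")
}

# Effective filling time: seconds of perfused flow since injection, i.e.
# elapsed time minus the part spent inside the lock interval
# [ep, ep + lock_release].
effective_fill_time <- function(t, injection_time, ep_time, lock_release_s) {
  u <- pmax(0, t - injection_time)
  if (lock_release_s > 0) {
    lo <- pmax(injection_time, ep_time)
    hi <- pmin(t, ep_time + lock_release_s)
    u <- u - pmax(0, hi - lo)
  }
  u
}

fill_fraction <- function(t, injection_time, ep_time, dynamics) {
  u <- effective_fill_time(t, injection_time, ep_time, dynamics$lock_release_s)
  1 - exp(-u / dynamics$tau_fill_s)
}

leak_fraction <- function(t, injection_time, ep_time, dynamics) {
  t0 <- max(ep_time, injection_time)
  dynamics$leak_rate_per_min *
    pmin(pmax(t - t0, 0), dynamics$leak_linear_s) / 60
}

bleach_factor <- function(t, t_first, dynamics) {
  if (dynamics$bleach_per_min == 0) return(rep(1, length(t)))
  exp(-dynamics$bleach_per_min * pmax(t - t_first, 0) / 60)
}

#' Acquisition schedule
#'
#' Frame times (seconds relative to EP) following the intravital protocol:
#' when the tracer is injected before EP, a pre-injection series every 20 s
#' for 2 min, then a post-EP series every 20 s for 8 min followed by every
#' 2 min for 22 min; when the tracer is injected at a delay after EP, only
#' the second series is acquired, starting at the injection.
#'
#' @param design `"pre_injection"` (tracer 2 min before EP) or `"post_delay"`
#'   (tracer `delay_min` minutes after EP).
#' @param delay_min Injection delay in minutes (required for `"post_delay"`).
#' @param fast_cadence_s,fast_duration_s Cadence/duration of the fast series.
#' @param slow_cadence_s,slow_duration_s Cadence/duration of the slow series.
#' @param pre_cadence_s,pre_duration_s Cadence/duration of the pre-EP series
#'   (pre-injection design only).
#' @return A list of class `acquisition_schedule` with `times` (s),
#'   `injection_time` (s) and `ep_time` (s).
#' @export
acquisition_schedule <- function(design = c("pre_injection", "post_delay"),
                                 delay_min = NULL,
                                 fast_cadence_s = 20, fast_duration_s = 480,
                                 slow_cadence_s = 120, slow_duration_s = 1320,
                                 pre_cadence_s = 20, pre_duration_s = 120) {
  design <- match.arg(design)
  fast <- seq(fast_cadence_s, fast_duration_s, by = fast_cadence_s)
  slow <- seq(fast_duration_s + slow_cadence_s,
              fast_duration_s + slow_duration_s, by = slow_cadence_s)
  if (design == "pre_injection") {
    injection <- -pre_duration_s
    times <- c(seq(-pre_duration_s, 0, by = pre_cadence_s), fast, slow)
  } else {
    if (is.null(delay_min)) abort("`delay_min` is required for the post-delay design.")
    injection <- delay_min * 60
    times <- injection + c(0, fast, slow)
  }
  if (any(diff(times) <= 0)) abort("frame times must be strictly increasing.")
  structure(list(times = times, injection_time = injection, ep_time = 0,
                 design = design, delay_min = delay_min),
            class = "acquisition_schedule")
}

#' Simulation configuration
#'
#' Bundles a vessel network (or the parameters to generate one), the dynamics
#' model, the acquisition schedule, and the imaging model (blur, noise, bit
#' depth). A fixed `seed` makes the rendered sequence bit-identical across
#' runs.
#'
#' @param network A [vessel_network()], or `NULL` to generate one from
#'   `network_args`.
#' @param dynamics A [dynamics_model()].
#' @param schedule An [acquisition_schedule()].
#' @param network_args List of arguments to [generate_network()] when
#'   `network` is `NULL`.
#' @param snr Signal-to-noise ratio at plateau: the vascular plateau amplitude
#'   divided by the additive Gaussian noise sd. `Inf` disables noise.
#' @param noise_mult Optional signal-dependent noise scale; the per-pixel sd
#'   becomes `sigma * (1 + noise_mult * value)`.
#' @param psf_sigma_px Gaussian point-spread blur sd (pixels).
#' @param bit_depth Output quantization depth (8 or 16).
#' @param seed Integer seed controlling network generation and noise.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(network = NULL, dynamics = dynamics_model(),
                              schedule = acquisition_schedule("pre_injection"),
                              network_args = list(), snr = 10, noise_mult = 0,
                              psf_sigma_px = 1, bit_depth = 16, seed = 1) {
  if (!bit_depth %in% c(8, 16)) abort("`bit_depth` must be 8 or 16.")
  structure(list(network = network, dynamics = dynamics, schedule = schedule,
                 network_args = network_args, snr = snr,
                 noise_mult = noise_mult, psf_sigma_px = psf_sigma_px,
                 bit_depth = bit_depth, seed = seed),
            class = "simulation_config")
}

#' Preset simulation configurations
#'
#' Named presets for the four study conditions:
#' * `"control"`: tracer 2 min before a sham pulse; no lock, no constriction,
#'   no leakage. Filling completes within 2 min.
#' * `"ep-lock"`: perfusion suspended until 8 min after EP, so filling
#'   completes about 10 min after an injection given 0.5 min post-EP.
#' * `"ep-leak"`: tissue intensity rises linearly for 8 min after EP, then
#'   plateaus.
#' * `"ep-constrict"`: arterioles constrict by 70% without recovery within
#'   the observation window; venules constrict by 30% and recover by 14 min.
#'
#' @param preset Preset name.
#' @param design,delay_min Passed to [acquisition_schedule()].
#' @param seed,... Passed to [simulation_config()].
#' @return A [simulation_config()].
#' @export
preset_config <- function(preset = c("control", "ep-lock", "ep-leak",
                                     "ep-constrict"),
                          design = c("pre_injection", "post_delay"),
                          delay_min = NULL, seed = 1, ...) {
  preset <- match.arg(preset)
  design <- match.arg(design)
  dyn <- switch(preset,
    "control" = dynamics_model(),
    "ep-lock" = dynamics_model(lock_release_s = 480),
    "ep-leak" = dynamics_model(leak_rate_per_min = 0.04),
    "ep-constrict" = dynamics_model(constriction = list(
      arteriole = constriction_profile(amplitude = 0.70, recovery_s = Inf),
      venule = constriction_profile(amplitude = 0.30, recovery_s = 840)))
  )
  simulation_config(dynamics = dyn,
                    schedule = acquisition_schedule(design, delay_min),
                    seed = seed, ...)
}
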
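# End-to-end experiment drivers: single-sequence analysis, the
# injection-delay sweep, and the simulated vessel cohort used for the
# per-timepoint diameter statistics.

#' Describe an experiment
#'
#' The two experiment designs: tracer injected 2 min before EP
#' (`"pre_injection"`, permeability kinetics) or at a delay after EP
#' (`"post_delay"`, vascular-lock and resealing duration).
#'
#' @param kind Design kind.
#' @param delay_min Injection delay in minutes; required for (and only
#'   allowed with) the post-delay design.
#' @param stack A `frame_sequence` or a [write_stack()] path prefix.
#' @param segments Optional segment annotations (network, tibble or
#'   [read_segments()] path) for the morphometry track.
#' @param reference_window Segmentation reference window `c(t0, t1)` (s);
#'   default: the last pre-EP minute for the pre-injection design, the last
#'   three frames otherwise.
#' @param completion_threshold,alpha,leak_window_s,tissue_margin_px Analysis
#'   parameters passed to the stages.
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(kind = c("pre_injection", "post_delay"),
                              delay_min = NULL, stack = NULL, segments = NULL,
                              reference_window = NULL,
                              completion_threshold = 95, alpha = 0.05,
                              leak_window_s = c(0, 480),
                              tissue_margin_px = 3) {
  kind <- match.arg(kind)
  if (kind == "post_delay" && is.null(delay_min)) {
    abort("`delay_min` is required for the post-delay design.")
  }
  if (kind == "pre_injection" && !is.null(delay_min)) {
    abort("`delay_min` is only meaningful for the post-delay design.")
  }
  structure(list(kind = kind, delay_min = delay_min, stack = stack,
                 segments = segments, reference_window = reference_window,
                 completion_threshold = completion_threshold, alpha = alpha,
                 leak_window_s = leak_window_s,
                 tissue_margin_px = tissue_margin_px),
            class = "experiment_design")
}

#' Run one experiment end to end
#'
#' Executes segmentation, compartment-trace extraction, filling and leakage
#' kinetics (with the linear-plateau segmented fit), and — when segment
#' annotations are provided — the diameter morphometry track. Deterministic
#' given a fixed input sequence and parameters.
#'
#' @param design An [experiment_design()].
#' @return A list of class `vasodyn_run` with elements `mask`, `traces`,
#'   `fill`, `leakage`, `segmented`, `diameters` (or `NULL`) and `manifest`;
#'   [glance()] collapses the scalar metrics to one row.
#' @export
run_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  seq <- design$stack
  checksums <- NULL
  if (is.character(seq)) {
    checksums <- tools::md5sum(paste0(seq, c(".tif", "_frames.tsv", "_meta.tsv")))
    seq <- read_stack(seq)
  }
  if (is.null(seq)) abort("`design$stack` must supply a sequence.")
  ref <- design$reference_window %||% (
    if (design$kind == "pre_injection") c(seq$ep_time - 60, seq$ep_time)
    else c(seq$times[max(1, length(seq$times) - 2)], max(seq$times))
  )
  mask <- build_mask(seq, reference_window = ref)
  traces <- extract_traces(seq, mask, tissue_margin_px = design$tissue_margin_px)
  fill <- fill_curve(traces, completion_threshold = design$completion_threshold)
  leakage <- leakage_curve(traces, window = design$leak_window_s)
  segmented <- segmented_fit(leakage)
  diameters <- NULL
  if (!is.null(design$segments)) {
    segs <- design$segments
    if (is.character(segs)) segs <- read_segments(segs)
    diameters <- measure_network_diameters(seq, segs,
                                           baseline_time = seq$ep_time)
  }
  manifest <- list(
    tool = "vasodyn", version = as.character(packageVersion("vasodyn")),
    kind = design$kind, delay_min = design$delay_min,
    seed = seq$seed, input_md5 = checksums,
    parameters = list(reference_window = ref,
                      completion_threshold = design$completion_threshold,
                      leak_window_s = design$leak_window_s,
                      tissue_margin_px = design$tissue_margin_px,
                      alpha = design$alpha),
    n_frames = length(seq$frames), timestamp = format(Sys.time(), tz = "UTC")
  )
  structure(list(design = design, mask = mask, traces = traces, fill = fill,
                 leakage = leakage, segmented = segmented,
                 diameters = diameters, manifest = manifest),
            class = "vasodyn_run")
}

#' @export
print.vasodyn_run <- function(x, ...) {
  cat(sprintf("<vasodyn_run> %s design: completion %s, leak rate %.4g /min, breakpoint %.0f s\n",
              x$design$kind,
              if (x$fill$completion_reached) sprintf("%g s", x$fill$completion_s)
              else "not reached",
              x$leakage$rate_per_min, x$segmented$breakpoint_s))
  invisible(x)
}

#' @export
glance.vasodyn_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble(kind = x$design$kind,
           delay_min = x$design$delay_min %||% NA_real_),
    glance(x$fill),
    glance(x$leakage)[, "rate_per_min"],
    glance(x$segmented)[, c("breakpoint_s", "breakpoint_detected")]
  )
}

#' Write the result tables of a run
#'
#' CSV tables (`traces.csv`, `metrics.csv`, and `diameters.csv` when the
#' morphometry track ran) plus a plain-text `manifest.txt`. The CSV content
#' is a pure function of the inputs, so re-running an identical design gives
#' byte-identical tables.
#'
#' @param run A `vasodyn_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_tables <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traces <- dplyr::left_join(as_tibble(run$traces),
                             tidy(run$fill)[, c("time_s", "fill_pct")],
                             by = "time_s")
  traces <- dplyr::left_join(traces,
                             tidy(run$leakage)[, c("time_s", "delta_rel")],
                             by = "time_s")
  write.csv(traces, file.path(dir, "traces.csv"), row.names = FALSE)
  write.csv(glance(run), file.path(dir, "metrics.csv"), row.names = FALSE)
  if (!is.null(run$diameters)) {
    write.csv(run$diameters, file.path(dir, "diameters.csv"),
              row.names = FALSE)
  }
  m <- run$manifest
  lines <- c(
    sprintf("tool\t%s %s", m$tool, m$version),
    sprintf("kind\t%s", m$kind),
    sprintf("delay_min\t%s", m$delay_min %||% "NA"),
    sprintf("seed\t%s", m$seed %||% "NA"),
    sprintf("n_frames\t%d", m$n_frames),
    sprintf("timestamp\t%s", m$timestamp),
    vapply(names(m$parameters), function(k) {
      sprintf("param.%s\t%s", k, paste(m$parameters[[k]], collapse = ","))
    }, character(1)),
    if (!is.null(m$input_md5)) {
      sprintf("md5.%s\t%s", basename(names(m$input_md5)), m$input_md5)
    }
  )
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(dir)
}

# Derive per-replicate sub-seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1, n))
}

#' Injection-delay sweep
#'
#' Simulates and analyzes the resealing experiment: the tracer is injected
#' at each of the tested delays after EP (plus a no-EP control on the same
#' acquisition grid), with the vascular lock releasing at `lock_release_s`
#' and the extravasation rate decaying with the delay. Per condition it
#' reports completion times and per-minute leakage rates and summarizes
#' * the lock duration: the smallest tested delay whose completion time is
#'   not significantly different from control, and
#' * the permeability recovery delay: the smallest tested delay whose
#'   leakage rate is not significantly different from control
#' (two-sample t tests at `alpha`).
#'
#' @param delays_min Tested injection delays (minutes after EP).
#' @param n Replicates (animals) per condition.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param lock_release_s Lock duration of the simulation truth (s).
#' @param leak_rates_per_min Named vector mapping each delay to its true
#'   extravasation rate (1/min); the default encodes elevated leakage at
#'   0.5-5 min, intermediate at 10 min and control-level at 30 min.
#' @param rate_cv Between-animal lognormal coefficient of variation applied
#'   to the true rate.
#' @param tau_fill_s Filling time constant (s).
#' @param alpha Significance level for the summaries.
#' @param n_arterioles,n_venules,field_px,snr Simulation size parameters.
#' @return A list of class `delay_sweep`: `data` (per-replicate tibble),
#'   `summary` (per-condition means), `lock_duration_min`,
#'   `leak_recovery_delay_min`.
#' @export
run_delay_sweep <- function(delays_min = c(0.5, 1, 5, 10, 30), n = 3,
                            seed = 1, lock_release_s = 480,
                            leak_rates_per_min = c("0.5" = 0.04, "1" = 0.035,
                                                   "5" = 0.02, "10" = 0.008,
                                                   "30" = 0),
                            rate_cv = 0.1, tau_fill_s = 35, alpha = 0.05,
                            n_arterioles = 2, n_venules = 3,
                            field_px = c(128, 128), snr = 10) {
  delays_min <- sort(delays_min)
  conditions <- c("control", as.character(delays_min))
  seeds <- matrix(derive_seeds(seed, n * length(conditions)),
                  nrow = length(conditions))
  jitters <- withr::with_seed(seed + 1,
                              matrix(rnorm(n * length(conditions), 0, rate_cv),
                                     nrow = length(conditions)))
  rows <- purrr::map_dfr(seq_along(conditions), function(ci) {
    cond <- conditions[ci]
    purrr::map_dfr(seq_len(n), function(r) {
      s <- seeds[ci, r]
      if (cond == "control") {
        dyn <- dynamics_model(tau_fill_s = tau_fill_s)
        sched <- acquisition_schedule("post_delay", delay_min = 0)
        delay <- NA_real_
      } else {
        delay <- as.numeric(cond)
        rate <- leak_rates_per_min[[cond]] * exp(jitters[ci, r])
        dyn <- dynamics_model(tau_fill_s = tau_fill_s,
                              lock_release_s = lock_release_s,
                              leak_rate_per_min = rate)
        sched <- acquisition_schedule("post_delay", delay_min = delay)
      }
      net <- generate_network(n_arterioles = n_arterioles,
                              n_venules = n_venules, field_px = field_px,
                              seed = s)
      sq <- render_sequence(net, simulation_config(dynamics = dyn,
                                                   schedule = sched,
                                                   snr = snr, seed = s))
      mask <- build_mask(sq)
      tr <- extract_traces(sq, mask)
      fk <- fill_curve(tr)
      lk <- leakage_curve(tr)
      tibble(condition = cond, delay_min = delay, replicate = r, seed = s,
             completion_s = fk$completion_s,
             completion_min = fk$completion_s / 60,
             max_variation_per_s = fk$max_variation_per_s,
             leak_rate_per_min = lk$rate_per_min)
    })
  })

  ctrl <- rows[rows$condition == "control", ]
  per_delay <- function(metric) {
    map_dbl(as.character(delays_min), function(d) {
      ttest2(rows[[metric]][rows$condition == d], ctrl[[metric]])$p.value
    })
  }
  p_completion <- per_delay("completion_s")
  p_leak <- per_delay("leak_rate_per_min")
  first_ns <- function(p) {
    i <- which(p >= alpha)
    if (length(i) == 0) NA_real_ else delays_min[min(i)]
  }
  summary <- rows |>
    group_by(.data$condition) |>
    summarise(delay_min = .data$delay_min[1],
              completion_min = mean(.data$completion_min),
              leak_rate_per_min = mean(.data$leak_rate_per_min),
              .groups = "drop") |>
    arrange(!is.na(.data$delay_min), .data$delay_min)
  summary$p_completion_vs_control <- c(NA_real_, p_completion)
  summary$p_leak_vs_control <- c(NA_real_, p_leak)
  structure(list(data = rows, summary = summary,
                 lock_duration_min = first_ns(p_completion),
                 leak_recovery_delay_min = first_ns(p_leak),
                 alpha = alpha, delays_min = delays_min),
            class = "delay_sweep")
}

#' @export
print.delay_sweep <- function(x, ...) {
  cat(sprintf("<delay_sweep> delays %s min; lock duration %s min; leakage recovered at %s min (alpha %g)\n",
              paste(x$delays_min, collapse = "/"),
              format(x$lock_duration_min), format(x$leak_recovery_delay_min),
              x$alpha))
  print(x$summary)
  invisible(x)
}

#' @export
glance.delay_sweep <- function(x, ...) {
  tibble(lock_duration_min = x$lock_duration_min,
         leak_recovery_delay_min = x$leak_recovery_delay_min,
         alpha = x$alpha)
}

#' Simulate a vessel cohort for per-timepoint diameter statistics
#'
#' Renders one synthetic sequence per animal — an EP group whose vessels of
#' the chosen class constrict and recover, and a control group without EP
#' effects — measures all vessels of that class, and collapses to one value
#' per animal and timepoint (the per-animal mean of its vessels' normalized
#' diameters; the animal is the unit of replication). Between-animal
#' variability comprises the network geometry, a constriction-amplitude
#' jitter, and a persistent vasomotor-tone factor applied to post-EP
#' diameters of both groups.
#'
#' @param n_per_group Animals per group.
#' @param n_vessels Vessels of the measured class per animal.
#' @param vessel_class `"venule"` or `"arteriole"`.
#' @param amplitude,amplitude_sd Mean and between-animal sd of the
#'   constriction amplitude.
#' @param recovery_s Constriction recovery time (s; `Inf` = no recovery).
#' @param tone_sd Between-animal sd of the post-EP vasomotor-tone factor.
#' @param seed Master seed.
#' @param field_px,snr Simulation size parameters.
#' @return Tidy tibble: `condition` (`"EP"`/`"control"`), `animal`, `time_s`,
#'   `value` (per-animal mean normalized diameter).
#' @export
simulate_vessel_cohort <- function(n_per_group = 3, n_vessels = 5,
                                   vessel_class = "venule",
                                   amplitude = 0.30, amplitude_sd = 0.03,
                                   recovery_s = 840, tone_sd = 0.01,
                                   seed = 1, field_px = c(160, 160),
                                   snr = 10) {
  n_total <- 2 * n_per_group
  seeds <- derive_seeds(seed, n_total)
  draws <- withr::with_seed(seed + 1, list(
    amp = pmin(pmax(rnorm(n_total, amplitude, amplitude_sd), 0.02), 0.95),
    tone = rnorm(n_total, 1, tone_sd)
  ))
  purrr::map_dfr(seq_len(n_total), function(a) {
    is_ep <- a <= n_per_group
    prof <- constriction_profile(amplitude = if (is_ep) draws$amp[a] else 0,
                                 recovery_s = recovery_s)
    constr <- list(arteriole = constriction_profile(),
                   venule = constriction_profile())
    constr[[vessel_class]] <- prof
    dyn <- dynamics_model(constriction = constr, tone_factor = draws$tone[a])
    net <- generate_network(
      n_arterioles = if (vessel_class == "arteriole") n_vessels else 1,
      n_venules = if (vessel_class == "venule") n_vessels else 1,
      field_px = field_px, seed = seeds[a])
    sq <- render_sequence(net, simulation_config(
      dynamics = dyn, schedule = acquisition_schedule("pre_injection"),
      snr = snr, seed = seeds[a]))
    segs <- net$segments[net$segments$class == vessel_class, ]
    diam <- measure_network_diameters(sq, segs, baseline_time = sq$ep_time)
    diam <- qc_stable_segments(diam)
    diam |>
      group_by(.data$time_s) |>
      summarise(value = mean(.data$normalized, na.rm = TRUE),
                .groups = "drop") |>
      mutate(condition = if (is_ep) "EP" else "control",
             animal = a, .before = 1)
  })
}
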
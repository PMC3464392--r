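# Rendering of the synthetic angiography sequence and its ground truth.

#' Render a synthetic angiography sequence
#'
#' Produces timestamped frames plus the complete ground truth for every
#' quantity the analysis stages estimate. Per frame, each vessel segment is
#' rasterized as a ribbon around its centerline with the diameter dictated by
#' the constriction profile (soft, area-weighted edges); vascular pixels carry
#' the filling-up intensity, tissue pixels the background plus accumulated
#' leakage; a Gaussian point-spread blur and noise are applied last and the
#' frame is quantized to the configured bit depth.
#'
#' @param network A [vessel_network()], or `NULL` to use/generate the one in
#'   `config`.
#' @param config A [simulation_config()].
#' @return An object of class `frame_sequence`: list with `frames` (list of
#'   matrices in `[0, 1]`), `times` (s relative to EP), `injection_time`,
#'   `ep_time`, `pixel_size_um`, `network`, and `ground_truth` (list with the
#'   rendering `mask`, per-frame `intensity` tibble of noiseless compartment
#'   means, per-segment `diameters` tibble, `lock_release_s`,
#'   `leak_breakpoint_s` and the constriction profiles).
#' @export
render_sequence <- function(network = NULL, config = simulation_config()) {
  network <- network %||% config$network %||%
    do.call(generate_network, c(config$network_args, list(seed = config$seed)))
  sched <- config$schedule
  dyn <- config$dynamics
  times <- sched$times
  if (any(times < sched$injection_time & sched$design == "post_delay")) {
    abort("frames before the injection are not part of the post-delay design.")
  }
  H <- network$field_px[1]; W <- network$field_px[2]
  px_um <- network$pixel_size_um

  dist_fields <- map(network$segments$polyline, polyline_distance_field,
                     dim = c(H, W))

  # ground-truth diameters at every frame time
  segs <- network$segments
  factor_by_class <- function(cls, t) {
    constriction_factor(dyn$constriction[[cls]], t, sched$ep_time)
  }
  tone <- ifelse(times > sched$ep_time, dyn$tone_factor, 1)
  diam_truth <- purrr::map_dfr(seq_len(nrow(segs)), function(i) {
    tibble(segment = segs$id[i], class = segs$class[i], time_s = times,
           diameter_um = segs$caliber_um[i] *
             factor_by_class(segs$class[i], times) * tone)
  })

  fillf <- fill_fraction(times, sched$injection_time, sched$ep_time, dyn)
  leakf <- leak_fraction(times, sched$injection_time, sched$ep_time, dyn)
  bleach <- bleach_factor(times, times[1], dyn)
  vasc_int <- (dyn$background + (dyn$vascular_plateau - dyn$background) * fillf) * bleach
  tiss_int <- dyn$background * (1 + leakf) * bleach

  baseline_cov <- coverage_stack(dist_fields, segs$caliber_um / (2 * px_um))
  gt_mask <- baseline_cov >= 0.5

  sigma <- if (is.finite(config$snr) && config$snr > 0) {
    (dyn$vascular_plateau - dyn$background) / config$snr
  } else 0
  levels <- 2^config$bit_depth - 1
  clamped_any <- FALSE

  render_one <- function(k) {
    radii <- diam_truth$diameter_um[diam_truth$time_s == times[k]]
    radii <- radii[order(diam_truth$segment[diam_truth$time_s == times[k]])] /
      (2 * px_um)
    if (any(radii < 0.5)) {
      clamped_any <<- TRUE
      radii <- pmax(radii, 0.5)
    }
    w <- coverage_stack(dist_fields, radii)
    w * vasc_int[k] + (1 - w) * tiss_int[k]
  }

  run <- function() {
    frames <- vector("list", length(times))
    vasc_true <- tiss_true <- numeric(length(times))
    for (k in seq_along(times)) {
      f <- render_one(k)
      vasc_true[k] <- mean(f[gt_mask])
      tiss_true[k] <- mean(f[!gt_mask])
      if (config$psf_sigma_px > 0) {
        f <- EBImage::gblur(f, sigma = config$psf_sigma_px)
      }
      if (sigma > 0) {
        eps <- rnorm(length(f), 0, sigma)
        if (config$noise_mult > 0) eps <- eps * (1 + config$noise_mult * f)
        f <- f + eps
      }
      f <- pmin(pmax(f, 0), 1)
      frames[[k]] <- matrix(round(f * levels) / levels, H, W)
    }
    list(frames = frames, vasc_true = vasc_true, tiss_true = tiss_true)
  }
  out <- withr::with_seed(config$seed, run())
  if (clamped_any) {
    warn("constriction reduced a rendered vessel below 1 px width; clamped to 1 px.")
  }

  structure(
    list(frames = out$frames, times = times,
         injection_time = sched$injection_time, ep_time = sched$ep_time,
         pixel_size_um = px_um, bit_depth = config$bit_depth,
         seed = config$seed, network = network,
         ground_truth = list(
           mask = gt_mask,
           # *_true: noiseless raster means over the rendering mask and its
           # complement (including partial-volume edge pixels);
           # *_model: the pure compartment intensities of the dynamics model
           intensity = tibble(time_s = times, vascular_true = out$vasc_true,
                              tissue_true = out$tiss_true,
                              vascular_model = vasc_int,
                              tissue_model = tiss_int),
           diameters = diam_truth,
           lock_release_s = dyn$lock_release_s,
           leak_breakpoint_s = if (dyn$leak_rate_per_min > 0) {
             max(sched$ep_time, sched$injection_time) + dyn$leak_linear_s
           } else NA_real_,
           constriction = dyn$constriction,
           fill_tau_s = dyn$tau_fill_s)),
    class = "frame_sequence"
  )
}

# Combined soft vascular coverage: per pixel, max over segments of
# clamp(radius + 0.5 - distance, 0, 1) — an area-weight approximation giving
# sub-pixel edges.
coverage_stack <- function(dist_fields, radii_px) {
  w <- matrix(0, nrow(dist_fields[[1]]), ncol(dist_fields[[1]]))
  for (i in seq_along(dist_fields)) {
    w <- pmax(w, pmin(pmax(radii_px[i] + 0.5 - dist_fields[[i]], 0), 1))
  }
  w
}

#' Simulate an angiography experiment in one call
#'
#' Convenience wrapper: builds a preset configuration, generates a network and
#' renders the sequence.
#'
#' @inheritParams preset_config
#' @param n_arterioles,n_venules Network composition.
#' @param dynamics Optional [dynamics_model()] overriding the preset's.
#' @param field_px,pixel_size_um Raster geometry.
#' @param ... Passed to [simulation_config()].
#' @return A `frame_sequence` (see [render_sequence()]).
#' @export
simulate_angiography <- function(preset = "control",
                                 design = c("pre_injection", "post_delay"),
                                 delay_min = NULL, n_arterioles = 5,
                                 n_venules = 5, dynamics = NULL,
                                 field_px = c(192, 192), pixel_size_um = 2,
                                 seed = 1, ...) {
  cfg <- preset_config(preset, design = design, delay_min = delay_min,
                       seed = seed, ...)
  if (!is.null(dynamics)) cfg$dynamics <- dynamics
  net <- generate_network(n_arterioles = n_arterioles, n_venules = n_venules,
                          field_px = field_px, pixel_size_um = pixel_size_um,
                          seed = seed)
  render_sequence(net, cfg)
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames %dx%d px @ %g um/px, t = [%g, %g] s (EP at %g s, injection at %g s)\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$pixel_size_um, min(x$times), max(x$times), x$ep_time,
              x$injection_time))
  invisible(x)
}
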
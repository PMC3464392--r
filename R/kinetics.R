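# Intensity-derived kinetic metrics: compartment traces, filling-up curves,
# leakage (relative-variation) curves, and the linear-plateau segmented fit.

#' Extract compartment mean-intensity traces
#'
#' Per-frame arithmetic mean intensity over the vascular pixels and over the
#' tissue pixels. A dilation margin around the vascular mask (default 3 px,
#' about three PSF sigmas of the default imaging model) is excluded from the
#' tissue compartment so that partial-volume boundary pixels, spread by the
#' point-spread blur, do not bleed vascular signal into the tissue mean.
#'
#' @param sequence A `frame_sequence`.
#' @param mask A `vessel_mask` (or logical matrix) matching the frame shape.
#' @param tissue_margin_px Dilation margin (pixels) excluded from the tissue
#'   compartment; 0 disables the exclusion.
#' @return A tibble of class `compartment_trace` with columns `time_s`,
#'   `vascular_mean`, `tissue_mean` and attributes `injection_time`,
#'   `ep_time`.
#' @export
extract_traces <- function(sequence, mask, tissue_margin_px = 3) {
  m <- as_mask_matrix(mask)
  if (!all(dim(m) == dim(sequence$frames[[1]]))) {
    abort("mask shape does not match the frames.")
  }
  if (sum(m) == 0) abort("empty vascular mask: no vascular compartment.")
  tissue <- !m
  if (tissue_margin_px > 0) {
    brush <- EBImage::makeBrush(2 * tissue_margin_px + 1, shape = "disc")
    tissue <- !(EBImage::dilate(m, brush) > 0)
  }
  if (sum(tissue) == 0) abort("tissue compartment is empty after the margin exclusion.")
  out <- tibble(
    time_s = sequence$times,
    vascular_mean = map_dbl(sequence$frames, ~ mean(.x[m])),
    tissue_mean = map_dbl(sequence$frames, ~ mean(.x[tissue]))
  )
  new_compartment_trace(out, sequence$injection_time, sequence$ep_time)
}

new_compartment_trace <- function(data, injection_time, ep_time,
                                  condition = NA_character_) {
  structure(as_tibble(data),
            injection_time = injection_time, ep_time = ep_time,
            condition = condition,
            class = c("compartment_trace", class(as_tibble(data))))
}

#' Assemble a compartment trace from vectors
#'
#' Constructor for hand-built traces (testing, external data).
#'
#' @param time_s Frame times, seconds relative to EP, strictly increasing.
#' @param vascular_mean,tissue_mean Mean intensities per frame.
#' @param injection_time,ep_time Event times (s).
#' @param condition Optional condition label.
#' @return A `compartment_trace` tibble.
#' @export
compartment_trace <- function(time_s, vascular_mean, tissue_mean = NULL,
                              injection_time = -120, ep_time = 0,
                              condition = NA_character_) {
  if (any(diff(time_s) <= 0)) abort("`time_s` must be strictly increasing.")
  if (length(vascular_mean) != length(time_s)) {
    abort("`vascular_mean` and `time_s` lengths differ.")
  }
  tissue_mean <- tissue_mean %||% rep(NA_real_, length(time_s))
  new_compartment_trace(
    tibble(time_s = time_s, vascular_mean = vascular_mean,
           tissue_mean = tissue_mean),
    injection_time, ep_time, condition
  )
}

#' Filling-up kinetics
#'
#' Normalizes the vascular trace to the maximal (plateau) vascular intensity
#' I_max and derives the filling metrics: the curve as percent of I_max, the
#' completion time (first post-injection frame at which the curve reaches the
#' completion threshold and stays at or above it), and the maximal intensity
#' variation per second over consecutive frames (computed with the actual,
#' non-uniform frame spacing).
#'
#' @param trace A `compartment_trace`.
#' @param completion_threshold Percent of I_max that must be sustained
#'   (default 95).
#' @param imax `"tail"` (mean of the last `imax_frames` frames, default) or
#'   `"quantile"` (95th percentile of the post-injection curve).
#' @param imax_frames Number of tail frames averaged for I_max.
#' @param background Optional background intensity subtracted from the
#'   vascular trace before normalization (default 0 = off).
#' @return An object of class `fill_kinetics`; use [tidy()] for the per-frame
#'   curve and [glance()] for the scalar metrics.
#' @export
fill_curve <- function(trace, completion_threshold = 95,
                       imax = c("tail", "quantile"), imax_frames = 3,
                       background = 0) {
  imax <- match.arg(imax)
  inj <- attr(trace, "injection_time")
  post <- trace[trace$time_s >= inj, ]
  if (nrow(post) < 3) abort("need at least 3 frames after the injection.")
  v <- post$vascular_mean - background
  i_max <- switch(imax,
    tail = mean(tail(v, imax_frames)),
    quantile = as.numeric(quantile(v, 0.95)))
  if (i_max <= 0) abort("plateau vascular intensity is not above background.")
  pct <- 100 * v / i_max
  ok <- pct >= completion_threshold
  sustained <- rev(cumprod(rev(ok))) > 0
  t_after <- post$time_s - inj
  completion <- if (any(sustained & t_after > 0)) {
    min(t_after[sustained & t_after > 0])
  } else NA_real_
  dv <- diff(v) / diff(post$time_s)
  structure(
    list(data = tibble(time_s = post$time_s,
                       time_after_injection_s = t_after,
                       vascular_mean = post$vascular_mean, fill_pct = pct),
         i_max = i_max, completion_s = completion,
         completion_reached = !is.na(completion),
         max_variation_per_s = max(dv),
         completion_threshold = completion_threshold,
         injection_time = inj),
    class = "fill_kinetics"
  )
}

#' @export
print.fill_kinetics <- function(x, ...) {
  cat(sprintf("<fill_kinetics> I_max = %.4g; completion (%g%% sustained) = %s; max dI/dt = %.4g /s\n",
              x$i_max, x$completion_threshold,
              if (x$completion_reached) sprintf("%g s after injection", x$completion_s)
              else "not reached", x$max_variation_per_s))
  invisible(x)
}

#' @export
tidy.fill_kinetics <- function(x, ...) x$data

#' @export
glance.fill_kinetics <- function(x, ...) {
  tibble(i_max = x$i_max, completion_s = x$completion_s,
         completion_min = x$completion_s / 60,
         completion_reached = x$completion_reached,
         max_variation_per_s = x$max_variation_per_s)
}

#' Tissue leakage (relative-variation) kinetics
#'
#' Computes the relative variation of the tissue mean intensity,
#' `(I(t) - I(t_ref)) / I(t_ref)`, and its per-minute rate as the
#' ordinary-least-squares slope over a designated window (default: the first
#' 8 min after the reference frame, the window within which extravasation
#' grows linearly with time).
#'
#' @param trace A `compartment_trace` with a tissue series.
#' @param reference_time Reference frame time (s). Default: the last frame at
#'   or before EP when the tracer was injected before EP, otherwise the first
#'   post-injection frame. The nearest frame within one cadence step is used.
#' @param window `c(t0, t1)` in seconds after the reference frame over which
#'   the rate is fitted.
#' @param rate_method `"ols"` (least-squares slope, default) or `"endpoint"`
#'   (difference between the last and first frame of the window divided by
#'   the elapsed minutes).
#' @return An object of class `leakage_kinetics`; [tidy()] gives the
#'   relative-variation series, [glance()] the scalar rate.
#' @export
leakage_curve <- function(trace, reference_time = NULL, window = c(0, 480),
                          rate_method = c("ols", "endpoint")) {
  rate_method <- match.arg(rate_method)
  inj <- attr(trace, "injection_time"); ep <- attr(trace, "ep_time")
  if (is.null(reference_time)) {
    reference_time <- if (inj < ep) {
      max(trace$time_s[trace$time_s <= ep])
    } else {
      min(trace$time_s[trace$time_s >= inj])
    }
  }
  k <- which.min(abs(trace$time_s - reference_time))
  cadence <- median(diff(trace$time_s))
  if (abs(trace$time_s[k] - reference_time) > cadence) {
    abort("no frame within one cadence step of `reference_time`.")
  }
  t_ref <- trace$time_s[k]
  i_ref <- trace$tissue_mean[k]
  if (!is.finite(i_ref) || i_ref <= 0) {
    abort("reference tissue mean must be positive; relative variation undefined.")
  }
  delta <- (trace$tissue_mean - i_ref) / i_ref
  dat <- tibble(time_s = trace$time_s, tissue_mean = trace$tissue_mean,
                delta_rel = delta)
  inw <- dat$time_s >= t_ref + window[1] & dat$time_s <= t_ref + window[2]
  if (sum(inw) < 2) abort("leakage-rate window contains fewer than 2 frames.")
  x_min <- (dat$time_s[inw] - t_ref) / 60
  y <- dat$delta_rel[inw]
  rate <- if (rate_method == "ols") {
    xc <- x_min - mean(x_min)
    sum(xc * (y - mean(y))) / sum(xc^2)
  } else {
    (y[length(y)] - y[1]) / (x_min[length(x_min)] - x_min[1])
  }
  structure(
    list(data = dat, rate_per_min = rate, reference_time = t_ref,
         reference_intensity = i_ref, window = window,
         rate_method = rate_method),
    class = "leakage_kinetics"
  )
}

#' @export
print.leakage_kinetics <- function(x, ...) {
  cat(sprintf("<leakage_kinetics> reference t = %g s; rate = %.4g /min (%s, window %g-%g s)\n",
              x$reference_time, x$rate_per_min, x$rate_method,
              x$window[1], x$window[2]))
  invisible(x)
}

#' @export
tidy.leakage_kinetics <- function(x, ...) x$data

#' @export
glance.leakage_kinetics <- function(x, ...) {
  tibble(rate_per_min = x$rate_per_min, reference_time = x$reference_time,
         window_start_s = x$window[1], window_end_s = x$window[2])
}

#' Linear-plateau segmented fit
#'
#' Least-squares fit of a continuous two-piece model to the
#' relative-variation curve: linear through the reference point up to a
#' breakpoint `b`, constant thereafter. The breakpoint is optimized over a
#' grid of candidate frame times with continuous refinement between
#' neighboring candidates. When the best breakpoint sits at the boundary of
#' the candidate range, the data contain a single regime and
#' `breakpoint_detected` is `FALSE`.
#'
#' @param kinetics A `leakage_kinetics` object, or a data frame with columns
#'   `time_s` and `delta_rel`.
#' @param reference_time Time of the reference point the linear piece passes
#'   through (taken from `kinetics` when available).
#' @return An object of class `segmented_fit` with `breakpoint_s`,
#'   `slope_per_min`, `plateau`, `ssr` and `breakpoint_detected`; [glance()]
#'   returns them as a one-row tibble.
#' @export
segmented_fit <- function(kinetics, reference_time = NULL) {
  if (inherits(kinetics, "leakage_kinetics")) {
    reference_time <- reference_time %||% kinetics$reference_time
    dat <- kinetics$data
  } else {
    dat <- as_tibble(kinetics)
    reference_time <- reference_time %||% min(dat$time_s)
  }
  dat <- dat[dat$time_s >= reference_time, ]
  if (nrow(dat) < 5) abort("need at least 5 points spanning both regimes.")
  t <- dat$time_s; y <- dat$delta_rel

  ssr_at <- function(b) {
    x <- (pmin(t, b) - reference_time) / 60
    sxx <- sum(x^2)
    s <- if (sxx > 0) sum(x * y) / sxx else 0
    list(ssr = sum((y - s * x)^2), slope = s)
  }
  candidates <- t[t > reference_time]
  fits <- map_dbl(candidates, ~ ssr_at(.x)$ssr)
  best <- which.min(fits)
  b <- candidates[best]
  lo <- if (best > 1) candidates[best - 1] else candidates[best]
  hi <- if (best < length(candidates)) candidates[best + 1] else candidates[best]
  if (hi > lo) {
    opt <- optimize(function(bb) ssr_at(bb)$ssr, interval = c(lo, hi))
    if (opt$objective <= fits[best]) b <- opt$minimum
  }
  fit <- ssr_at(b)
  detected <- best > 1 && best < length(candidates)
  structure(
    list(breakpoint_s = b, slope_per_min = fit$slope,
         plateau = fit$slope * (b - reference_time) / 60, ssr = fit$ssr,
         breakpoint_detected = detected, reference_time = reference_time,
         n = length(t)),
    class = "segmented_fit"
  )
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("<segmented_fit> breakpoint = %.1f s%s; slope = %.4g /min; plateau = %.4g (SSR %.3g)\n",
              x$breakpoint_s,
              if (x$breakpoint_detected) "" else " [no breakpoint detected]",
              x$slope_per_min, x$plateau, x$ssr))
  invisible(x)
}

#' @export
glance.segmented_fit <- function(x, ...) {
  tibble(breakpoint_s = x$breakpoint_s, breakpoint_min = x$breakpoint_s / 60,
         slope_per_min = x$slope_per_min, plateau = x$plateau, ssr = x$ssr,
         breakpoint_detected = x$breakpoint_detected)
}
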
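# Vessel diameter morphometry: full width at half maximum of intensity
# profiles sampled perpendicular to the centerline, with sub-pixel bilinear
# interpolation, and baseline normalization over time.

# Bilinear interpolation of image values at fractional 0-based (x, y)
# coordinates; NA outside the field.
bilinear_sample <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- x >= 0 & x <= W - 1 & y >= 0 & y <= H - 1
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), W - 2); y0 <- pmin(floor(y), H - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i01 <- img[cbind(y0 + 1, x0 + 2)]
  i10 <- img[cbind(y0 + 2, x0 + 1)]
  i11 <- img[cbind(y0 + 2, x0 + 2)]
  out[ok] <- i00 * (1 - fx) * (1 - fy) + i01 * fx * (1 - fy) +
    i10 * (1 - fx) * fy + i11 * fx * fy
  out
}

# Resample a polyline to n points equally spaced in arc length; returns the
# points plus unit tangents.
resample_polyline <- function(polyline, n) {
  d <- sqrt(rowSums(diff(polyline)^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  si <- seq(0, total, length.out = n)
  x <- approx(s, polyline[, 1], xout = si, ties = "ordered")$y
  y <- approx(s, polyline[, 2], xout = si, ties = "ordered")$y
  pts <- cbind(x, y)
  tg <- rbind(pts[2, ] - pts[1, ],
              (pts[-(1:2), , drop = FALSE] - pts[seq_len(n - 2), , drop = FALSE]) / 2,
              pts[n, ] - pts[n - 1, ])
  tg <- tg / pmax(sqrt(rowSums(tg^2)), .Machine$double.eps)
  list(points = pts, tangents = tg)
}

# FWHM of one perpendicular profile (in pixels); NA when the vessel signal is
# lost (profile never crosses half-max on both sides of the peak).
profile_fwhm <- function(img, center, normal, half_len_px, step_px,
                         min_contrast) {
  u <- seq(-half_len_px, half_len_px, by = step_px)
  vals <- bilinear_sample(img, center[1] + u * normal[1],
                          center[2] + u * normal[2])
  if (mean(is.na(vals)) > 0.5) return(NA_real_)
  n <- length(u)
  tail_n <- max(2, floor(0.2 * n / 2))
  # local background per tail: a bright neighboring vessel in one tail (or a
  # tail outside the field) must not distort the other side's half-max level
  bg_l <- mean(head(vals, tail_n), na.rm = TRUE)
  bg_r <- mean(tail(vals, tail_n), na.rm = TRUE)
  if (!is.finite(bg_l)) bg_l <- bg_r
  if (!is.finite(bg_r)) bg_r <- bg_l
  bg <- suppressWarnings(min(bg_l, bg_r))
  core <- vals[u >= -half_len_px / 3 & u <= half_len_px / 3]
  if (all(is.na(core))) return(NA_real_)
  peak_val <- max(core, na.rm = TRUE)
  # unmeasurable when the peak barely rises above the local background (an
  # unfilled vessel); the floor of 10% of the background level keeps
  # filter-boundary ripples on empty frames from faking a profile
  if (!is.finite(bg) || peak_val - bg < max(min_contrast, 0.1 * abs(bg))) {
    return(NA_real_)
  }
  peak_i <- which(vals == peak_val & u >= -half_len_px / 3 &
                    u <= half_len_px / 3)[1]

  cross_out <- function(idx_seq, level) {
    prev <- peak_i
    for (i in idx_seq) {
      if (is.na(vals[i])) return(NA_real_)
      if (vals[i] < level) {
        # linear interpolation between samples prev (>= level) and i (< level)
        frac <- (vals[prev] - level) / (vals[prev] - vals[i])
        return(u[prev] + frac * (u[i] - u[prev]))
      }
      prev <- i
    }
    NA_real_
  }
  left <- cross_out(rev(seq_len(peak_i - 1)), bg_l + 0.5 * (peak_val - bg_l))
  right <- cross_out(seq(peak_i + 1, n), bg_r + 0.5 * (peak_val - bg_r))
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}

#' Measure a vessel diameter in one frame
#'
#' At sampling positions along the annotated centerline, extracts the
#' intensity profile perpendicular to the local centerline direction and
#' measures its full width at half maximum; the half-max level sits midway
#' between the local background (estimated from the outer 20% of the
#' profile) and the local peak. The segment diameter is the median over
#' positions, converted to micrometres.
#'
#' @param frame Numeric image matrix.
#' @param segment A one-row data frame (or list) with a `polyline` element
#'   (two-column pixel-coordinate matrix) and optionally `caliber_um` used to
#'   size the profile; alternatively a bare polyline matrix.
#' @param pixel_size_um Micrometres per pixel.
#' @param n_positions Number of sampling positions along the centerline.
#' @param expected_radius_px Expected vessel radius (pixels), used to size
#'   the profile (half-length = 3x the expected radius); inferred from
#'   `caliber_um` when present.
#' @param step_px Profile sampling step (pixels; sub-pixel values use
#'   bilinear interpolation).
#' @param min_contrast_frac Minimum peak-over-background contrast, as a
#'   fraction of the frame's dynamic range, below which the position is
#'   unmeasurable (signal lost, e.g. an unfilled vessel during the vascular
#'   lock).
#' @return Diameter in micrometres, or `NA` when fewer than half of the
#'   positions are measurable.
#' @export
measure_diameter <- function(frame, segment, pixel_size_um,
                             n_positions = 7, expected_radius_px = NULL,
                             step_px = 0.25, min_contrast_frac = 0.1) {
  polyline <- if (is.matrix(segment)) segment else segment$polyline[[1]]
  if (is.null(expected_radius_px)) {
    cal <- if (!is.matrix(segment) && !is.null(segment$caliber_um)) {
      segment$caliber_um[[1]]
    } else NA_real_
    expected_radius_px <- if (is.finite(cal)) cal / (2 * pixel_size_um) else 12
  }
  half_len <- max(3 * expected_radius_px, 6)
  # sample the distal 30-90% of the segment: the first third is close to the
  # branching junction, where the parent vessel pollutes the profile
  rs <- resample_polyline(polyline, max(3 * (n_positions + 2), 24))
  n_rs <- nrow(rs$points)
  pick <- unique(round(seq(0.3 * n_rs, 0.9 * n_rs, length.out = n_positions)))
  pick <- pmin(pmax(pick, 2), n_rs - 1)
  rng <- range(frame)
  min_contrast <- min_contrast_frac * (rng[2] - rng[1])
  widths <- map_dbl(pick, function(i) {
    normal <- c(-rs$tangents[i, 2], rs$tangents[i, 1])
    profile_fwhm(frame, rs$points[i, ], normal, half_len, step_px,
                 min_contrast)
  })
  if (sum(!is.na(widths)) < ceiling(n_positions / 2)) return(NA_real_)
  median(widths, na.rm = TRUE) * pixel_size_um
}

#' Diameter time course of one vessel segment
#'
#' Measures the segment diameter in every frame and normalizes it to the
#' baseline frame (default: the last frame at or before EP, i.e. the value
#' before the pulses, which in the standard protocol is 2 min after the
#' tracer injection). Frames where the vessel signal is lost (e.g. unfilled
#' during the vascular lock) are `NA`, never a spurious small diameter.
#'
#' @param sequence A `frame_sequence`.
#' @param segment Segment annotation as in [measure_diameter()].
#' @param baseline_time Baseline frame time (s); default the EP time.
#' @param ... Passed to [measure_diameter()].
#' @return A tibble of class `diameter_series` with columns `time_s`,
#'   `diameter_um`, `normalized`, and attributes `baseline_um`,
#'   `baseline_time_s`.
#' @export
diameter_timecourse <- function(sequence, segment, baseline_time = NULL, ...) {
  baseline_time <- baseline_time %||% sequence$ep_time
  d <- map_dbl(sequence$frames, measure_diameter, segment = segment,
               pixel_size_um = sequence$pixel_size_um, ...)
  at_or_before <- sequence$times <= baseline_time
  if (!any(at_or_before)) abort("no frame at or before `baseline_time`.")
  bi <- max(which(at_or_before))
  if (is.na(d[bi])) abort("baseline diameter unmeasurable; normalization undefined.")
  out <- tibble(time_s = sequence$times, diameter_um = d,
                normalized = d / d[bi])
  structure(out, baseline_um = d[bi], baseline_time_s = sequence$times[bi],
            class = c("diameter_series", class(out)))
}

#' Measure all network segments over time
#'
#' Tidy convenience wrapper around [diameter_timecourse()] for every segment
#' of a network (or an annotation table with `id`, `class`, `caliber_um`,
#' `polyline`).
#'
#' @inheritParams diameter_timecourse
#' @param network A [vessel_network()] or its `segments` tibble.
#' @return A tibble with columns `segment`, `class`, `time_s`, `diameter_um`,
#'   `normalized`, `baseline_um`.
#' @export
measure_network_diameters <- function(sequence, network = NULL,
                                      baseline_time = NULL, ...) {
  segs <- if (is.null(network)) sequence$network$segments
          else if (inherits(network, "vessel_network")) network$segments
          else as_tibble(network)
  purrr::map_dfr(seq_len(nrow(segs)), function(i) {
    ts <- tryCatch(
      diameter_timecourse(sequence, segs[i, ],
                          baseline_time = baseline_time, ...),
      error = function(e) {
        warn(sprintf("segment %s skipped: %s", segs$id[i],
                     conditionMessage(e)))
        NULL
      })
    if (is.null(ts)) return(tibble())
    tibble(segment = segs$id[i], class = segs$class[i],
           time_s = ts$time_s, diameter_um = ts$diameter_um,
           normalized = ts$normalized,
           baseline_um = attr(ts, "baseline_um"))
  })
}

#' Select stably measured segments
#'
#' Quality control mirroring how an analyst selects vessels: a segment is
#' kept when its measured diameter is available and stable (coefficient of
#' variation at most `cv_max`) over a pre-EP window in which the vessels are
#' filled and no EP effect has occurred yet. Segments measured unstably
#' there — typically because another vessel runs too close to the profile —
#' are excluded before any group averaging.
#'
#' @param diameters Tidy tibble from [measure_network_diameters()].
#' @param window `c(t0, t1)` pre-EP window (s) used to assess stability.
#' @param cv_max Maximum coefficient of variation of the measured diameter
#'   over the window.
#' @param min_keep Always keep at least this many segments (the most stable
#'   ones) even if they fail `cv_max`.
#' @return The input tibble restricted to the retained segments.
#' @export
qc_stable_segments <- function(diameters, window = c(-60, 0), cv_max = 0.05,
                               min_keep = 2) {
  stab <- diameters |>
    filter(.data$time_s >= window[1], .data$time_s <= window[2]) |>
    group_by(.data$segment) |>
    summarise(cv = if (any(is.na(.data$diameter_um))) Inf else
                sd(.data$diameter_um) / mean(.data$diameter_um),
              .groups = "drop")
  keep <- stab$segment[stab$cv <= cv_max]
  if (length(keep) < min_keep) {
    keep <- stab$segment[order(stab$cv)][seq_len(min(min_keep, nrow(stab)))]
  }
  diameters[diameters$segment %in% keep, ]
}

#' Heuristic arteriole/venule classification
#'
#' Applies the morphological convention used for these preparations: narrow,
#' straight vessels with few branches are arterioles; the rest are venules.
#' A segment is called an arteriole when its tortuosity and branch count are
#' below their thresholds AND its diameter is at most `max_arteriole_um`;
#' conflicting evidence (straight and unbranched but too wide) yields a
#' venule call flagged as low confidence. User-supplied labels always take
#' precedence over the heuristic.
#'
#' @param segments Data frame with columns `diameter_um`, `tortuosity`,
#'   `n_branches`, and optionally `label` (user-supplied labels returned
#'   as-is).
#' @param tortuosity_max Maximum tortuosity for an arteriole call.
#' @param branches_max Maximum branch count for an arteriole call.
#' @param max_arteriole_um Maximum arteriole diameter (um).
#' @return The input tibble with columns `label` and `low_confidence`.
#' @export
classify_vessel <- function(segments, tortuosity_max = 1.15,
                            branches_max = 1, max_arteriole_um = 100) {
  segs <- as_tibble(segments)
  straightish <- segs$tortuosity <= tortuosity_max &
    segs$n_branches <= branches_max
  narrow <- segs$diameter_um <= max_arteriole_um
  heur <- ifelse(straightish & narrow, "arteriole", "venule")
  low_conf <- straightish != narrow     # evidence conflicts
  if ("label" %in% names(segs)) {
    keep <- !is.na(segs$label)
    heur[keep] <- segs$label[keep]
    low_conf[keep] <- FALSE
  }
  segs$label <- heur
  segs$low_confidence <- low_conf
  segs
}
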
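# Synthetic vessel-network geometry.
#
# Coordinate convention used throughout the package: pixel coordinates are
# 0-based with x along columns and y along rows, pixel centers at integer
# coordinates; a point (x, y) addresses matrix element [y + 1, x + 1].

#' Construct a vessel network
#'
#' A vessel network is a set of labeled centerline segments with per-segment
#' caliber, embedded in a pixel raster of known physical pixel size. Networks
#' are usually produced by [generate_network()]; this constructor is for
#' building small explicit networks (e.g. a single straight test vessel).
#'
#' @param segments A data frame with one row per segment and columns `id`
#'   (integer), `class` (`"arteriole"` or `"venule"`), `caliber_um` (vessel
#'   diameter, micrometres), `parent` (integer id of the parent segment, `NA`
#'   for a root) and `polyline` (list-column of two-column `x`,`y` matrices in
#'   pixel coordinates, at least 2 vertices each).
#' @param field_px Integer vector `c(rows, cols)`: raster size in pixels.
#' @param pixel_size_um Physical pixel size, micrometres per pixel.
#' @param caliber_range_um Named list with elements `arteriole` and `venule`,
#'   each `c(min, max)` in micrometres; segment calibers must lie inside the
#'   range for their class. Defaults to the conventional caliber windows for
#'   skin arterioles (10-100 um) and venules (20-250 um).
#'
#' @return An object of class `vessel_network`: a list with elements
#'   `segments` (tibble as above, plus `tortuosity` and `n_children`),
#'   `field_px` and `pixel_size_um`.
#' @export
vessel_network <- function(segments, field_px, pixel_size_um,
                           caliber_range_um = list(arteriole = c(10, 100),
                                                   venule = c(20, 250))) {
  segments <- as_tibble(segments)
  stopifnot(all(c("id", "class", "caliber_um", "polyline") %in% names(segments)))
  if (!"parent" %in% names(segments)) segments$parent <- NA_integer_
  if (length(field_px) == 1) field_px <- c(field_px, field_px)
  field_px <- as.integer(field_px)
  if (any(field_px < 2)) abort("`field_px` must be at least 2x2.")
  if (!all(segments$class %in% c("arteriole", "venule"))) {
    abort("segment `class` must be 'arteriole' or 'venule'.")
  }
  for (cls in unique(segments$class)) {
    rng <- caliber_range_um[[cls]]
    cal <- segments$caliber_um[segments$class == cls]
    if (any(cal < rng[1] | cal > rng[2])) {
      abort(sprintf("%s calibers must lie in [%g, %g] um.", cls, rng[1], rng[2]))
    }
  }
  for (pl in segments$polyline) {
    if (!is.matrix(pl) || nrow(pl) < 2 || ncol(pl) != 2) {
      abort("each polyline must be a matrix with >= 2 rows and columns x, y.")
    }
    if (any(pl[, 1] < 0 | pl[, 1] > field_px[2] - 1 |
            pl[, 2] < 0 | pl[, 2] > field_px[1] - 1)) {
      abort("polyline vertices must lie inside the field.")
    }
  }
  segments$tortuosity <- map_dbl(segments$polyline, polyline_tortuosity)
  segments$n_children <- map_dbl(segments$id, function(i) {
    sum(!is.na(segments$parent) & segments$parent == i)
  })
  structure(
    list(segments = segments, field_px = field_px,
         pixel_size_um = pixel_size_um, caliber_range_um = caliber_range_um),
    class = "vessel_network"
  )
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("<vessel_network> %d segments (%d arterioles, %d venules), field %dx%d px @ %g um/px\n",
              nrow(x$segments), sum(x$segments$class == "arteriole"),
              sum(x$segments$class == "venule"),
              x$field_px[1], x$field_px[2], x$pixel_size_um))
  print(dplyr::select(x$segments, -"polyline"))
  invisible(x)
}

#' Tortuosity of a polyline
#'
#' Arc length divided by chord length; 1 for a straight segment.
#'
#' @param polyline Two-column `x`,`y` matrix.
#' @return A scalar >= 1.
#' @export
polyline_tortuosity <- function(polyline) {
  d <- diff(polyline)
  arc <- sum(sqrt(rowSums(d^2)))
  chord <- sqrt(sum((polyline[nrow(polyline), ] - polyline[1, ])^2))
  if (chord == 0) return(Inf)
  arc / chord
}

#' Generate a random branching vessel network
#'
#' Builds a connected network emulating the vasculature seen through a dorsal
#' window chamber: a tortuous venular trunk crossing the field, additional
#' venules branching off existing segments, and straighter, narrower
#' arterioles. Calibers are drawn uniformly within per-class windows that sit
#' inside the conventional caliber ranges (arterioles 10-100 um, venules
#' 20-250 um).
#'
#' @param n_arterioles,n_venules Number of segments of each class (both >= 1).
#' @param field_px Raster size `c(rows, cols)`, at least 128 pixels each way.
#' @param pixel_size_um Micrometres per pixel.
#' @param caliber_draw_um Named list `arteriole`/`venule` of `c(min, max)`
#'   sampling windows for calibers (micrometres). The defaults keep vessels
#'   well resolved yet small relative to a desk-scale field.
#' @param seed Optional integer seed; the same seed yields an identical
#'   network.
#'
#' @return A [vessel_network()].
#' @export
generate_network <- function(n_arterioles = 5, n_venules = 5,
                             field_px = c(192, 192), pixel_size_um = 2,
                             caliber_draw_um = list(arteriole = c(12, 28),
                                                    venule = c(20, 45)),
                             seed = NULL) {
  if (length(field_px) == 1) field_px <- c(field_px, field_px)
  if (any(field_px < 128)) abort("`field_px` must be at least 128x128.")
  if (n_arterioles < 1 || n_venules < 1) {
    abort("at least one segment of each class must be requested.")
  }
  build <- function() {
    H <- field_px[1]; W <- field_px[2]

    segs <- vector("list", n_arterioles + n_venules)
    classes <- c(rep("venule", n_venules), rep("arteriole", n_arterioles))
    parents <- rep(NA_integer_, length(segs))
    caliber <- map_dbl(classes, function(cls) {
      runif(1, caliber_draw_um[[cls]][1], caliber_draw_um[[cls]][2])
    })
    # keep each centerline one radius plus a guard away from the border so
    # the rendered ribbon (and measurement profiles) stay inside the field
    margins <- caliber / (2 * pixel_size_um) + 4

    clampx <- function(v, m) pmin(pmax(v, m), W - 1 - m)
    clampy <- function(v, m) pmin(pmax(v, m), H - 1 - m)

    wiggly <- function(from, heading, step, n_pts, m,
                       jitter = 25 * pi / 180) {
      pts <- matrix(NA_real_, n_pts, 2)
      pts[1, ] <- from
      for (k in 2:n_pts) {
        heading <- heading + runif(1, -jitter, jitter)
        pts[k, ] <- pts[k - 1, ] + step * c(cos(heading), sin(heading))
      }
      cbind(clampx(pts[, 1], m), clampy(pts[, 2], m))
    }
    straightish <- function(from, heading, len, m) {
      ends <- from + len * c(cos(heading), sin(heading))
      mid <- (from + ends) / 2 + runif(2, -1, 1)
      pts <- rbind(from, mid, ends)
      cbind(clampx(pts[, 1], m), clampy(pts[, 2], m))
    }
    anchor_on <- function(polyline) {
      # random point along the polyline, linear interpolation between vertices
      k <- sample(nrow(polyline) - 1, 1)
      a <- runif(1)
      polyline[k, ] * (1 - a) + polyline[k + 1, ] * a
    }

    # venular trunk crossing the field left to right
    m1 <- margins[1]
    y0 <- runif(1, 0.3, 0.7) * H
    trunk <- wiggly(c(m1, clampy(y0, m1)), heading = runif(1, -0.2, 0.2),
                    step = (W - 2 * m1) / 5, n_pts = 6, m = m1)
    trunk[nrow(trunk), 1] <- W - 1 - m1
    segs[[1]] <- trunk

    radius_px <- caliber / (2 * pixel_size_um)
    # clearance score of a candidate against existing segments: minimum of
    # (centerline distance - required ribbon separation) over the candidate
    # points beyond the branching junction; >= 0 means no ribbon overlap
    clearance <- function(pl, i, parent) {
      pts <- densify_polyline(pl, spacing = 3)
      arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
      junction <- radius_px[i] + radius_px[parent] + 6
      far <- pts[arc > junction, , drop = FALSE]
      if (nrow(far) == 0) return(-Inf)
      score <- Inf
      for (j in seq_len(i - 1)) {
        need <- radius_px[i] + radius_px[j] + 4
        dd <- min(dist_points_to_polyline(far, segs[[j]]))
        score <- min(score, dd - need)
      }
      score
    }

    for (i in seq_along(segs)[-1]) {
      best <- NULL; best_parent <- 1L; best_score <- -Inf
      for (try in seq_len(40)) {
        parent <- sample(i - 1, 1)
        from <- anchor_on(segs[[parent]])
        from <- c(clampx(from[1], margins[i]), clampy(from[2], margins[i]))
        heading <- runif(1, 0, 2 * pi)
        cand <- if (classes[i] == "arteriole") {
          straightish(from, heading, len = runif(1, 0.35, 0.6) * min(H, W),
                      m = margins[i])
        } else {
          wiggly(from, heading, step = min(H, W) / 7,
                 n_pts = sample(4:6, 1), m = margins[i])
        }
        sc <- clearance(cand, i, parent)
        if (sc > best_score) {
          best <- cand; best_parent <- parent; best_score <- sc
        }
        if (best_score >= 0) break
      }
      segs[[i]] <- best
      parents[i] <- best_parent
    }
    vessel_network(
      tibble(id = seq_along(segs), class = classes, caliber_um = caliber,
             parent = parents, polyline = segs),
      field_px = field_px, pixel_size_um = pixel_size_um
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# Points along a polyline at roughly `spacing` pixel intervals.
densify_polyline <- function(polyline, spacing = 3) {
  d <- sqrt(rowSums(diff(polyline)^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  si <- seq(0, total, length.out = max(2, ceiling(total / spacing) + 1))
  cbind(approx(s, polyline[, 1], xout = si, ties = "ordered")$y,
        approx(s, polyline[, 2], xout = si, ties = "ordered")$y)
}

# Minimum distance from each point (rows of `pts`) to a polyline.
dist_points_to_polyline <- function(pts, polyline) {
  d2 <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(polyline) - 1)) {
    p <- polyline[k, ]; q <- polyline[k + 1, ]
    vx <- q[1] - p[1]; vy <- q[2] - p[2]
    L2 <- vx * vx + vy * vy
    if (L2 == 0) {
      dx <- pts[, 1] - p[1]; dy <- pts[, 2] - p[2]
    } else {
      tt <- pmin(pmax(((pts[, 1] - p[1]) * vx + (pts[, 2] - p[2]) * vy) / L2, 0), 1)
      dx <- pts[, 1] - (p[1] + tt * vx); dy <- pts[, 2] - (p[2] + tt * vy)
    }
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Distance field to a polyline
#'
#' Minimum Euclidean distance (pixels) from every pixel center to a polyline,
#' computed by exact point-to-segment projection on each edge.
#'
#' @param polyline Two-column `x`,`y` matrix in 0-based pixel coordinates.
#' @param dim Raster size `c(rows, cols)`.
#' @return A `dim[1]` x `dim[2]` numeric matrix of distances.
#' @export
polyline_distance_field <- function(polyline, dim) {
  H <- dim[1]; W <- dim[2]
  px <- rep(0:(W - 1), each = H)
  py <- rep.int(0:(H - 1), W)
  d2 <- rep(Inf, H * W)
  for (k in seq_len(nrow(polyline) - 1)) {
    p <- polyline[k, ]; q <- polyline[k + 1, ]
    vx <- q[1] - p[1]; vy <- q[2] - p[2]
    L2 <- vx * vx + vy * vy
    if (L2 == 0) {
      dx <- px - p[1]; dy <- py - p[2]
    } else {
      tt <- ((px - p[1]) * vx + (py - p[2]) * vy) / L2
      tt <- pmin(pmax(tt, 0), 1)
      dx <- px - (p[1] + tt * vx); dy <- py - (p[2] + tt * vy)
    }
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  matrix(sqrt(d2), H, W)
}
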
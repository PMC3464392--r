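# Shared fixtures and independent oracles, built in code at test time.

# Single straight vessel crossing a field at a given orientation.
straight_vessel_network <- function(caliber_um = 50, pixel_size_um = 2,
                                    field_px = c(128, 128),
                                    orientation_deg = 0) {
  H <- field_px[1]; W <- field_px[2]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  th <- orientation_deg * pi / 180
  r <- 0.38 * min(H, W)
  pl <- rbind(c(cx - r * cos(th), cy - r * sin(th)),
              c(cx, cy),
              c(cx + r * cos(th), cy + r * sin(th)))
  vessel_network(
    tibble::tibble(id = 1L, class = "venule", caliber_um = caliber_um,
                   parent = NA_integer_, polyline = list(pl)),
    field_px = field_px, pixel_size_um = pixel_size_um
  )
}

# Brute-force rasterization oracle: a pixel is vascular iff its distance to
# the nearest of a dense sampling of centerline points is <= radius.
# Independent of the edge-projection route used by the package.
brute_force_mask <- function(polyline, radius_px, dim, spacing = 0.05) {
  d <- sqrt(rowSums(diff(polyline)^2))
  s <- c(0, cumsum(d))
  si <- seq(0, s[length(s)], by = spacing)
  xs <- approx(s, polyline[, 1], xout = si, ties = "ordered")$y
  ys <- approx(s, polyline[, 2], xout = si, ties = "ordered")$y
  H <- dim[1]; W <- dim[2]
  m <- matrix(FALSE, H, W)
  for (col in seq_len(W)) {
    dx2 <- (xs - (col - 1))^2
    for (row in seq_len(H)) {
      if (min(dx2 + (ys - (row - 1))^2) <= radius_px^2) m[row, col] <- TRUE
    }
  }
  m
}

# Minimal hand-built frame sequence (list of matrices + metadata).
toy_sequence <- function(frames, times, injection_time = -120, ep_time = 0,
                         pixel_size_um = 2) {
  structure(list(frames = frames, times = times,
                 injection_time = injection_time, ep_time = ep_time,
                 pixel_size_um = pixel_size_um, bit_depth = 16, seed = NULL),
            class = "frame_sequence")
}

# Memoised expensive fixtures shared across test files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

control_sequence <- function() {
  fixture("control_seq", function() {
    simulate_angiography("control", seed = 42)
  })
}

noiseless_control_sequence <- function() {
  fixture("noiseless_control_seq", function() {
    simulate_angiography("control", seed = 42, snr = Inf)
  })
}
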
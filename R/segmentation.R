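# Vessel-network mask construction: split every frame into a vascular and a
# tissue compartment.

#' Build the blood-vessel-network mask
#'
#' Computes a temporal maximum-intensity projection over a user-designated
#' reference window of post-fill frames, smooths it, optionally removes
#' smooth background with a morphological white top-hat (tubular structures
#' survive, slowly varying background does not), thresholds with Otsu's
#' method, removes small components and fills holes. The threshold is
#' data-adaptive, so the mask is invariant to adding a constant offset to all
#' frames.
#'
#' @param sequence A `frame_sequence` (see [render_sequence()] /
#'   [read_stack()]).
#' @param reference_window `c(t0, t1)` in seconds: frames with
#'   `t0 <= time <= t1` enter the projection. Default: the last three frames
#'   of the sequence, which in the default protocol lie well after fill
#'   completion.
#' @param smooth_sigma_px Gaussian smoothing sd applied to the projection.
#' @param enhance `"none"` or `"tophat"` (white top-hat background removal).
#' @param tophat_radius_px Structuring-disc radius for the top-hat; should
#'   exceed the largest vessel radius in pixels.
#' @param min_size_px Connected components smaller than this are removed.
#' @param fill_holes Fill enclosed holes in the mask.
#' @param min_contrast_mads Empty-field guard: if the projection's 99th
#'   percentile exceeds its median by less than this many MADs, no vessel
#'   signal is present and an empty mask is returned with a warning.
#' @param exclusion Optional logical matrix of pixels to exclude from the
#'   vascular mask (e.g. hair or glass artifacts).
#'
#' @return An object of class `vessel_mask`: list with `mask` (logical
#'   matrix), `n_vascular`, `n_tissue` and `provenance` (frames and
#'   parameters used).
#' @export
build_mask <- function(sequence, reference_window = NULL,
                       smooth_sigma_px = 2,
                       enhance = c("none", "tophat"), tophat_radius_px = 31,
                       min_size_px = 20, fill_holes = TRUE,
                       min_contrast_mads = 5, exclusion = NULL) {
  enhance <- match.arg(enhance)
  times <- sequence$times
  if (is.null(reference_window)) {
    reference_window <- c(times[max(1, length(times) - 2)], times[length(times)])
  }
  idx <- which(times >= reference_window[1] & times <= reference_window[2])
  if (length(idx) == 0) {
    abort("`reference_window` selects no frames of the sequence.")
  }
  proj <- Reduce(pmax, sequence$frames[idx])
  if (smooth_sigma_px > 0) proj <- EBImage::gblur(proj, sigma = smooth_sigma_px)
  if (enhance == "tophat") {
    brush <- EBImage::makeBrush(2 * tophat_radius_px + 1, shape = "disc")
    proj <- proj - EBImage::opening(proj, brush)
    proj <- pmax(proj, 0)
  }

  prov <- list(frames = idx, reference_window = reference_window,
               smooth_sigma_px = smooth_sigma_px, enhance = enhance,
               min_size_px = min_size_px, fill_holes = fill_holes)

  med <- median(proj)
  spread <- quantile(proj, 0.99) - med
  # noise scale from the below-median (background) pixels only, so that a
  # large vascular fraction cannot inflate it
  noise <- mad(proj[proj <= med], center = med)
  if (spread < min_contrast_mads * max(noise, .Machine$double.eps)) {
    warn("no pixel exceeds the background margin; returning an empty mask.")
    m <- matrix(FALSE, nrow(proj), ncol(proj))
    return(new_vessel_mask(m, c(prov, list(threshold = NA_real_))))
  }

  thr <- EBImage::otsu(proj, range = range(proj))
  m <- proj > thr
  if (min_size_px > 0) {
    lab <- EBImage::bwlabel(m)
    keep <- which(tabulate(lab[lab > 0]) >= min_size_px)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  if (fill_holes) m <- EBImage::fillHull(m) > 0
  if (!is.null(exclusion)) m <- m & !exclusion
  new_vessel_mask(m, c(prov, list(threshold = as.numeric(thr))))
}

new_vessel_mask <- function(mask, provenance = list()) {
  structure(list(mask = mask, n_vascular = sum(mask),
                 n_tissue = sum(!mask), provenance = provenance),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %dx%d px: %d vascular, %d tissue (%.1f%% vascular)\n",
              nrow(x$mask), ncol(x$mask), x$n_vascular, x$n_tissue,
              100 * x$n_vascular / length(x$mask)))
  invisible(x)
}

as_mask_matrix <- function(x) {
  if (inherits(x, "vessel_mask")) x$mask
  else if (is.matrix(x)) x > 0
  else abort("expected a `vessel_mask` or a matrix.")
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)` between two binary masks; defined as 1 when both
#' masks are empty.
#'
#' @param maskA,maskB `vessel_mask` objects or logical matrices of identical
#'   shape.
#' @return A fraction in `[0, 1]`.
#' @export
dice <- function(maskA, maskB) {
  a <- as_mask_matrix(maskA); b <- as_mask_matrix(maskB)
  if (!all(dim(a) == dim(b))) abort("mask shapes differ.")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
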
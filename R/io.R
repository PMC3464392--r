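# File formats: multi-page TIFF stacks with plain-text sidecar metadata,
# single-page TIFF masks, CSV segment annotations and result tables.

#' Write an image sequence to disk
#'
#' Writes `<base>.tif` (one page per frame, quantized at the sequence bit
#' depth), `<base>_frames.tsv` (frame index and time) and `<base>_meta.tsv`
#' (key/value pairs: pixel size, event times, bit depth, seed). The write
#' is lossless: [read_stack()] reproduces pixel data and timestamps exactly.
#'
#' @param sequence A `frame_sequence`.
#' @param base Output path without extension.
#' @return `base`, invisibly.
#' @export
write_stack <- function(sequence, base) {
  bits <- sequence$bit_depth %||% 16
  tiff::writeTIFF(sequence$frames, paste0(base, ".tif"),
                  bits.per.sample = bits)
  frames <- data.frame(frame = seq_along(sequence$times),
                       time_s = sequence$times)
  write.table(frames, paste0(base, "_frames.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- data.frame(
    key = c("pixel_size_um", "injection_time_s", "ep_time_s", "bit_depth",
            "seed"),
    value = c(sequence$pixel_size_um, sequence$injection_time,
              sequence$ep_time, bits, sequence$seed %||% NA)
  )
  write.table(meta, paste0(base, "_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(base)
}

#' Read an image sequence from disk
#'
#' Counterpart of [write_stack()]. Validates that the number of TIFF pages
#' matches the number of sidecar timestamps, that timestamps are strictly
#' increasing, and that a pixel size is present.
#'
#' @param base Path prefix used by [write_stack()].
#' @return A `frame_sequence` (without network/ground-truth elements).
#' @export
read_stack <- function(base) {
  pages <- tiff::readTIFF(paste0(base, ".tif"), all = TRUE)
  frames <- utils::read.delim(paste0(base, "_frames.tsv"))
  meta <- utils::read.delim(paste0(base, "_meta.tsv"))
  meta_val <- function(key) {
    v <- meta$value[meta$key == key]
    if (length(v) == 0 || is.na(v)) NULL else as.numeric(v)
  }
  if (length(pages) != nrow(frames)) {
    abort(sprintf("stack has %d frames but sidecar lists %d timestamps.",
                  length(pages), nrow(frames)))
  }
  if (any(diff(frames$time_s) <= 0)) {
    abort("sidecar timestamps are not strictly increasing.")
  }
  px <- meta_val("pixel_size_um")
  if (is.null(px)) abort("sidecar is missing `pixel_size_um`; diameters would be unitless.")
  structure(
    list(frames = pages, times = frames$time_s,
         injection_time = meta_val("injection_time_s") %||% NA_real_,
         ep_time = meta_val("ep_time_s") %||% 0,
         pixel_size_um = px, bit_depth = meta_val("bit_depth") %||% 16,
         seed = meta_val("seed")),
    class = "frame_sequence"
  )
}

#' Write / read a vessel mask
#'
#' Single-page TIFF (0/1) plus a plain-text provenance file.
#'
#' @param mask A `vessel_mask`.
#' @param base Path prefix.
#' @return `base` invisibly; `read_mask()` returns a `vessel_mask`.
#' @export
write_mask <- function(mask, base) {
  tiff::writeTIFF(mask$mask * 1, paste0(base, ".tif"), bits.per.sample = 8)
  prov <- mask$provenance
  lines <- vapply(names(prov), function(k) {
    sprintf("%s\t%s", k, paste(format(prov[[k]]), collapse = ","))
  }, character(1))
  writeLines(lines, paste0(base, "_provenance.tsv"))
  invisible(base)
}

#' @rdname write_mask
#' @export
read_mask <- function(base) {
  m <- tiff::readTIFF(paste0(base, ".tif")) > 0.5
  new_vessel_mask(m, list(source = paste0(base, ".tif")))
}

#' Write / read segment annotations as CSV
#'
#' One row per polyline vertex: `segment`, `label`, `caliber_um`, `x`, `y`
#' (0-based pixel coordinates), so annotations can be authored in any
#' external viewer.
#'
#' @param segments A [vessel_network()] or its `segments` tibble.
#' @param path CSV path.
#' @return `path` invisibly; `read_segments()` returns a segments tibble
#'   usable with [measure_network_diameters()].
#' @export
write_segments <- function(segments, path) {
  segs <- if (inherits(segments, "vessel_network")) segments$segments
          else as_tibble(segments)
  rows <- purrr::map_dfr(seq_len(nrow(segs)), function(i) {
    pl <- segs$polyline[[i]]
    tibble(segment = segs$id[i], label = segs$class[i],
           caliber_um = segs$caliber_um[i], x = pl[, 1], y = pl[, 2])
  })
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  rows <- read.csv(path)
  rows |>
    group_by(.data$segment) |>
    summarise(class = .data$label[1], caliber_um = .data$caliber_um[1],
              polyline = list(cbind(x = .data$x, y = .data$y)),
              .groups = "drop") |>
    dplyr::rename(id = "segment")
}
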
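#' Multi-channel image stack
#'
#' Lightweight container for multi-channel (optionally z-stacked) pixel data
#' with a physical pixel size. Pixels are stored as a 4-D array indexed
#' `[y, x, z, channel]`; all intensities must be non-negative and all
#' channels share dimensions. Pixel coordinates reported by measurement
#' functions are 0-based `(row, column)`.
#'
#' @param pixels a 2-D matrix (one channel, one plane), 3-D array
#'   `[y, x, channel]`, or 4-D array `[y, x, z, channel]` of non-negative
#'   intensities.
#' @param channels unique channel names; the roles `DAPI`, `MARKER` and
#'   `CELLBODY` are recognized by the pipeline.
#' @param pixel_size_um physical pixel size in um/pixel, or `NA` when
#'   unknown (areas are then reported in px^2 only).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, channels, pixel_size_um = NA_real_) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L, 1L)
  else if (length(dim(pixels)) == 3L) {
    d <- dim(pixels); dim(pixels) <- c(d[1], d[2], 1L, d[3])
  } else if (length(dim(pixels)) != 4L)
    stopf("'pixels' must be a 2-, 3- or 4-D array")
  if (length(channels) != dim(pixels)[4])
    stopf("length(channels) must match the channel dimension")
  if (anyDuplicated(channels)) stopf("channel names must be unique")
  if (any(pixels < 0)) stopf("intensities must be non-negative")
  if (!is.na(pixel_size_um)) check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  structure(list(pixels = pixels, channels = as.character(channels),
                 pixel_size_um = pixel_size_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image_stack: %d x %d px, %d z-plane(s), channels [%s], pixel %s um\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ", "),
              ifelse(is.na(x$pixel_size_um), "NA", format(x$pixel_size_um))))
  invisible(x)
}

#' Extract one channel plane as a matrix
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @param z z-plane (defaults to 1; the stack must be projected first if it
#'   has several planes and no `z` is given).
#' @return A numeric matrix `[y, x]`.
#' @export
get_channel <- function(stack, channel, z = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  ci <- match(channel, stack$channels)
  if (is.na(ci)) stopf("channel '%s' not present", channel)
  nz <- dim(stack$pixels)[3]
  if (is.null(z)) {
    if (nz > 1L) stopf("stack has %d z-planes; use max_project() or give z", nz)
    z <- 1L
  }
  if (z < 1L || z > nz) stopf("z out of range")
  stack$pixels[, , z, ci]
}

#' Maximum-intensity projection over z
#'
#' Reduces a z-stack to a single plane per channel by the pointwise maximum
#' over z. Identity for single-plane stacks, hence idempotent.
#'
#' @param stack an [image_stack()].
#' @return An [image_stack()] with one z-plane.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  if (d[3] == 1L) return(stack)
  out <- array(0, dim = c(d[1], d[2], 1L, d[4]))
  for (ci in seq_len(d[4])) {
    m <- stack$pixels[, , 1L, ci]
    for (z in 2:d[3]) m <- pmax(m, stack$pixels[, , z, ci])
    out[, , 1L, ci] <- m
  }
  image_stack(out, stack$channels, stack$pixel_size_um)
}

# Scale factor used when writing counts into [0,1]-ranged float TIFF pages.
TIFF_SCALE <- 65536

#' Write an image stack as a multi-page TIFF
#'
#' Pages are written channel-major (all z of channel 1, then channel 2, ...)
#' as 32-bit float, with intensities divided by a fixed scale so they fit
#' the \[0, 1\] storage range. Channel names, z-count, pixel size and the
#' scale are recorded in a JSON sidecar (`<path>.json`), which
#' [read_stack()] uses to reconstruct the stack; round-trip is exact to
#' float32 precision.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  if (max(stack$pixels) > TIFF_SCALE)
    stopf("intensities exceed the storage scale (%g)", TIFF_SCALE)
  pages <- list()
  for (ci in seq_len(d[4])) for (z in seq_len(d[3]))
    pages[[length(pages) + 1L]] <- stack$pixels[, , z, ci] / TIFF_SCALE
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(channels = stack$channels, n_z = d[3],
               pixel_size_um = stack$pixel_size_um, scale = TIFF_SCALE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' If the JSON sidecar written by [write_stack()] is present it supplies the
#' channel layout, z-count, pixel size and intensity scale. Otherwise
#' `channel_map` must assign channel roles to pages (e.g.
#' `c(DAPI = 1, MARKER = 2)`); a `DAPI` role is required.
#'
#' @param path TIFF path.
#' @param channel_map named integer vector mapping channel names to page
#'   indices (ignored when a sidecar exists).
#' @param pixel_size_um pixel size override when no sidecar exists.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_map = NULL, pixel_size_um = NA_real_) {
  if (!file.exists(path)) stopf("cannot read '%s'", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("read_stack: inconsistent dimensions across TIFF pages")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    channels <- meta$channels
    n_z <- meta$n_z
    scale <- meta$scale %||% 1
    pixel_size_um <- meta$pixel_size_um %||% NA_real_
    if (length(pages) != n_z * length(channels))
      stopf("read_stack: page count does not match sidecar metadata")
  } else {
    if (is.null(channel_map) || is.null(names(channel_map)))
      stopf("read_stack: no sidecar metadata; a named 'channel_map' is required")
    channels <- names(channel_map)
    pages <- pages[as.integer(channel_map)]
    n_z <- 1L
    scale <- 1
  }
  if (!"DAPI" %in% channels)
    stopf("read_stack: missing DAPI channel")
  H <- dims[1, 1]; W <- dims[2, 1]
  pix <- array(0, dim = c(H, W, n_z, length(channels)))
  k <- 1L
  for (ci in seq_along(channels)) for (z in seq_len(n_z)) {
    pix[, , z, ci] <- pages[[k]] * scale
    k <- k + 1L
  }
  if (!is.null(pixel_size_um) && length(pixel_size_um) == 0) pixel_size_um <- NA_real_
  image_stack(pix, channels, pixel_size_um)
}

#' Write a label map as a 16-bit single-page TIFF
#'
#' @param labels integer label matrix (0 = background).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  if (max(labels) > 65535L) stopf("more than 65535 labels cannot be stored")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#'
#' @param path TIFF path.
#' @return An integer label matrix.
#' @export
read_label_map <- function(path) {
  m <- tiff::readTIFF(path)
  storage.mode(m) <- "double"
  lab <- as_mat(round(m * 65535))
  storage.mode(lab) <- "integer"
  lab
}

#' Write per-nucleus and per-cell tables plus a summary JSON
#'
#' @param nucleus_records per-nucleus data frame (see [measure_nuclei()]).
#' @param cell_records per-cell data frame (see [aggregate_cells()]).
#' @param summary a list (e.g. a classification summary) serialized to JSON.
#' @param out_dir output directory, created if needed.
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(nucleus_records, cell_records, summary, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory '%s'", out_dir)
  files <- c(nuclei = file.path(out_dir, "nuclei.csv"),
             cells = file.path(out_dir, "cells.csv"),
             summary = file.path(out_dir, "summary.json"))
  write.csv(nucleus_records, files[["nuclei"]], row.names = FALSE)
  write.csv(cell_records, files[["cells"]], row.names = FALSE)
  jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(files)
}
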
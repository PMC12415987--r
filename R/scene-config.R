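#' Configuration for a synthetic microscopy scene
#'
#' Bundles all knobs of the synthetic fluorescence-microscopy generator into
#' a validated list. A scene emulates one confocal field of DAPI-stained
#' cultured cells: a vehicle-like population of mononucleated cells with
#' log-normally distributed nuclear areas, optionally mixed with giant cells
#' (linear nuclear radius scaled by `giant_scale`) and multinucleated cells
#' (2 or more nuclei inside one cell body). The three rendered channels are
#' `DAPI` (nuclei), `MARKER` (a translocating or focus-forming protein, e.g.
#' NF-kB p65 or gamma-H2AX) and `CELLBODY` (a GFP-like whole-cell stain).
#'
#' Giant and multinucleated subsets are drawn independently, so a cell can be
#' both. Per-scene composition uses exact counts (`round(fraction * n_cells)`)
#' with uniformly sampled membership, so the planted fractions are not
#' confounded with binomial sampling noise.
#'
#' @param image_height_px,image_width_px scene size in pixels.
#' @param pixel_size_um physical pixel size, um/pixel.
#' @param n_cells number of cells to place (rejection sampling, no overlap).
#' @param vehicle_area_mean_um2 mean nuclear area of the vehicle population
#'   (um^2); the area distribution is log-normal.
#' @param vehicle_area_cv coefficient of variation of the vehicle nuclear
#'   area, in (0, 1).
#' @param giant_fraction fraction of cells flagged giant.
#' @param giant_scale multiplier (> 1) on the linear nuclear radius of giant
#'   cells; the default 2 gives ~4x area.
#' @param mnc_fraction fraction of cells that are multinucleated.
#' @param mnc_nuclei_range integer pair (min >= 2) giving the range of nuclei
#'   per multinucleated cell.
#' @param marker_ratio planted nuclear:cytosolic mean-intensity ratio on the
#'   MARKER channel.
#' @param foci_lambda Poisson mean number of foci planted per nucleus.
#' @param foci_sigma_px Gaussian sigma (pixels) of a rendered focus.
#' @param dapi_level,cytosol_level,cellbody_level noise-free rendering
#'   intensities (camera counts) of nuclei on DAPI, of the cytosol on MARKER,
#'   and of the cell body on CELLBODY. Focus peak amplitude is fixed at
#'   5 x `cytosol_level` so planted foci are unambiguous ground truth.
#' @param background_level camera offset added everywhere.
#' @param gaussian_noise_sd read-noise SD (counts), applied after shot noise.
#' @param poisson_noise apply Poisson shot noise to the noise-free counts?
#' @param n_z number of z-planes; planes repeat the same noise-free scene
#'   with independent per-plane noise.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   scenes.
#'
#' @return A validated list of class `scene_config`.
#' @seealso [generate_scene()], [generate_population()]
#' @export
scene_config <- function(image_height_px = 900L,
                         image_width_px = 900L,
                         pixel_size_um = 0.25,
                         n_cells = 35L,
                         vehicle_area_mean_um2 = 100,
                         vehicle_area_cv = 0.1,
                         giant_fraction = 0,
                         giant_scale = 2,
                         mnc_fraction = 0,
                         mnc_nuclei_range = c(2L, 4L),
                         marker_ratio = 1,
                         foci_lambda = 0,
                         foci_sigma_px = 2,
                         dapi_level = 120,
                         cytosol_level = 40,
                         cellbody_level = 80,
                         background_level = 5,
                         gaussian_noise_sd = 2,
                         poisson_noise = TRUE,
                         n_z = 1L,
                         seed = 1L) {
  check_scalar(image_height_px, "image_height_px", positive = TRUE, integer = TRUE)
  check_scalar(image_width_px, "image_width_px", positive = TRUE, integer = TRUE)
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  check_scalar(n_cells, "n_cells", nonneg = TRUE, integer = TRUE)
  check_scalar(vehicle_area_mean_um2, "vehicle_area_mean_um2", positive = TRUE)
  check_scalar(vehicle_area_cv, "vehicle_area_cv")
  if (vehicle_area_cv <= 0 || vehicle_area_cv >= 1)
    stopf("'vehicle_area_cv' must lie in (0, 1)")
  check_fraction(giant_fraction, "giant_fraction")
  check_fraction(mnc_fraction, "mnc_fraction")
  check_scalar(giant_scale, "giant_scale")
  if (giant_scale <= 1) stopf("'giant_scale' must be > 1")
  if (length(mnc_nuclei_range) != 2L || any(mnc_nuclei_range != round(mnc_nuclei_range)) ||
      mnc_nuclei_range[1] < 2L || mnc_nuclei_range[2] < mnc_nuclei_range[1])
    stopf("'mnc_nuclei_range' must be an integer pair (min >= 2, max >= min)")
  check_scalar(marker_ratio, "marker_ratio", positive = TRUE)
  check_scalar(foci_lambda, "foci_lambda", nonneg = TRUE)
  check_scalar(foci_sigma_px, "foci_sigma_px", positive = TRUE)
  check_scalar(dapi_level, "dapi_level", positive = TRUE)
  check_scalar(cytosol_level, "cytosol_level", positive = TRUE)
  check_scalar(cellbody_level, "cellbody_level", positive = TRUE)
  check_scalar(background_level, "background_level", nonneg = TRUE)
  check_scalar(gaussian_noise_sd, "gaussian_noise_sd", nonneg = TRUE)
  stopifnot(is.logical(poisson_noise), length(poisson_noise) == 1L)
  check_scalar(n_z, "n_z", positive = TRUE, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)

  structure(list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_size_um = pixel_size_um,
    n_cells = as.integer(n_cells),
    vehicle_area_mean_um2 = vehicle_area_mean_um2,
    vehicle_area_cv = vehicle_area_cv,
    giant_fraction = giant_fraction,
    giant_scale = giant_scale,
    mnc_fraction = mnc_fraction,
    mnc_nuclei_range = as.integer(mnc_nuclei_range),
    marker_ratio = marker_ratio,
    foci_lambda = foci_lambda,
    foci_sigma_px = foci_sigma_px,
    dapi_level = dapi_level,
    cytosol_level = cytosol_level,
    cellbody_level = cellbody_level,
    background_level = background_level,
    gaussian_noise_sd = gaussian_noise_sd,
    poisson_noise = isTRUE(poisson_noise),
    n_z = as.integer(n_z),
    seed = as.integer(seed)
  ), class = "scene_config")
}

#' Modify a scene configuration
#'
#' Returns a copy of `config` with the named fields replaced, re-validated.
#'
#' @param config a [scene_config()] object.
#' @param ... fields to replace.
#' @return A new `scene_config`.
#' @export
update_config <- function(config, ...) {
  stopifnot(inherits(config, "scene_config"))
  do.call(scene_config, modifyList(unclass(config), list(...)))
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("scene_config: %dx%d px (%.3g um/px), %d cells, seed %d\n",
              x$image_height_px, x$image_width_px, x$pixel_size_um,
              x$n_cells, x$seed))
  cat(sprintf("  giant %.0f%% (scale %.2g), mnc %.0f%% (%d-%d nuclei), ratio %.2g, foci lambda %.2g\n",
              100 * x$giant_fraction, x$giant_scale, 100 * x$mnc_fraction,
              x$mnc_nuclei_range[1], x$mnc_nuclei_range[2],
              x$marker_ratio, x$foci_lambda))
  invisible(x)
}
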
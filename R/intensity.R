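#' Foci-detection parameters
#'
#' Defaults target diffraction-limited spots rendered at sigma ~2 px:
#' Laplacian-of-Gaussian band-pass at `log_sigma_px`, candidate maxima must
#' exceed the in-nucleus median response by `prominence_k` robust SDs
#' (median absolute deviation), and maxima closer than `min_separation_px`
#' merge into the stronger one. The per-nucleus threshold makes counts
#' invariant to intensity offsets.
#'
#' @param log_sigma_px Gaussian sigma of the LoG filter (px).
#' @param prominence_k threshold in MAD units above the in-nucleus median.
#' @param min_separation_px minimum distance between two reported foci.
#' @return A validated list of class `foci_params`.
#' @export
foci_params <- function(log_sigma_px = 2, prominence_k = 5,
                        min_separation_px = 3L) {
  check_scalar(log_sigma_px, "log_sigma_px", positive = TRUE)
  check_scalar(prominence_k, "prominence_k", positive = TRUE)
  check_scalar(min_separation_px, "min_separation_px", positive = TRUE, integer = TRUE)
  structure(list(log_sigma_px = log_sigma_px, prominence_k = prominence_k,
                 min_separation_px = as.integer(min_separation_px)),
            class = "foci_params")
}

#' Cytosolic signal intensity
#'
#' Mean marker intensity over the cytosol ring:
#' `(IntegratedDensity(cell) - IntegratedDensity(nucleus)) /
#'  (Area(cell) - Area(nucleus))`,
#' reading the cytosol integrated density as the whole-cell integrated
#' density (the subtraction of the nuclear integrated density would be
#' redundant if the cytosol region already excluded the nucleus). The
#' `"strict"` mode integrates over the ring directly; for nested masks the
#' two are algebraically identical.
#'
#' @param marker_2d marker intensity matrix.
#' @param cell_mask,nucleus_mask logical matrices; the nucleus mask must be
#'   nested inside the cell mask and strictly smaller.
#' @param mode `"whole_cell"` (default) or `"strict"`.
#' @return Mean cytosolic intensity (scalar).
#' @export
cytosolic_intensity <- function(marker_2d, cell_mask, nucleus_mask,
                                mode = c("whole_cell", "strict")) {
  mode <- match.arg(mode)
  cell_mask <- as_mat(cell_mask) > 0
  nucleus_mask <- as_mat(nucleus_mask) > 0
  stopifnot(is.matrix(marker_2d), all(dim(marker_2d) == dim(cell_mask)),
            all(dim(cell_mask) == dim(nucleus_mask)))
  if (any(nucleus_mask & !cell_mask))
    stopf("cytosolic_intensity: masks not nested (nucleus outside cell)")
  a_cell <- sum(cell_mask); a_nuc <- sum(nucleus_mask)
  if (a_cell <= a_nuc) stopf("cytosolic_intensity: empty cytosol")
  if (mode == "whole_cell")
    (sum(marker_2d[cell_mask]) - sum(marker_2d[nucleus_mask])) / (a_cell - a_nuc)
  else {
    ring <- cell_mask & !nucleus_mask
    sum(marker_2d[ring]) / sum(ring)
  }
}

#' Nuclear-to-cytosolic signal intensity ratio
#'
#' Ratio of the nuclear mean marker intensity to the cytosolic signal
#' intensity; values > 1 indicate nuclear translocation (e.g. of NF-kB
#' p65). Undefined (returned as `NA`) when the cytosolic intensity is not
#' positive; such cells are excluded from group means and counted.
#'
#' @inheritParams cytosolic_intensity
#' @return The ratio, or `NA_real_` when undefined.
#' @export
nuclear_cytosolic_ratio <- function(marker_2d, cell_mask, nucleus_mask,
                                    mode = c("whole_cell", "strict")) {
  cyto <- cytosolic_intensity(marker_2d, cell_mask, nucleus_mask, mode)
  nucleus_mask <- as_mat(nucleus_mask) > 0
  nuc_mean <- sum(marker_2d[nucleus_mask]) / sum(nucleus_mask)
  if (cyto <= 0) return(NA_real_)
  nuc_mean / cyto
}

#' Per-cell translocation measurements
#'
#' Applies [cytosolic_intensity()] / [nuclear_cytosolic_ratio()] to every
#' cell of a segmented scene, using the union of the cell's nuclei as the
#' nuclear region.
#'
#' @param marker_2d marker intensity matrix.
#' @param cells cell label matrix.
#' @param nuclei nucleus label matrix.
#' @param mapping data frame from [assign_nuclei_to_cells()].
#' @param mode cytosol mode, see [cytosolic_intensity()].
#' @return A data frame with `cell_id`, `integrated_density_cell`,
#'   `integrated_density_nucleus`, `cell_area_px2`, `nucleus_area_px2`,
#'   `cytosolic_intensity`, `nuclear_mean`, `ratio`, `ratio_defined`.
#' @export
measure_translocation <- function(marker_2d, cells, nuclei, mapping,
                                  mode = c("whole_cell", "strict")) {
  mode <- match.arg(mode)
  mapping <- mapping[!is.na(mapping$cell_id), , drop = FALSE]
  cell_ids <- sort(unique(mapping$cell_id))
  out <- lapply(cell_ids, function(cid) {
    cm <- cells == cid
    nm <- matrix(FALSE, nrow(nuclei), ncol(nuclei))
    for (nid in mapping$nucleus_id[mapping$cell_id == cid])
      nm <- nm | nuclei == nid
    a_cell <- sum(cm); a_nuc <- sum(nm)
    id_cell <- sum(marker_2d[cm]); id_nuc <- sum(marker_2d[nm])
    if (a_cell > a_nuc && a_nuc > 0) {
      cyto <- cytosolic_intensity(marker_2d, cm, nm, mode)
      nuc_mean <- id_nuc / a_nuc
      ratio <- if (cyto > 0) nuc_mean / cyto else NA_real_
    } else {
      cyto <- NA_real_; nuc_mean <- if (a_nuc > 0) id_nuc / a_nuc else NA_real_
      ratio <- NA_real_
    }
    data.frame(cell_id = cid, integrated_density_cell = id_cell,
               integrated_density_nucleus = id_nuc,
               cell_area_px2 = a_cell, nucleus_area_px2 = a_nuc,
               cytosolic_intensity = cyto, nuclear_mean = nuc_mean,
               ratio = ratio, ratio_defined = !is.na(ratio))
  })
  do.call(rbind, out)
}

# Zero-mean negated Laplacian-of-Gaussian kernel (peak response positive).
log_kernel <- function(sigma) {
  ext <- ceiling(3 * sigma)
  x <- -ext:ext
  g <- exp(-outer(x^2, x^2, `+`) / (2 * sigma^2))
  r2 <- outer(x^2, x^2, `+`)
  k <- -(r2 - 2 * sigma^2) / sigma^2 * g   # scale-normalized, negated LoG
  k - mean(k)
}

#' Detect foci within nuclei
#'
#' Laplacian-of-Gaussian band-pass at the expected spot scale, local maxima
#' restricted to nucleus masks with response above
#' `median + prominence_k * MAD` of the in-nucleus response, and maxima
#' closer than `min_separation_px` merged keeping the stronger. Nuclei with
#' no candidate report 0 foci.
#'
#' @param marker_2d marker intensity matrix.
#' @param nuclei nucleus label matrix.
#' @param params a [foci_params()].
#' @return A data frame `nucleus_id`, `foci_count`.
#' @export
detect_foci <- function(marker_2d, nuclei, params = foci_params()) {
  stopifnot(is.matrix(marker_2d), is.matrix(nuclei),
            all(dim(marker_2d) == dim(nuclei)))
  ids <- sort(unique(nuclei[nuclei > 0L]))
  if (!length(ids))
    return(data.frame(nucleus_id = integer(0), foci_count = integer(0)))
  resp <- as_mat(EBImage::filter2(EBImage::Image(marker_2d),
                                  log_kernel(params$log_sigma_px),
                                  boundary = "replicate"))
  locmax <- resp >= as_mat(EBImage::dilate(EBImage::Image(resp),
                                           EBImage::makeBrush(3L, "box")))
  H <- nrow(marker_2d)
  counts <- vapply(ids, function(id) {
    px <- which(nuclei == id)
    v <- resp[px]
    thr <- median(v) + params$prominence_k * mad(v)
    cand <- px[locmax[px] & v > thr]
    if (!length(cand)) return(0L)
    rc <- idx_rc(cand, H)
    o <- order(resp[cand], decreasing = TRUE)
    keep_y <- numeric(0); keep_x <- numeric(0)
    for (j in o) {
      y <- rc[j, 1]; x <- rc[j, 2]
      if (!length(keep_y) ||
          all((keep_y - y)^2 + (keep_x - x)^2 >= params$min_separation_px^2)) {
        keep_y <- c(keep_y, y); keep_x <- c(keep_x, x)
      }
    }
    length(keep_y)
  }, integer(1))
  data.frame(nucleus_id = ids, foci_count = counts)
}

#' Sum foci counts per cell
#'
#' @param foci_df output of [detect_foci()].
#' @param mapping data frame from [assign_nuclei_to_cells()].
#' @return A data frame `cell_id`, `foci_count`.
#' @export
foci_per_cell <- function(foci_df, mapping) {
  m <- merge(foci_df, mapping[, c("nucleus_id", "cell_id")], by = "nucleus_id")
  m <- m[!is.na(m$cell_id), , drop = FALSE]
  agg <- tapply(m$foci_count, m$cell_id, sum)
  data.frame(cell_id = as.integer(names(agg)),
             foci_count = as.integer(agg))
}

#' Fraction of values strictly above a cutoff
#'
#' The proportion-of-positive-cells read-out; the comparison is strict, so
#' values equal to the cutoff do not count as positive. The cutoff carries
#' no default: it is assay-specific.
#'
#' @param values numeric vector (non-empty).
#' @param cutoff finite cutoff.
#' @return Fraction in \[0, 1\].
#' @export
positive_fraction <- function(values, cutoff) {
  if (!length(values)) stopf("positive_fraction: empty value list")
  check_scalar(cutoff, "cutoff")
  mean(values > cutoff)
}
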
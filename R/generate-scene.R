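#' Generate one ground-truthed synthetic scene
#'
#' Samples a cell population from `config`, places cells without overlap by
#' rejection sampling, places the nuclei of multinucleated cells inside their
#' cell body, plants Poisson-distributed diffraction-limited foci, and
#' renders the three channels (DAPI, MARKER, CELLBODY) as piecewise-constant
#' intensities plus Gaussian focus spots, with Poisson shot noise followed by
#' additive Gaussian read noise applied last, independently per z-plane.
#'
#' Nuclear geometry: every nucleus is an ellipse with log-normal area,
#' aspect ratio uniform in \[0.85, 1\] and uniform rotation. A giant cell
#' scales each nuclear semi-axis by `giant_scale`. A multinucleated cell with
#' k nuclei that is *not* giant scales each semi-axis by 1/k, so its total
#' nuclear perimeter stays vehicle-typical and its total area below it:
#' splitting a vehicle-sized total area over k equal nuclei would inflate the
#' perimeter sum by sqrt(k) and push every multinucleated cell over the
#' vehicle-referenced 3-sigma perimeter threshold, conflating the two
#' planted phenotypes. A cell that is both giant and multinucleated scales
#' by `giant_scale`/k, which keeps both its area and perimeter sums above
#' the thresholds.
#'
#' The MARKER channel renders `cytosol_level` counts over the cytosol and
#' `marker_ratio * cytosol_level` inside nuclei, so with noise off the
#' nuclear:cytosolic mean-intensity ratio equals `marker_ratio` exactly.
#' Focus peaks are 5 x `cytosol_level` above the local nuclear level.
#'
#' @param config a [scene_config()].
#' @param render if `FALSE`, skip rendering and return ground truth only
#'   (fast path for distributional checks on the sampler).
#' @return A list with elements
#'   \describe{
#'     \item{stack}{an [image_stack()] (`NULL` when `render = FALSE`).}
#'     \item{truth}{a `scene_truth` list: `cells` and `nuclei` data frames,
#'       `foci` data frame (planted focus centers), pixel-exact
#'       `nucleus_labels`/`cell_labels` matrices (when rendered), and the
#'       generating `config`.}
#'   }
#' @export
generate_scene <- function(config, render = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, generate_scene_impl(config, render))
}

generate_scene_impl <- function(config, render) {
  H <- config$image_height_px
  W <- config$image_width_px
  ps <- config$pixel_size_um
  n <- config$n_cells

  if (n == 0L) {
    truth <- empty_truth(config)
    stack <- if (render) render_scene(truth, config) else NULL
    return(list(stack = stack, truth = truth))
  }

  # --- composition: exact per-scene counts, uniformly sampled membership ---
  n_mnc <- round(config$mnc_fraction * n)
  n_giant <- round(config$giant_fraction * n)
  is_mnc <- rep(FALSE, n)
  is_giant <- rep(FALSE, n)
  if (n_mnc > 0) is_mnc[sample.int(n, n_mnc)] <- TRUE
  if (n_giant > 0) is_giant[sample.int(n, n_giant)] <- TRUE

  k_range <- config$mnc_nuclei_range
  n_nuclei <- ifelse(is_mnc,
                     sample(seq(k_range[1], k_range[2]), n, replace = TRUE),
                     1L)

  # --- nuclear geometry -----------------------------------------------------
  cv <- config$vehicle_area_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(config$vehicle_area_mean_um2) - sdlog^2 / 2

  nuc <- vector("list", n)
  cell_radius <- numeric(n)
  for (i in seq_len(n)) {
    k <- n_nuclei[i]
    lin <- (if (is_giant[i]) config$giant_scale else 1) / k
    base_area <- rlnorm(k, meanlog, sdlog)        # um^2, vehicle scale
    area_um2 <- base_area * lin^2
    q <- runif(k, 0.85, 1)
    theta <- runif(k, 0, pi)
    area_px <- area_um2 / ps^2
    a <- sqrt(area_px / (pi * q))
    b <- q * a
    nuc[[i]] <- data.frame(a = a, b = b, theta = theta,
                           area_um2 = area_um2)
    r_tot <- sqrt(sum(area_px) / pi)
    a_max <- max(a)
    ring <- if (k > 1) 1 / (2 * sin(pi / k)) else 0
    cell_radius[i] <- max(1.6 * r_tot,
                          a_max + 4 + (2 * a_max + 4) * ring,
                          12)
  }

  # --- place cell centers (largest first) without overlap -------------------
  centers <- place_cells(cell_radius, H, W, margin = 4, max_attempts = 8000)

  # --- place nuclei inside each cell body -----------------------------------
  nuclei_rows <- vector("list", n)
  nid <- 0L
  for (i in seq_len(n)) {
    g <- nuc[[i]]
    k <- nrow(g)
    pos <- place_nuclei(centers[i, ], cell_radius[i], g$a, gap = 4)
    ids <- nid + seq_len(k)
    nid <- nid + k
    nuclei_rows[[i]] <- data.frame(
      nucleus_id = ids, cell_id = i,
      cy = pos[, 1], cx = pos[, 2],
      a = g$a, b = g$b, theta = g$theta,
      area_um2 = pi * g$a * g$b * ps^2,
      perimeter_um = ellipse_perimeter(g$a, g$b) * ps
    )
  }
  nuclei <- do.call(rbind, nuclei_rows)

  # --- plant foci -----------------------------------------------------------
  foci <- plant_foci(nuclei, config)
  nuclei$foci_count <- tabulate(foci$nucleus_id, nbins = nrow(nuclei))

  cells <- data.frame(
    cell_id = seq_len(n),
    cy = centers[, 1], cx = centers[, 2],
    radius_px = cell_radius,
    n_nuclei = n_nuclei,
    is_mnc_true = is_mnc,
    is_giant_true = is_giant,
    total_area_um2 = as.numeric(tapply(nuclei$area_um2, nuclei$cell_id, sum)),
    total_perimeter_um = as.numeric(tapply(nuclei$perimeter_um, nuclei$cell_id, sum)),
    planted_ratio = config$marker_ratio
  )

  truth <- structure(list(cells = cells, nuclei = nuclei, foci = foci,
                          nucleus_labels = NULL, cell_labels = NULL,
                          config = config, seed = config$seed),
                     class = "scene_truth")
  stack <- NULL
  if (render) {
    stack <- render_scene(truth, config)
    truth$nucleus_labels <- attr(stack, "nucleus_labels")
    truth$cell_labels <- attr(stack, "cell_labels")
    attr(stack, "nucleus_labels") <- NULL
    attr(stack, "cell_labels") <- NULL
  }
  list(stack = stack, truth = truth)
}

empty_truth <- function(config) {
  structure(list(
    cells = data.frame(cell_id = integer(0), cy = numeric(0), cx = numeric(0),
                       radius_px = numeric(0), n_nuclei = integer(0),
                       is_mnc_true = logical(0), is_giant_true = logical(0),
                       total_area_um2 = numeric(0),
                       total_perimeter_um = numeric(0),
                       planted_ratio = numeric(0)),
    nuclei = data.frame(nucleus_id = integer(0), cell_id = integer(0),
                        cy = numeric(0), cx = numeric(0), a = numeric(0),
                        b = numeric(0), theta = numeric(0),
                        area_um2 = numeric(0), perimeter_um = numeric(0),
                        foci_count = integer(0)),
    foci = data.frame(nucleus_id = integer(0), cy = numeric(0),
                      cx = numeric(0)),
    nucleus_labels = NULL, cell_labels = NULL,
    config = config, seed = config$seed), class = "scene_truth")
}

# Rejection-sample non-overlapping cell centers; big cells placed first.
place_cells <- function(radius, H, W, margin, max_attempts) {
  n <- length(radius)
  ord <- order(radius, decreasing = TRUE)
  cy <- numeric(n); cx <- numeric(n)
  placed <- integer(0)
  for (i in ord) {
    r <- radius[i]
    if (H - 2 * (r + 2) <= 0 || W - 2 * (r + 2) <= 0)
      stopf("generate_scene: a cell of radius %.0f px does not fit the image", r)
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      y <- runif(1, r + 2, H - r - 2)
      x <- runif(1, r + 2, W - r - 2)
      if (!length(placed) ||
          all((cy[placed] - y)^2 + (cx[placed] - x)^2 >=
              (radius[placed] + r + margin)^2)) {
        cy[i] <- y; cx[i] <- x; placed <- c(placed, i); ok <- TRUE
        break
      }
    }
    if (!ok)
      stopf("generate_scene: could not place %d cells without overlap; scene too dense",
            n)
  }
  cbind(cy, cx)
}

# Place k nucleus centers inside a cell body of radius R, pairwise separated.
place_nuclei <- function(center, R, a, gap) {
  k <- length(a)
  if (k == 1L) {
    jit <- min(max(R - a[1] - 2, 0), 0.25 * R)
    ang <- runif(1, 0, 2 * pi); rad <- jit * sqrt(runif(1))
    return(cbind(center[1] + rad * sin(ang), center[2] + rad * cos(ang)))
  }
  for (restart in 1:400) {
    pos <- matrix(NA_real_, k, 2)
    fail <- FALSE
    for (j in seq_len(k)) {
      ok <- FALSE
      rho_max <- max(R - a[j] - 2, 1)
      for (att in 1:200) {
        ang <- runif(1, 0, 2 * pi); rad <- rho_max * sqrt(runif(1))
        y <- center[1] + rad * sin(ang); x <- center[2] + rad * cos(ang)
        prev <- seq_len(j - 1L)
        if (j == 1L ||
            all((pos[prev, 1] - y)^2 + (pos[prev, 2] - x)^2 >=
                (a[prev] + a[j] + gap)^2)) {
          pos[j, ] <- c(y, x); ok <- TRUE; break
        }
      }
      if (!ok) { fail <- TRUE; break }
    }
    if (!fail) return(pos)
  }
  stopf("generate_scene: could not place %d nuclei inside a cell of radius %.0f px",
        k, R)
}

# Plant Poisson(lambda) foci per nucleus, pairwise well-separated and away
# from the nuclear boundary. Counts are truncated when a nucleus is too small
# or too crowded to hold the draw; the recorded truth is what was planted.
plant_foci <- function(nuclei, config) {
  lambda <- config$foci_lambda
  out <- list()
  if (lambda > 0 && nrow(nuclei)) {
    sig <- config$foci_sigma_px
    min_sep <- max(4 * sig, 8)
    margin <- 2 * sig
    for (r in seq_len(nrow(nuclei))) {
      n_f <- rpois(1, lambda)
      if (n_f == 0) next
      am <- nuclei$a[r] - margin; bm <- nuclei$b[r] - margin
      if (am <= 0.5 || bm <= 0.5) next
      ct <- cos(nuclei$theta[r]); st <- sin(nuclei$theta[r])
      pts <- matrix(NA_real_, 0, 2)
      for (f in seq_len(n_f)) {
        for (att in 1:200) {
          ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1))
          u <- rad * cos(ang) * am; v <- rad * sin(ang) * bm
          y <- nuclei$cy[r] + u * st + v * ct
          x <- nuclei$cx[r] + u * ct - v * st
          if (!nrow(pts) ||
              all((pts[, 1] - y)^2 + (pts[, 2] - x)^2 >= min_sep^2)) {
            pts <- rbind(pts, c(y, x))
            break
          }
        }
      }
      if (nrow(pts))
        out[[length(out) + 1L]] <- data.frame(
          nucleus_id = nuclei$nucleus_id[r], cy = pts[, 1], cx = pts[, 2])
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(nucleus_id = integer(0), cy = numeric(0), cx = numeric(0))
}

# Render the three channels from ground truth; also build pixel-exact truth
# label maps (returned as attributes).
render_scene <- function(truth, config) {
  H <- config$image_height_px
  W <- config$image_width_px
  bg <- config$background_level

  dapi <- matrix(bg, H, W)
  marker <- matrix(bg, H, W)
  cellb <- matrix(bg, H, W)
  nuc_lab <- matrix(0L, H, W)
  cell_lab <- matrix(0L, H, W)

  cells <- truth$cells
  for (i in seq_len(nrow(cells))) {
    px <- ellipse_pixels(cells$cy[i], cells$cx[i], cells$radius_px[i],
                         cells$radius_px[i], 0, H, W)
    cellb[px] <- config$cellbody_level
    marker[px] <- config$cytosol_level
    cell_lab[px] <- cells$cell_id[i]
  }
  nuclei <- truth$nuclei
  for (r in seq_len(nrow(nuclei))) {
    px <- ellipse_pixels(nuclei$cy[r], nuclei$cx[r], nuclei$a[r], nuclei$b[r],
                         nuclei$theta[r], H, W)
    dapi[px] <- config$dapi_level
    marker[px] <- config$cytosol_level * config$marker_ratio
    nuc_lab[px] <- nuclei$nucleus_id[r]
  }
  foci <- truth$foci
  if (nrow(foci)) {
    sig <- config$foci_sigma_px
    amp <- 5 * config$cytosol_level
    ext <- ceiling(3 * sig) + 1L
    for (f in seq_len(nrow(foci))) {
      rows <- max(1L, floor(foci$cy[f] + 1 - ext)):min(H, ceiling(foci$cy[f] + 1 + ext))
      cols <- max(1L, floor(foci$cx[f] + 1 - ext)):min(W, ceiling(foci$cx[f] + 1 + ext))
      dy <- (rows - 1) - foci$cy[f]
      dx <- (cols - 1) - foci$cx[f]
      g <- amp * exp(-outer(dy^2, dx^2, `+`) / (2 * sig^2))
      marker[rows, cols] <- marker[rows, cols] + g
    }
  }

  planes <- list(DAPI = dapi, MARKER = marker, CELLBODY = cellb)
  pix <- array(0, dim = c(H, W, config$n_z, 3L))
  for (ci in 1:3) {
    base <- planes[[ci]]
    for (z in seq_len(config$n_z)) {
      p <- base
      if (config$poisson_noise) p[] <- rpois(length(p), p)
      if (config$gaussian_noise_sd > 0)
        p <- p + rnorm(length(p), 0, config$gaussian_noise_sd)
      pix[, , z, ci] <- pmax(p, 0)
    }
  }
  stack <- image_stack(pix, channels = c("DAPI", "MARKER", "CELLBODY"),
                       pixel_size_um = config$pixel_size_um)
  attr(stack, "nucleus_labels") <- nuc_lab
  attr(stack, "cell_labels") <- cell_lab
  stack
}

#' Generate paired vehicle and exposed scene lists
#'
#' Emulates a two-arm chronic-exposure experiment: `n_scenes` independent
#' fields per arm, with per-scene seeds derived deterministically from
#' `master_seed` so regeneration is bit-identical and independent of order.
#' The vehicle arm must have `giant_fraction = 0` and `mnc_fraction = 0`.
#'
#' @param vehicle_config,exposed_config [scene_config()]s for the two arms.
#' @param n_scenes number of scenes per arm.
#' @param master_seed master seed; per-scene seeds are
#'   `master_seed + 101 * i` (vehicle) and `master_seed + 101 * i + 50`
#'   (exposed).
#' @param render render pixel data (see [generate_scene()]).
#' @return A list with `vehicle` and `exposed` (each a list of scenes) and
#'   `master_seed`.
#' @export
generate_population <- function(vehicle_config, exposed_config, n_scenes,
                                master_seed = vehicle_config$seed,
                                render = TRUE) {
  stopifnot(inherits(vehicle_config, "scene_config"),
            inherits(exposed_config, "scene_config"))
  check_scalar(n_scenes, "n_scenes", positive = TRUE, integer = TRUE)
  if (vehicle_config$giant_fraction != 0 || vehicle_config$mnc_fraction != 0)
    stopf("generate_population: vehicle arm must have giant_fraction = 0 and mnc_fraction = 0")
  gen_arm <- function(config, offset) {
    lapply(seq_len(n_scenes), function(i) {
      generate_scene(update_config(config, seed = master_seed + 101L * i + offset),
                     render = render)
    })
  }
  list(vehicle = gen_arm(vehicle_config, 0L),
       exposed = gen_arm(exposed_config, 50L),
       master_seed = as.integer(master_seed))
}

#' Concatenate ground truths across scenes
#'
#' @param scenes a list of scenes as returned by [generate_scene()] (or the
#'   `vehicle`/`exposed` element of [generate_population()]).
#' @return A list of `cells` and `nuclei` data frames with a `scene_id`
#'   column and globally unique ids.
#' @export
bind_scene_truth <- function(scenes) {
  cells <- list(); nuclei <- list()
  cell_off <- 0L; nuc_off <- 0L
  for (i in seq_along(scenes)) {
    tr <- scenes[[i]]$truth
    ce <- tr$cells; nu <- tr$nuclei
    if (nrow(ce)) {
      ce$scene_id <- i; ce$cell_id <- ce$cell_id + cell_off
      cells[[length(cells) + 1L]] <- ce
    }
    if (nrow(nu)) {
      nu$scene_id <- i
      nu$cell_id <- nu$cell_id + cell_off
      nu$nucleus_id <- nu$nucleus_id + nuc_off
      nuclei[[length(nuclei) + 1L]] <- nu
    }
    cell_off <- cell_off + nrow(tr$cells)
    nuc_off <- nuc_off + nrow(tr$nuclei)
  }
  list(cells = if (length(cells)) do.call(rbind, cells) else NULL,
       nuclei = if (length(nuclei)) do.call(rbind, nuclei) else NULL)
}
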
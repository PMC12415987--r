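test_that("identical config and seed give bit-identical scenes", {
  cfg <- small_cfg(n_cells = 8, giant_fraction = 0.25, mnc_fraction = 0.25,
                   foci_lambda = 2, seed = 11)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$stack$pixels, b$stack$pixels)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(a$truth$nuclei, b$truth$nuclei)
  expect_identical(a$truth$foci, b$truth$foci)
})

test_that("an empty scene has no cells and a flat background", {
  cfg <- noise_off(small_cfg(n_cells = 0))
  sc <- generate_scene(cfg)
  expect_equal(nrow(sc$truth$cells), 0)
  expect_equal(nrow(sc$truth$nuclei), 0)
  dapi <- get_channel(sc$stack, "DAPI")
  expect_true(all(dapi == cfg$background_level))
})

test_that("forced multinucleation yields one cell with the forced nucleus count", {
  cfg <- small_cfg(n_cells = 1, mnc_fraction = 1, mnc_nuclei_range = c(2, 2))
  sc <- generate_scene(cfg, render = FALSE)
  expect_equal(nrow(sc$truth$cells), 1)
  expect_equal(sc$truth$cells$n_nuclei, 2L)
  expect_true(sc$truth$cells$is_mnc_true)
  expect_equal(nrow(sc$truth$nuclei), 2)
})

test_that("composition flags match the seeded sampler and ground-truth invariants hold", {
  cfg <- small_cfg(image_height_px = 900, image_width_px = 900, n_cells = 50,
                   giant_fraction = 0.2, mnc_fraction = 0.2, seed = 7)
  sc <- generate_scene(cfg, render = FALSE)
  tr <- sc$truth
  # exact-count composition: the sampler plants round(fraction * n) flags
  expect_equal(sum(tr$cells$is_giant_true), round(0.2 * 50))
  expect_equal(sum(tr$cells$is_mnc_true), round(0.2 * 50))
  # is_mnc_true <=> more than one nucleus
  expect_equal(tr$cells$is_mnc_true, tr$cells$n_nuclei > 1)
  # totals are sums of per-nucleus analytic values
  by_cell <- tapply(tr$nuclei$area_um2, tr$nuclei$cell_id, sum)
  expect_equal(as.numeric(by_cell[as.character(tr$cells$cell_id)]),
               tr$cells$total_area_um2)
})

test_that("empirical giant fraction over a large exposed arm is consistent with the planted rate", {
  cfg <- small_cfg(image_height_px = 1200, image_width_px = 1200,
                   n_cells = 120, giant_fraction = 0.2, mnc_fraction = 0.1)
  pop <- generate_population(update_config(cfg, giant_fraction = 0, mnc_fraction = 0),
                             cfg, n_scenes = 5, master_seed = 3, render = FALSE)
  truth <- bind_scene_truth(pop$exposed)
  n <- nrow(truth$cells)
  expect_gte(n, 500)
  phat <- mean(truth$cells$is_giant_true)
  ci <- qnorm(0.995) * sqrt(0.2 * 0.8 / n)
  expect_lt(abs(phat - 0.2), ci + 1e-12)
  # vehicle arm carries no giant or multinucleated cells by convention
  vt <- bind_scene_truth(pop$vehicle)
  expect_equal(sum(vt$cells$is_giant_true), 0)
  expect_equal(sum(vt$cells$is_mnc_true), 0)
})

test_that("regenerating a population is bit-identical and over-dense configs fail", {
  cfg <- small_cfg(n_cells = 6)
  p1 <- generate_population(cfg, update_config(cfg, giant_fraction = 0.5),
                            n_scenes = 3, master_seed = 5, render = FALSE)
  p2 <- generate_population(cfg, update_config(cfg, giant_fraction = 0.5),
                            n_scenes = 3, master_seed = 5, render = FALSE)
  expect_identical(bind_scene_truth(p1$exposed), bind_scene_truth(p2$exposed))
  dense <- scene_config(image_height_px = 150, image_width_px = 150,
                        n_cells = 50, seed = 1)
  expect_error(generate_scene(dense, render = FALSE), "dense|fit")
})

test_that("rendered ellipse pixel areas match analytic areas within the discretization bound", {
  cfg <- noise_off(small_cfg(image_height_px = 700, image_width_px = 700,
                             n_cells = 15, seed = 21))
  sc <- generate_scene(cfg)
  tr <- sc$truth
  px_area <- tabulate(tr$nucleus_labels, nbins = nrow(tr$nuclei))
  analytic_px <- pi * tr$nuclei$a * tr$nuclei$b
  big <- pmin(tr$nuclei$a, tr$nuclei$b) >= 8
  expect_true(any(big))
  expect_true(all(abs(px_area[big] - analytic_px[big]) / analytic_px[big] <= 0.05))
})

test_that("with noise off the planted nuclear:cytosolic ratio is exact", {
  for (r in c(1, 2.5)) {
    cfg <- noise_off(small_cfg(n_cells = 6, marker_ratio = r, seed = 31))
    sc <- generate_scene(cfg)
    marker <- get_channel(sc$stack, "MARKER")
    nuc <- sc$truth$nucleus_labels > 0
    cyto <- sc$truth$cell_labels > 0 & !nuc
    expect_equal(mean(marker[nuc]) / mean(marker[cyto]), r)
  }
})

test_that("planted foci counts per nucleus are Poisson distributed", {
  for (lambda in c(1, 5)) {
    counts <- integer(0)
    for (i in 1:5) {
      cfg <- small_cfg(image_height_px = 2000, image_width_px = 2000,
                       n_cells = 200, foci_lambda = lambda, seed = 100 + i)
      sc <- generate_scene(cfg, render = FALSE)
      counts <- c(counts, sc$truth$nuclei$foci_count)
    }
    expect_gte(length(counts), 1000)
    kmax <- max(counts)
    obs <- tabulate(factor(counts, levels = 0:kmax), nbins = kmax + 1)
    prob <- dpois(0:kmax, lambda)
    prob[kmax + 1] <- prob[kmax + 1] + ppois(kmax, lambda, lower.tail = FALSE)
    # pool bins with expected count < 5 into their tail
    exp_n <- prob * length(counts)
    keep <- which(exp_n >= 5)
    lo <- min(keep); hi <- max(keep)
    obs2 <- c(sum(obs[seq_len(lo)]), obs[(lo + 1):(hi - 1)],
              sum(obs[hi:(kmax + 1)]))
    exp2 <- c(sum(exp_n[seq_len(lo)]), exp_n[(lo + 1):(hi - 1)],
              sum(exp_n[hi:(kmax + 1)]))
    stat <- sum((obs2 - exp2)^2 / exp2)
    p <- pchisq(stat, df = length(obs2) - 1, lower.tail = FALSE)
    expect_gt(p, 0.01)
  }
})
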
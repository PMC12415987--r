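make_nested_masks <- function(n = 10) {
  cell <- matrix(FALSE, n, n); cell[2:(n - 1), 2:(n - 1)] <- TRUE
  nuc <- matrix(FALSE, n, n); nuc[4:(n - 3), 4:(n - 3)] <- TRUE
  list(cell = cell, nuc = nuc)
}

test_that("cytosolic intensity reproduces hand-computed and degenerate cases", {
  m <- make_nested_masks()
  uni <- matrix(5, 10, 10)
  expect_equal(cytosolic_intensity(uni, m$cell, m$nuc), 5)
  # 200-px cell with integrated density 2000; 50-px nucleus with 1500
  cell <- matrix(FALSE, 20, 20); cell[1:10, 1:20] <- TRUE
  nuc <- matrix(FALSE, 20, 20); nuc[1:5, 1:10] <- TRUE
  img <- matrix(0, 20, 20)
  img[nuc] <- 30                         # 50 * 30 = 1500
  img[cell & !nuc] <- 500 / 150          # remainder sums to 500
  expect_equal(cytosolic_intensity(img, cell, nuc), (2000 - 1500) / (200 - 50))
  # marker entirely inside the nucleus -> zero cytosolic signal
  inside <- matrix(0, 10, 10); inside[m$nuc] <- 7
  expect_equal(cytosolic_intensity(inside, m$cell, m$nuc), 0)
  # errors: non-nested masks and empty cytosol
  expect_error(cytosolic_intensity(uni, m$nuc, m$cell), "not nested")
  expect_error(cytosolic_intensity(uni, m$nuc, m$nuc), "empty cytosol")
})

test_that("whole-cell and strict cytosol modes coincide for nested masks", {
  set.seed(41)
  for (i in 1:10) {
    m <- make_nested_masks()
    img <- matrix(runif(100, 0, 50), 10, 10)
    expect_equal(cytosolic_intensity(img, m$cell, m$nuc, mode = "whole_cell"),
                 cytosolic_intensity(img, m$cell, m$nuc, mode = "strict"))
  }
})

test_that("cytosolic intensity equals the brute-force pixel loop on small fixtures", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(6:10, 1)
    cell <- matrix(FALSE, n, n); cell[2:(n - 1), 2:(n - 1)] <- TRUE
    nuc <- matrix(FALSE, n, n)
    nuc[3:(n - 2), 3:(n - 2)] <- runif((n - 4)^2) > 0.3
    if (!any(nuc)) nuc[3, 3] <- TRUE
    img <- matrix(runif(n * n, 0, 100), n, n)
    expect_equal(cytosolic_intensity(img, cell, nuc),
                 brute_cytosolic(img, cell, nuc), tolerance = 1e-14)
  }
})

test_that("the nuclear:cytosolic ratio matches hand arithmetic and is scale invariant", {
  m <- make_nested_masks()
  expect_equal(nuclear_cytosolic_ratio(matrix(5, 10, 10), m$cell, m$nuc), 1)
  cell <- matrix(FALSE, 20, 20); cell[1:10, 1:20] <- TRUE
  nuc <- matrix(FALSE, 20, 20); nuc[1:5, 1:10] <- TRUE
  img <- matrix(0, 20, 20); img[nuc] <- 30; img[cell & !nuc] <- 500 / 150
  expect_equal(nuclear_cytosolic_ratio(img, cell, nuc), 30 / (500 / 150))
  expect_equal(nuclear_cytosolic_ratio(img * 17.3, cell, nuc),
               nuclear_cytosolic_ratio(img, cell, nuc))
  # zero cytosolic signal -> undefined
  inside <- matrix(0, 10, 10); inside[m$nuc] <- 7
  expect_true(is.na(nuclear_cytosolic_ratio(inside, m$cell, m$nuc)))
})

test_that("planted ratios are recovered exactly from noise-free scenes via truth masks", {
  for (r in c(2, 4)) {
    cfg <- noise_off(small_cfg(n_cells = 5, marker_ratio = r, seed = 13))
    sc <- generate_scene(cfg)
    marker <- get_channel(sc$stack, "MARKER")
    map <- data.frame(nucleus_id = sc$truth$nuclei$nucleus_id,
                      cell_id = sc$truth$nuclei$cell_id, flagged = FALSE)
    tr <- measure_translocation(marker, sc$truth$cell_labels,
                                sc$truth$nucleus_labels, map)
    expect_equal(tr$ratio, rep(r, nrow(tr)))
  }
})

test_that("foci detection counts planted spots and obeys the merge rule", {
  # blank nucleus reports zero
  lab <- matrix(0L, 60, 60); lab[ellipse_pixels(30, 30, 20, 20, 0, 60, 60)] <- 1L
  blank <- matrix(10, 60, 60)
  expect_equal(detect_foci(blank, lab)$foci_count, 0L)
  # five well-separated Gaussian spots of amplitude 5x background
  img <- matrix(10, 60, 60)
  pts <- rbind(c(20, 20), c(20, 40), c(40, 20), c(40, 40), c(30, 30))
  for (k in seq_len(nrow(pts))) {
    dy <- (1:60) - pts[k, 1]; dx <- (1:60) - pts[k, 2]
    img <- img + 50 * exp(-outer(dy^2, dx^2, `+`) / (2 * 4))
  }
  expect_equal(detect_foci(img, lab)$foci_count, 5L)
  # two spots 1 px apart with min separation 3 merge into one
  img2 <- matrix(10, 60, 60)
  for (p in list(c(30, 30), c(30, 31))) {
    dy <- (1:60) - p[1]; dx <- (1:60) - p[2]
    img2 <- img2 + 50 * exp(-outer(dy^2, dx^2, `+`) / (2 * 4))
  }
  expect_equal(detect_foci(img2, lab)$foci_count, 1L)
})

test_that("generator-planted foci are recovered exactly on noise-free scenes", {
  cfg <- noise_off(small_cfg(n_cells = 8, foci_lambda = 4, seed = 19))
  sc <- generate_scene(cfg)
  marker <- get_channel(sc$stack, "MARKER")
  fc <- detect_foci(marker, sc$truth$nucleus_labels)
  truth <- sc$truth$nuclei
  expect_equal(fc$foci_count,
               truth$foci_count[match(fc$nucleus_id, truth$nucleus_id)])
  # per-cell sums follow the nucleus-to-cell mapping
  map <- data.frame(nucleus_id = truth$nucleus_id, cell_id = truth$cell_id,
                    flagged = FALSE)
  pc <- foci_per_cell(fc, map)
  expect_equal(sum(pc$foci_count), sum(fc$foci_count))
})

test_that("positive_fraction uses a strict cutoff and rejects empty input", {
  expect_equal(positive_fraction(c(1, 2, 3), 2), 1 / 3)
  expect_equal(positive_fraction(c(1, 1, 1), 5), 0)
  expect_equal(positive_fraction(c(2, 2, 2), 2), 0)  # ties are not positive
  expect_error(positive_fraction(numeric(0), 1), "empty")
})
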
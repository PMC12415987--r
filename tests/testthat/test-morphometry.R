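test_that("area is the pixel count scaled by the pixel size", {
  lab <- matrix(0L, 20, 20)
  lab[6:15, 6:15] <- 1L  # 10x10 solid square
  rec <- measure_nuclei(lab, matrix(1, 20, 20), pixel_size_um = 1)
  expect_equal(rec$area_px2, 100)
  expect_equal(rec$area_um2, 100)
  expect_false(rec$border_censored)
})

test_that("the Crofton perimeter agrees with an independent contour estimator and oracle values", {
  sq <- matrix(0L, 14, 14); sq[3:12, 3:12] <- 1L
  # independent reference implementation, 4-direction Crofton on a 10x10 square
  expect_equal(crofton_perimeter(sq), 36.811657224201205, tolerance = 1e-12)
  # agreement with the 4-neighbour contour length within 10%
  expect_lt(abs(crofton_perimeter(sq) - contour_perimeter(sq)) / contour_perimeter(sq), 0.1)
  disk <- outer((0:60 - 30)^2, (0:60 - 30)^2, `+`) <= 400
  expect_equal(crofton_perimeter(disk), 127.71373126734748, tolerance = 1e-12)
  # near exact on a disk of radius 20 (true 2*pi*20)
  expect_lt(abs(crofton_perimeter(disk) - 2 * pi * 20) / (2 * pi * 20), 0.02)
})

test_that("a digitized ellipse measures close to its analytic area and perimeter", {
  lab <- matrix(0L, 60, 60)
  lab[ellipse_pixels(30, 30, 10, 5, 0, 60, 60)] <- 1L
  rec <- measure_nuclei(lab, matrix(0, 60, 60), pixel_size_um = 1)
  expect_lt(abs(rec$area_um2 - pi * 10 * 5) / (pi * 10 * 5), 0.05)
  expect_lt(abs(rec$perimeter_um - ellipse_perimeter(10, 5)) / ellipse_perimeter(10, 5), 0.1)
})

test_that("the vehicle reference is the sample mean/SD with 3-sigma thresholds", {
  recs <- data.frame(nucleus_id = 1:3, area_um2 = c(90, 100, 110),
                     perimeter_um = c(33, 35, 37),
                     area_px2 = c(90, 100, 110) * 16,
                     perimeter_px = c(33, 35, 37) * 4,
                     border_censored = FALSE)
  ref <- build_vehicle_reference(recs)
  expect_equal(ref$mean_area, 100)
  expect_equal(ref$sd_area, 10)
  expect_equal(ref$area_threshold, 130)
  expect_equal(ref$units, "um")
  # degenerate spread warns, thresholds collapse to the mean
  same <- recs; same$area_um2 <- 100; same$perimeter_um <- 35
  expect_warning(ref0 <- build_vehicle_reference(same), "zero spread")
  expect_equal(ref0$area_threshold, 100)
  # fewer than two uncensored nuclei is an error
  expect_error(build_vehicle_reference(recs[1, ]), "insufficient vehicle reference")
  censored <- recs; censored$border_censored <- c(FALSE, TRUE, TRUE)
  expect_error(build_vehicle_reference(censored), "insufficient vehicle reference")
})

test_that("per-cell totals are exact sums over member nuclei", {
  recs <- data.frame(nucleus_id = 1:3,
                     area_px2 = c(640, 960, 800),
                     area_um2 = c(40, 60, 50),
                     perimeter_px = c(80, 100, 90),
                     perimeter_um = c(20, 25, 22.5),
                     border_censored = FALSE)
  map <- data.frame(nucleus_id = 1:3, cell_id = c(1L, 1L, 2L), flagged = FALSE)
  cells <- aggregate_cells(map, recs)
  expect_equal(cells$total_area_um2, c(100, 50))
  expect_equal(cells$total_perimeter_um, c(45, 22.5))
  expect_equal(cells$is_multinucleated, c(TRUE, FALSE))
  expect_equal(cells$n_nuclei, c(2L, 1L))
  # single-nucleus cell totals equal that nucleus's values exactly
  expect_equal(cells$total_area_um2[2], recs$area_um2[3])
  expect_error(aggregate_cells(data.frame(nucleus_id = 9, cell_id = 1, flagged = FALSE),
                               recs), "no measurement record")
})

test_that("the giant classifier applies the mean + 3 SD rule with strict inequality and OR combination", {
  ref <- structure(list(n_nuclei = 100, mean_area = 100, sd_area = 10,
                        mean_perimeter = 35, sd_perimeter = 2,
                        area_threshold = 130, perimeter_threshold = 41,
                        units = "um"), class = "vehicle_reference")
  cells <- data.frame(cell_id = 1:4, n_nuclei = c(1L, 1L, 2L, 1L),
                      total_area_um2 = c(131, 100, 140, 130),
                      total_perimeter_um = c(36, 35, 40, 41),
                      total_area_px2 = NA, total_perimeter_px = NA)
  res <- classify_cells(cells, ref)
  # area 131 > 130 -> giant; at the mean -> not; summed 70+70=140 -> giant AND mnc;
  # exactly at both thresholds -> not giant (strict inequality)
  expect_equal(res$cells$is_giant, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(res$cells$is_mnc, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(res$summary$n_giant_and_mnc, 1)
  expect_equal(res$summary$pct_giant, 50)
  # perimeter alone can trigger the OR rule
  perim_only <- data.frame(cell_id = 1L, n_nuclei = 1L, total_area_um2 = 100,
                           total_perimeter_um = 41.5, total_area_px2 = NA,
                           total_perimeter_px = NA)
  expect_true(classify_cells(perim_only, ref)$cells$is_giant)
  # empty cell list gives an empty summary
  empty <- classify_cells(cells[0, ], ref)
  expect_equal(empty$summary$n_cells, 0)
})

test_that("classifier flags equal plain arithmetic recomputed from the per-cell table", {
  rec <- recover_morphometry(seed = 77, n_scenes = 2, n_cells = 25)
  ref <- rec$reference
  for (arm in c("vehicle", "exposed")) {
    cells <- rec$result[[arm]]$cells
    redo_giant <- cells$total_area_um2 > ref$area_threshold |
      cells$total_perimeter_um > ref$perimeter_threshold
    expect_identical(cells$is_giant, redo_giant)
    expect_identical(cells$is_mnc, cells$n_nuclei > 1L)
  }
})

test_that("confluence reports occupied fraction, including a doubling growth series", {
  m <- matrix(0, 100, 100); m[1:50, 1:50] <- 1
  cf <- confluence(m, pixel_size_um = 2)
  expect_equal(cf$fraction, 0.25)
  expect_equal(cf$occupied_px, 2500)
  expect_equal(cf$occupied_um2, 10000)
  expect_equal(confluence(matrix(0, 10, 10))$fraction, 0)
  # areas doubling per step double the fraction until saturation
  fr <- vapply(c(625, 1250, 2500, 5000), function(n) {
    mm <- matrix(0, 100, 100); mm[seq_len(n)] <- 1
    confluence(mm)$fraction
  }, numeric(1))
  expect_equal(fr[-1] / fr[-4], rep(2, 3))
})
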
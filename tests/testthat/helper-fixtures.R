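# Small scene configurations and independent oracles used across tests.

small_cfg <- function(...) {
  args <- list(...)
  base <- list(image_height_px = 500L, image_width_px = 500L, n_cells = 10L,
               seed = 1L)
  do.call(scene_config, modifyList(base, args))
}

noise_off <- function(cfg) {
  update_config(cfg, poisson_noise = FALSE, gaussian_noise_sd = 0)
}

# Independent boundary-length estimator: number of 4-neighbour edges between
# object and background (the contour length of the pixel polygon).
contour_perimeter <- function(mask) {
  m <- (mask > 0) + 0L
  p <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  nr <- nrow(p); nc <- ncol(p)
  sum(p[-1, ] != p[-nr, ]) + sum(p[, -1] != p[, -nc])
}

# Brute-force pixel loop for the cytosolic-intensity formula.
brute_cytosolic <- function(marker, cell_mask, nucleus_mask) {
  id_cell <- 0; id_nuc <- 0; a_cell <- 0; a_nuc <- 0
  for (i in seq_len(nrow(marker))) for (j in seq_len(ncol(marker))) {
    if (cell_mask[i, j]) { id_cell <- id_cell + marker[i, j]; a_cell <- a_cell + 1 }
    if (nucleus_mask[i, j]) { id_nuc <- id_nuc + marker[i, j]; a_nuc <- a_nuc + 1 }
  }
  (id_cell - id_nuc) / (a_cell - a_nuc)
}

# Exhaustive step-up oracle for Benjamini-Hochberg: for each p_i, the
# minimum of m * p_j / rank(j) over all j with p_j >= p_i, clipped at 1.
brute_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    min(1, min(m * p[r >= r[i]] / r[r >= r[i]]))
  }, numeric(1))
}

# Textbook two-sample t-test p-values (two-sided).
oracle_t_pooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t, pvalue = 2 * pt(-abs(t), na + nb - 2))
}

oracle_t_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(statistic = t, pvalue = 2 * pt(-abs(t), df))
}

# Match measured labels to ground-truth nuclei by majority pixel overlap.
match_labels <- function(measured, truth_labels) {
  ids <- sort(unique(measured[measured > 0L]))
  vapply(ids, function(id) {
    v <- truth_labels[measured == id]
    v <- v[v > 0L]
    if (!length(v)) return(NA_integer_)
    which.max(tabulate(v))
  }, integer(1))
}

jaccard <- function(mask_a, mask_b) {
  sum(mask_a & mask_b) / sum(mask_a | mask_b)
}
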
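#' Quantify one image stack
#'
#' End-to-end per-scene chain: maximum-intensity projection, nucleus
#' segmentation on DAPI, cell segmentation on CELLBODY (when present;
#' otherwise each nucleus is its own cell and multinucleation is reported
#' as unavailable), nucleus-to-cell assignment, per-nucleus morphometry and
#' per-cell aggregation, plus optional translocation and foci read-outs on
#' the MARKER channel.
#'
#' @param stack an [image_stack()] with at least a DAPI channel.
#' @param params a [seg_params()].
#' @param fparams a [foci_params()].
#' @param intensity compute MARKER read-outs (translocation ratios and foci
#'   counts) when a MARKER channel exists?
#' @return A list with `nuclei_labels`, `cell_labels`, `mapping`, `nuclei`
#'   (records), `cells` (records), `translocation`, `foci`,
#'   `mnc_available`.
#' @export
quantify_stack <- function(stack, params = seg_params(),
                           fparams = foci_params(), intensity = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  if (!"DAPI" %in% stack$channels)
    stopf("quantify: missing DAPI channel")
  proj <- max_project(stack)
  dapi <- get_channel(proj, "DAPI")
  nuclei <- segment_nuclei(dapi, params)

  if ("CELLBODY" %in% stack$channels) {
    cells <- segment_cells(get_channel(proj, "CELLBODY"), nuclei, params)
    mapping <- assign_nuclei_to_cells(nuclei, cells)
    mnc_available <- TRUE
  } else {
    cells <- nuclei
    ids <- sort(unique(nuclei[nuclei > 0L]))
    mapping <- data.frame(nucleus_id = ids, cell_id = ids,
                          flagged = rep(FALSE, length(ids)))
    mnc_available <- FALSE
  }

  nrec <- measure_nuclei(nuclei, dapi, stack$pixel_size_um)
  crec <- aggregate_cells(mapping, nrec)

  trans <- NULL; foci <- NULL
  if (intensity && "MARKER" %in% stack$channels) {
    marker <- get_channel(proj, "MARKER")
    trans <- measure_translocation(marker, cells, nuclei, mapping)
    foci <- detect_foci(marker, nuclei, fparams)
  }
  list(nuclei_labels = nuclei, cell_labels = cells, mapping = mapping,
       nuclei = nrec, cells = crec, translocation = trans, foci = foci,
       mnc_available = mnc_available)
}

# Quantify a list of scenes and pool records with scene_id / unique ids.
quantify_scenes <- function(scenes, params = seg_params(),
                            intensity = FALSE) {
  nrecs <- list(); crecs <- list(); results <- vector("list", length(scenes))
  cell_off <- 0L; nuc_off <- 0L
  for (i in seq_along(scenes)) {
    q <- quantify_stack(scenes[[i]]$stack, params, intensity = intensity)
    results[[i]] <- q
    nr <- q$nuclei; cr <- q$cells
    if (nrow(nr)) {
      nr$scene_id <- i
      nr$nucleus_id <- nr$nucleus_id + nuc_off
      nrecs[[length(nrecs) + 1L]] <- nr
    }
    if (nrow(cr)) {
      cr$scene_id <- i
      cr$cell_id <- cr$cell_id + cell_off
      crecs[[length(crecs) + 1L]] <- cr
    }
    nuc_off <- nuc_off + max(0L, suppressWarnings(max(q$nuclei$nucleus_id, 0L)))
    cell_off <- cell_off + max(0L, suppressWarnings(max(q$cells$cell_id, 0L)))
  }
  list(nuclei = if (length(nrecs)) do.call(rbind, nrecs) else NULL,
       cells = if (length(crecs)) do.call(rbind, crecs) else NULL,
       per_scene = results)
}

#' Run the two-arm quantification pipeline
#'
#' Quantifies vehicle and exposed scene lists, builds the vehicle nuclear
#' reference from uncensored vehicle nuclei, classifies both arms with the
#' giant/multinucleated rule, and optionally writes CSVs, summary JSON and
#' a run manifest.
#'
#' @param vehicle_scenes,exposed_scenes lists of scenes as produced by
#'   [generate_population()] (or lists of `list(stack = <image_stack>)`).
#' @param params a [seg_params()].
#' @param gc_rule giant-cell rule, see [classify_cells()].
#' @param out_dir optional output directory for CSV/JSON results.
#' @return A list with `reference`, `vehicle` and `exposed` classification
#'   results (each `cells` + `summary`), pooled `nuclei` records per arm,
#'   and the written `files` when `out_dir` is given.
#' @export
run_quantify <- function(vehicle_scenes, exposed_scenes,
                         params = seg_params(),
                         gc_rule = c("mean_plus_3sd", "3sd_abs"),
                         out_dir = NULL) {
  gc_rule <- match.arg(gc_rule)
  qv <- quantify_scenes(vehicle_scenes, params)
  qe <- quantify_scenes(exposed_scenes, params)
  if (is.null(qv$nuclei)) stopf("run_quantify: vehicle arm yielded no nuclei")
  ref <- build_vehicle_reference(qv$nuclei)
  mnc_ok <- all(vapply(qv$per_scene, `[[`, logical(1), "mnc_available"))
  veh <- classify_cells(qv$cells, ref, gc_rule, group = "vehicle",
                        mnc_available = mnc_ok)
  exp <- classify_cells(qe$cells, ref, gc_rule, group = "exposed",
                        mnc_available = mnc_ok)
  files <- NULL
  if (!is.null(out_dir)) {
    files <- write_results(rbind(cbind(qv$nuclei, group = "vehicle"),
                                 cbind(qe$nuclei, group = "exposed")),
                           rbind(cbind(veh$cells, group = "vehicle"),
                                 cbind(exp$cells, group = "exposed")),
                           list(reference = unclass(ref),
                                vehicle = unclass(veh$summary)[
                                  setdiff(names(veh$summary), "per_scene")],
                                exposed = unclass(exp$summary)[
                                  setdiff(names(exp$summary), "per_scene")]),
                           out_dir)
    manifest <- list(package_version = as.character(utils::packageVersion("nucquant")),
                     gc_rule = gc_rule, params = unclass(params),
                     n_vehicle_scenes = length(vehicle_scenes),
                     n_exposed_scenes = length(exposed_scenes),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(reference = ref, vehicle = veh, exposed = exp,
       vehicle_nuclei = qv$nuclei, exposed_nuclei = qe$nuclei,
       files = files)
}

#' Giant/multinucleated-cell parameter-recovery benchmark
#'
#' Generates a vehicle arm (no giant, no multinucleated cells) and an
#' exposed arm with planted giant and multinucleated fractions, runs the
#' full segmentation + classification pipeline, and compares recovered to
#' planted percentages.
#'
#' @param seed master seed.
#' @param n_scenes scenes per arm.
#' @param n_cells cells per scene.
#' @param giant_fraction,mnc_fraction planted exposed-arm fractions.
#' @param base_config scene configuration shared by both arms.
#' @param params segmentation parameters.
#' @return A list with planted and recovered percentages, the vehicle-arm
#'   giant percentage, cell counts, the vehicle reference, and the full
#'   [run_quantify()] result.
#' @export
recover_morphometry <- function(seed = 1L, n_scenes = 15L, n_cells = 35L,
                                giant_fraction = 0.2, mnc_fraction = 0.1,
                                base_config = scene_config(),
                                params = seg_params()) {
  vcfg <- update_config(base_config, n_cells = n_cells, giant_fraction = 0,
                        mnc_fraction = 0, seed = seed)
  ecfg <- update_config(vcfg, giant_fraction = giant_fraction,
                        mnc_fraction = mnc_fraction)
  pop <- generate_population(vcfg, ecfg, n_scenes, master_seed = seed)
  truth <- bind_scene_truth(pop$exposed)
  res <- run_quantify(pop$vehicle, pop$exposed, params)
  planted_giant <- 100 * mean(truth$cells$is_giant_true)
  planted_mnc <- 100 * mean(truth$cells$is_mnc_true)
  list(planted_pct_giant = planted_giant,
       planted_pct_mnc = planted_mnc,
       recovered_pct_giant = res$exposed$summary$pct_giant,
       recovered_pct_mnc = res$exposed$summary$pct_mnc,
       vehicle_pct_giant = res$vehicle$summary$pct_giant,
       vehicle_pct_mnc = res$vehicle$summary$pct_mnc,
       n_cells_exposed = res$exposed$summary$n_cells,
       n_cells_vehicle = res$vehicle$summary$n_cells,
       n_cells_planted = nrow(truth$cells),
       reference = res$reference,
       result = res)
}

#' Translocation-ratio recovery benchmark
#'
#' Scenes with planted nuclear:cytosolic marker ratios are segmented and
#' measured; the mean recovered ratio per planted value is reported. With
#' `truth_masks = TRUE` the generator's pixel-exact masks are used instead
#' of segmentation (with noise off this recovers the planted ratio
#' exactly).
#'
#' @param seed master seed.
#' @param ratios planted ratios.
#' @param n_cells cells per ratio.
#' @param noise apply camera noise?
#' @param truth_masks measure on ground-truth label maps instead of
#'   segmented ones?
#' @param base_config scene configuration.
#' @return A data frame `planted`, `mean_recovered`, `rel_error`,
#'   `n_cells`.
#' @export
recover_translocation <- function(seed = 1L, ratios = c(1, 2, 4),
                                  n_cells = 60L, noise = TRUE,
                                  truth_masks = FALSE,
                                  base_config = scene_config()) {
  out <- lapply(seq_along(ratios), function(i) {
    cfg <- update_config(base_config, n_cells = n_cells,
                         marker_ratio = ratios[i],
                         poisson_noise = noise,
                         gaussian_noise_sd = if (noise) base_config$gaussian_noise_sd else 0,
                         seed = seed + 977L * i)
    sc <- generate_scene(cfg)
    marker <- get_channel(max_project(sc$stack), "MARKER")
    if (truth_masks) {
      nuclei <- sc$truth$nucleus_labels
      cells <- sc$truth$cell_labels
      mapping <- data.frame(nucleus_id = sc$truth$nuclei$nucleus_id,
                            cell_id = sc$truth$nuclei$cell_id,
                            flagged = FALSE)
    } else {
      q <- quantify_stack(sc$stack, intensity = FALSE)
      nuclei <- q$nuclei_labels; cells <- q$cell_labels; mapping <- q$mapping
    }
    tr <- measure_translocation(marker, cells, nuclei, mapping)
    r <- tr$ratio[tr$ratio_defined]
    data.frame(planted = ratios[i], mean_recovered = mean(r),
               rel_error = abs(mean(r) - ratios[i]) / ratios[i],
               n_cells = length(r))
  })
  do.call(rbind, out)
}

#' Foci-count recovery benchmark
#'
#' Scenes with Poisson-planted, well-separated foci are measured with the
#' LoG detector on the generator's nucleus masks; reports the fraction of
#' nuclei counted exactly and the spurious rate on focus-free nuclei.
#'
#' @param seed master seed.
#' @param lambda planted Poisson mean foci per nucleus.
#' @param n_scenes,n_cells scenes and cells per scene (all mononucleated).
#' @param fparams detector parameters.
#' @param base_config scene configuration.
#' @return A list with `exact_fraction`, `planted_total`, `detected_total`,
#'   `n_nuclei`, `spurious_rate` (foci/nucleus on blank nuclei),
#'   `n_blank_nuclei`.
#' @export
recover_foci <- function(seed = 1L, lambda = 5, n_scenes = 5L, n_cells = 40L,
                         fparams = foci_params(),
                         base_config = scene_config()) {
  measure_arm <- function(lam, offset) {
    planted <- integer(0); detected <- integer(0)
    for (i in seq_len(n_scenes)) {
      cfg <- update_config(base_config, n_cells = n_cells, foci_lambda = lam,
                           seed = seed + 389L * i + offset)
      sc <- generate_scene(cfg)
      marker <- get_channel(max_project(sc$stack), "MARKER")
      fc <- detect_foci(marker, sc$truth$nucleus_labels, fparams)
      tr <- sc$truth$nuclei
      planted <- c(planted, tr$foci_count[match(fc$nucleus_id, tr$nucleus_id)])
      detected <- c(detected, fc$foci_count)
    }
    list(planted = planted, detected = detected)
  }
  withf <- measure_arm(lambda, 0L)
  blank <- measure_arm(0, 7000L)
  list(exact_fraction = mean(withf$detected == withf$planted),
       planted_total = sum(withf$planted),
       detected_total = sum(withf$detected),
       n_nuclei = length(withf$planted),
       spurious_rate = mean(blank$detected),
       n_blank_nuclei = length(blank$detected))
}

#' ddCt fold-change recovery benchmark
#'
#' Repeatedly simulates Ct tables with planted folds and measures the
#' absolute relative error of the 2^-ddCt estimate.
#'
#' @param seed master seed.
#' @param folds planted fold changes.
#' @param ct_noise_sd Ct measurement noise (cycles).
#' @param n_replicates replicates per arm.
#' @param n_reps number of seeded repetitions.
#' @return A list with `per_fold` (mean absolute relative error per planted
#'   fold) and `mean_abs_rel_error` over all folds and repetitions.
#' @export
recover_ddct <- function(seed = 1L, folds = c(0.5, 1, 2, 8),
                         ct_noise_sd = 0.2, n_replicates = 4L,
                         n_reps = 200L) {
  genes <- paste0("gene_", seq_along(folds))
  errs <- matrix(NA_real_, n_reps, length(folds))
  for (r in seq_len(n_reps)) {
    tab <- generate_ct_table(genes, folds, n_replicates, ct_noise_sd,
                             seed = seed + r)
    est <- ddct_fold_changes(tab)$genes
    est <- est[match(genes, est$gene), ]
    errs[r, ] <- abs(est$fold_change - folds) / folds
  }
  list(per_fold = data.frame(planted = folds,
                             mean_abs_rel_error = colMeans(errs)),
       mean_abs_rel_error = mean(errs))
}

#' DEG-filter recovery benchmark
#'
#' Applies the differential-expression filter to a seeded table with
#' planted DEGs and reports overlap with the planted set.
#'
#' @param seed RNG seed.
#' @param n_genes,n_deg,planted_lfc table composition, see
#'   [generate_gene_stats()].
#' @return A list with `n_retained`, `n_planted`, `n_planted_retained`,
#'   `all_planted_recovered`, and the filter result.
#' @export
recover_deg <- function(seed = 1L, n_genes = 1000L, n_deg = 50L,
                        planted_lfc = 1) {
  tab <- generate_gene_stats(n_genes, n_deg, planted_lfc, seed = seed)
  res <- deg_filter(tab)
  planted <- tab$gene_id[tab$is_deg_true]
  list(n_retained = length(res$retained),
       n_planted = length(planted),
       n_planted_retained = length(intersect(res$retained, planted)),
       all_planted_recovered = all(planted %in% res$retained),
       filter = res)
}

#' Full parameter-recovery report
#'
#' Runs every recovery benchmark (giant/multinucleated classification,
#' translocation ratios with and without noise, foci counting, ddCt folds
#' at zero and default noise, DEG filter) under one master seed and checks
#' each against its tolerance.
#'
#' @param seed master seed.
#' @param morph_scenes,morph_cells morphometry benchmark size per arm.
#' @param ratio_cells cells per planted translocation ratio.
#' @param foci_scenes,foci_cells foci benchmark size.
#' @param ddct_reps ddCt repetitions.
#' @param tolerances named list of tolerances: `gc_pts`, `mnc_pts`,
#'   `vehicle_gc_max`, `ratio_rel`, `foci_exact_min`, `foci_spurious_max`,
#'   `ddct_rel`.
#' @return A list of class `recovery_report` with each benchmark's numbers
#'   and a logical `checks` vector; `all_pass` summarizes it.
#' @export
run_recover <- function(seed = 1L, morph_scenes = 15L, morph_cells = 35L,
                        ratio_cells = 60L, foci_scenes = 5L,
                        foci_cells = 40L, ddct_reps = 200L,
                        tolerances = list(gc_pts = 3, mnc_pts = 2,
                                          vehicle_gc_max = 1, ratio_rel = 0.1,
                                          foci_exact_min = 0.95,
                                          foci_spurious_max = 0.05,
                                          ddct_rel = 0.15)) {
  morph <- recover_morphometry(seed, n_scenes = morph_scenes,
                               n_cells = morph_cells)
  trans <- recover_translocation(seed, n_cells = ratio_cells, noise = TRUE)
  trans0 <- recover_translocation(seed, n_cells = 20L, noise = FALSE,
                                  truth_masks = TRUE)
  foci <- recover_foci(seed, n_scenes = foci_scenes, n_cells = foci_cells)
  ddct0 <- recover_ddct(seed, ct_noise_sd = 0, n_reps = 1L)
  ddct <- recover_ddct(seed, n_reps = ddct_reps)
  deg <- recover_deg(seed)

  checks <- c(
    gc_recovered = abs(morph$recovered_pct_giant - morph$planted_pct_giant) <=
      tolerances$gc_pts,
    mnc_recovered = abs(morph$recovered_pct_mnc - morph$planted_pct_mnc) <=
      tolerances$mnc_pts,
    vehicle_gc_low = morph$vehicle_pct_giant <= tolerances$vehicle_gc_max,
    ratio_recovered = all(trans$rel_error <= tolerances$ratio_rel),
    ratio_exact_noise_free = all(abs(trans0$mean_recovered - trans0$planted) < 1e-9),
    foci_exact = foci$exact_fraction >= tolerances$foci_exact_min,
    foci_spurious = foci$spurious_rate <= tolerances$foci_spurious_max,
    ddct_exact_noise_free = ddct0$mean_abs_rel_error < 1e-9,
    ddct_noise = ddct$mean_abs_rel_error <= tolerances$ddct_rel,
    deg_all_planted = deg$all_planted_recovered
  )
  structure(list(seed = seed, morphometry = morph, translocation = trans,
                 translocation_noise_free = trans0, foci = foci,
                 ddct_noise_free = ddct0, ddct = ddct, deg = deg,
                 tolerances = tolerances, checks = checks,
                 all_pass = all(checks)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  m <- x$morphometry
  cat(sprintf("recovery_report (seed %d): %s\n", x$seed,
              if (x$all_pass) "all checks pass" else "SOME CHECKS FAIL"))
  cat(sprintf("  GC%%: planted %.2f recovered %.2f | MNC%%: planted %.2f recovered %.2f | vehicle GC%% %.2f\n",
              m$planted_pct_giant, m$recovered_pct_giant,
              m$planted_pct_mnc, m$recovered_pct_mnc, m$vehicle_pct_giant))
  cat(sprintf("  ratio rel. errors: %s | foci exact %.3f, spurious %.3f\n",
              paste(sprintf("%.3f", x$translocation$rel_error), collapse = " "),
              x$foci$exact_fraction, x$foci$spurious_rate))
  cat(sprintf("  ddCt mean abs rel err: %.4f (noise-free %.2e) | DEG planted recovered %d/%d\n",
              x$ddct$mean_abs_rel_error, x$ddct_noise_free$mean_abs_rel_error,
              x$deg$n_planted_retained, x$deg$n_planted))
  for (nm in names(x$checks))
    cat(sprintf("  [%s] %s\n", if (x$checks[[nm]]) "pass" else "FAIL", nm))
  invisible(x)
}
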
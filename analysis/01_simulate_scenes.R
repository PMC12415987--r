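#!/usr/bin/env Rscript

# Step 1: simulate a ground-truthed two-arm imaging experiment.
#
# Generates a vehicle arm (mononucleated, vehicle-sized nuclei only) and an
# exposed arm carrying 20% giant and 10% multinucleated cells — the planted
# composition every later step is benchmarked against — and writes one
# example scene per arm as a multi-page TIFF plus its ground-truth tables.

suppressPackageStartupMessages(library(nucquant))

out_dir <- "results/simulated"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

vehicle_cfg <- scene_config(n_cells = 35, seed = 1)
exposed_cfg <- update_config(vehicle_cfg, giant_fraction = 0.2,
                             mnc_fraction = 0.1)

for (arm in c("vehicle", "exposed")) {
  cfg <- if (arm == "vehicle") vehicle_cfg else exposed_cfg
  sc <- generate_scene(cfg)
  write_stack(sc$stack, file.path(out_dir, paste0(arm, "_scene.tif")))
  write.csv(sc$truth$cells, file.path(out_dir, paste0(arm, "_truth_cells.csv")),
            row.names = FALSE)
  write.csv(sc$truth$nuclei, file.path(out_dir, paste0(arm, "_truth_nuclei.csv")),
            row.names = FALSE)
  cat(sprintf("%s scene: %d cells, %d nuclei, %d giant, %d multinucleated\n",
              arm, nrow(sc$truth$cells), nrow(sc$truth$nuclei),
              sum(sc$truth$cells$is_giant_true),
              sum(sc$truth$cells$is_mnc_true)))
}

cat(sprintf("Scenes and ground truth written under %s\n", out_dir))
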
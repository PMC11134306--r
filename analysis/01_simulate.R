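#!/usr/bin/env Rscript
# Generate the reference synthetic session: a saline-condition two-channel
# movie (NE sensor + calcium indicator) with known ground truth, written to
# results/session/ for the downstream analysis scripts.

library(neflow)

out <- "results/session"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(fov_px = c(128L, 128L), duration_s = 300, n_cells = 9,
                  n_varicosities = 16, release_rate_hz = 0.008,
                  global_drive_amp = 0.4, beta_local = 0.3,
                  beta_globalCa = 0.4, noise_sd = 0.1, seed = 42L)

sim <- simulate_ne_field(cfg)
ca <- simulate_cells(sim$movie, sim$truth, cfg)
two <- render_two_channel(sim$movie, ca, sim$truth, cfg)

write_movie_tiff(two, file.path(out, "movie.tif"))
write_mask_tiff(two$soma_labels, file.path(out, "soma_masks.tif"))
write_truth_json(sim$truth, file.path(out, "ground_truth.json"))
write_config_txt(cfg, file.path(out, "config.txt"))

cat(sprintf("simulated %d frames (%d x %d px), %d ground-truth events (%d release, %d reuptake), %d cells\n",
            nrow(two$green), two$h, two$w, nrow(sim$truth$events),
            sum(sim$truth$events$kind == "release"),
            sum(sim$truth$events$kind == "reuptake"), cfg$n_cells))
cat("wrote movie.tif, soma_masks.tif, ground_truth.json, config.txt to", out, "\n")
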
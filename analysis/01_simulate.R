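#!/usr/bin/env Rscript

# Stage 1: generate a small demonstration dataset for the IP3-uncaging
# FK506 paired experiment — one cell field per animal, paired control and
# treated recordings, rendered to 16-bit TIFF movies with a ground-truth
# event table and JSON sidecar per recording.
#
# The demonstration uses 2 animals x 2 technical replicates at desk-scale
# geometry so it runs in seconds; the statistical recovery at the preset's
# full replication structure lives in 05_recovery.R.

suppressMessages(library(endocal))

out_dir <- "results/simulated"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260920L
px <- 4; h <- 64; w <- 64

pr <- preset("ip3_fk506")
message("Simulating preset ", pr$name, " (demo: 2 animals x 2 reps)")

manifest <- list()
for (a in 1:2) {
  map <- generate_cell_map(h, w, pr$arms$control$n_cells, px,
                           seed = derive_seed(seed, 7L, a),
                           center_bias = TRUE)
  write_cell_map_tiff(map, file.path(out_dir, sprintf("animal%d_cellmap.tif", a)))
  # shared animal deviate across the paired arms
  z <- with(list(), { set.seed(derive_seed(seed, 11L, a)); rnorm(1) })
  for (arm_name in names(pr$arms)) {
    arm <- pr$arms[[arm_name]]
    am <- arm$mean_peak_amp + z * arm$between_animal_sd
    for (r in 1:2) {
      sim <- simulate_traces(arm, map, pr$frame_rate_hz,
                             seed = derive_seed(seed, match(arm_name, names(pr$arms)), a, r),
                             animal_mean = am)
      movie <- render_movie(sim$traces, map, pr$frame_rate_hz,
                            seed = derive_seed(seed, 100L, a, r,
                                               match(arm_name, names(pr$arms))))
      stem <- sprintf("animal%d_%s_rep%d", a, arm_name, r)
      write_movie_tiff(movie, file.path(out_dir, paste0(stem, ".tif")))
      write_ground_truth_csv(sim$truth, file.path(out_dir, paste0(stem, "_truth.csv")),
                             animal = a, tech_rep = r)
      write_sidecar(list(preset = pr$name, arm = arm_name, animal = a,
                         tech_rep = r, seed = sim$truth$seed,
                         frame_rate_hz = pr$frame_rate_hz,
                         pixel_size_um = px,
                         stim_frame = arm$stim_frame),
                    file.path(out_dir, paste0(stem, ".json")))
      manifest[[length(manifest) + 1L]] <- data.frame(
        animal = a, arm = arm_name, tech_rep = r, stem = stem,
        true_animal_mean = sim$truth$animal_true_mean
      )
      message("  wrote ", stem, " (true animal mean ",
              round(sim$truth$animal_true_mean, 3), ")")
    }
  }
}
write.csv(do.call(rbind, manifest), file.path(out_dir, "manifest.csv"),
          row.names = FALSE)
message("Done: ", out_dir)
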
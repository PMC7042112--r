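#!/usr/bin/env Rscript

# Stage 2: read the simulated movies back from disk, extract per-cell raw
# traces over the cell map, restrict uncaging recordings to cells inside
# the 70 um photolysis disc, and write trace tables.

suppressMessages(library(endocal))

in_dir <- "results/simulated"
out_dir <- "results/traces"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

manifest <- read.csv(file.path(in_dir, "manifest.csv"))
for (k in seq_len(nrow(manifest))) {
  row <- manifest[k, ]
  meta <- read_sidecar(file.path(in_dir, paste0(row$stem, ".json")))
  map <- read_cell_map_tiff(
    file.path(in_dir, sprintf("animal%d_cellmap.tif", row$animal)),
    pixel_size_um = meta$pixel_size_um
  )
  movie <- read_movie_tiff(file.path(in_dir, paste0(row$stem, ".tif")),
                           frame_rate_hz = meta$frame_rate_hz,
                           pixel_size_um = meta$pixel_size_um)
  traces <- extract_traces(movie, map)
  center <- c(ncol(map$labels) / 2, nrow(map$labels) / 2)
  photolysed <- uncaging_mask(map, center, diameter_um = 70)
  keep <- traces
  keep$traces <- traces$traces[, photolysed, drop = FALSE]
  keep$cell_ids <- photolysed
  write_traces_csv(keep, file.path(out_dir, paste0(row$stem, "_traces.csv")))
  message(row$stem, ": ", map$n_cells, " cells, ",
          length(photolysed), " inside the photolysis disc")
}
message("Done: ", out_dir)
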
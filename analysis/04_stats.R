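#!/usr/bin/env Rscript

# Stage 4: hierarchical aggregation (cells -> technical replicates ->
# animals) and the condition comparison: paired t test on log-transformed
# per-animal means with back-transformed (geometric) condition means.
# With only the 2 demo animals from stage 1 the test is illustrative;
# 05_recovery.R runs the preset's full replication structure.

suppressMessages(library(endocal))

out_dir <- "results/stats"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cells <- read.csv("results/events/cell_summaries.csv")
tab <- aggregate_cells(cells, metric = "peak_amp", responders_only = TRUE)
write.csv(tab$animal_means, file.path(out_dir, "animal_means.csv"),
          row.names = FALSE)

res <- paired_t_log(tab, "control", "treated")
print(res)

report <- list(
  test = res$test,
  statistic = res$statistic, df = res$df, p_value = res$p_value,
  n_animals = res$n,
  conditions = as.list(stats::setNames(
    lapply(seq_along(res$conditions), function(i) list(
      geometric_mean = res$geometric_mean[i],
      raw_mean = res$raw_mean[i], raw_sem = res$raw_sem[i]
    )), res$conditions))
)
jsonlite::write_json(report, file.path(out_dir, "paired_test.json"),
                     auto_unbox = TRUE, digits = NA)
message("Done: ", out_dir)
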
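#' Run the full measurement pipeline on one simulated seed batch of an arm
#'
#' Simulates every recording of one arm (all animals x technical
#' replicates), optionally renders each recording into a noisy movie and
#' re-extracts the traces, analyses every cell, and aggregates over the
#' replication hierarchy. For uncaging arms only cells inside the photolysis
#' disc are analysed, as in the experiments the generator emulates.
#'
#' @param preset A [condition_preset()] or preset name.
#' @param arm_name Arm to measure.
#' @param seed Batch master seed.
#' @param height,width,pixel_size_um Field geometry (coarser-than-
#'   acquisition geometry gives desk-scale runs; cells keep >= 20 px).
#' @param render Render movies and re-extract traces (`TRUE`, the full
#'   pipeline) or analyse the noise-free traces directly.
#' @param config Optional [analysis_config()]; by default the arm's stimulus
#'   frame and the package defaults are used.
#' @param uncage_diameter_um Photolysis disc diameter.
#' @return Data frame, one row per animal: `animal`, `measured` (per-animal
#'   mean measured peak amplitude), `true` (per-animal mean of the
#'   generator's true amplitudes), `n_cells_analysed`.
#' @export
measure_arm <- function(preset, arm_name, seed = 1L,
                        height = 512L, width = 512L, pixel_size_um = 0.4,
                        render = TRUE, config = NULL,
                        uncage_diameter_um = 70) {
  if (is.character(preset)) preset <- preset(preset)
  arm <- preset$arms[[arm_name]]
  if (is.null(arm)) stop("unknown arm: ", arm_name)
  j <- match(arm_name, names(preset$arms))
  sim <- simulate_experiment(preset, seed = seed, arms = arm_name,
                             height = height, width = width,
                             pixel_size_um = pixel_size_um,
                             uncage_diameter_um = uncage_diameter_um)
  if (is.null(config)) {
    config <- analysis_config(
      stim_frame = arm$stim_frame,
      spont_window = c(1L, min(150L, max(arm$stim_frame - 1L, 1L)))
    )
  }
  fps <- preset$frame_rate_hz
  cells <- list()
  true_by_rec <- list()
  for (rec in sim$arms[[arm_name]]) {
    map <- sim$maps[[rec$animal]]
    analysed <- if (arm$stimulus == "uncaging") rec$truth$eligible else
      seq_len(map$n_cells)
    if (render) {
      movie <- render_movie(
        rec$traces, map, frame_rate_hz = fps,
        seed = derive_seed(seed, 100L + j, rec$animal, rec$tech_rep)
      )
      tr <- extract_traces(movie, map)
    } else {
      tr <- rec$traces
    }
    summ <- analyze_recording(tr, config, frame_rate_hz = fps,
                              cell_ids = analysed)
    summ$animal <- rec$animal
    summ$tech_rep <- rec$tech_rep
    summ$condition <- arm_name
    cells[[length(cells) + 1L]] <- summ
    true_by_rec[[length(true_by_rec) + 1L]] <- data.frame(
      animal = rec$animal, true = rec$truth$animal_true_mean
    )
  }
  cells <- do.call(rbind, cells)
  agg <- aggregate_cells(cells, "peak_amp", responders_only = TRUE)
  am <- agg$animal_means
  tru <- stats::aggregate(true ~ animal, do.call(rbind, true_by_rec), mean)
  n_an <- stats::aggregate(cell_id ~ animal, cells, length)
  out <- data.frame(
    animal = am$animal, measured = am$value,
    true = tru$true[match(am$animal, tru$animal)],
    n_cells_analysed = n_an$cell_id[match(am$animal, n_an$animal)] /
      arm$n_tech_reps
  )
  attr(out, "cells") <- cells
  out
}

#' Parameter recovery for a condition preset
#'
#' The acceptance driver: repeats the full simulate -> render -> extract ->
#' process -> aggregate pipeline for each requested arm over `n_batches`
#' master seeds, and reports, per arm, the grand mean of the per-animal
#' measured means, its Monte-Carlo standard error and 95% CI over batches,
#' and the preset's encoded truth. With two arms a paired log-scale t test
#' is run per batch and the fraction of significant batches reported.
#'
#' @param preset A [condition_preset()] or preset name.
#' @param n_batches Number of master seed batches.
#' @param seed Master seed; batch b uses a sub-seed derived from it.
#' @param arms Arms to recover (default: all arms of the preset).
#' @inheritParams measure_arm
#' @param alpha Significance level for the per-batch paired test.
#' @return A `recovery_report`: per-arm summary data frame (`grand_mean`,
#'   `mc_se`, `ci_lo`, `ci_hi`, `encoded_mean`, `true_grand_mean`), the
#'   per-batch per-animal table, and the paired-test verdict.
#' @export
recover_preset <- function(preset, n_batches = 20L, seed = 1L, arms = NULL,
                           height = 512L, width = 512L, pixel_size_um = 0.4,
                           render = TRUE, alpha = 0.05,
                           uncage_diameter_um = 70) {
  if (is.character(preset)) preset <- preset(preset)
  if (is.null(arms)) arms <- names(preset$arms)
  batches <- list()
  p_values <- rep(NA_real_, n_batches)
  for (b in seq_len(n_batches)) {
    bseed <- derive_seed(seed, 17L, b)
    per_arm <- lapply(arms, function(an) {
      m <- measure_arm(preset, an, seed = bseed, height = height,
                       width = width, pixel_size_um = pixel_size_um,
                       render = render,
                       uncage_diameter_um = uncage_diameter_um)
      m$condition <- an
      m$batch <- b
      m
    })
    per_arm <- do.call(rbind, per_arm)
    batches[[b]] <- per_arm
    if (length(arms) == 2) {
      tb <- structure(list(
        animal_means = data.frame(animal = per_arm$animal,
                                  condition = per_arm$condition,
                                  value = per_arm$measured),
        metric = "peak_amp"), class = "replicate_table")
      p_values[b] <- tryCatch(
        paired_t_log(tb, arms[1], arms[2])$p_value,
        error = function(e) NA_real_)
    }
  }
  all_rows <- do.call(rbind, batches)
  summary <- do.call(rbind, lapply(arms, function(an) {
    rows <- all_rows[all_rows$condition == an, ]
    gm_b <- tapply(rows$measured, rows$batch, mean)  # per-batch grand means
    gm <- mean(gm_b)
    se <- sd(gm_b) / sqrt(length(gm_b))
    data.frame(
      condition = an, grand_mean = gm, mc_se = se,
      ci_lo = gm - 1.96 * se, ci_hi = gm + 1.96 * se,
      encoded_mean = preset$arms[[an]]$mean_peak_amp,
      true_grand_mean = mean(tapply(rows$true, rows$batch, mean))
    )
  }))
  structure(
    list(preset = preset$name, summary = summary, animals = all_rows,
         p_values = p_values,
         frac_significant = if (length(arms) == 2)
           mean(p_values < alpha, na.rm = TRUE) else NA_real_,
         n_batches = n_batches, alpha = alpha, seed = as.integer(seed)),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> preset %s, %d seed batches\n",
              x$preset, x$n_batches))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-22s grand mean %.3f (MC 95%% CI %.3f-%.3f), encoded %.3f\n",
      s$condition[i], s$grand_mean[i], s$ci_lo[i], s$ci_hi[i],
      s$encoded_mean[i]))
  }
  if (!is.na(x$frac_significant)) {
    cat(sprintf("  paired log t test significant at alpha=%.2g in %.0f%% of batches\n",
                x$alpha, 100 * x$frac_significant))
  }
  invisible(x)
}

#' Activity-fraction recovery for the endothelial patch preset
#'
#' Simulates `n_batches` patch recordings (one field of cells each),
#' renders and re-extracts them, runs peak detection, and applies the
#' any-activity rule per phase window. Reports the percentage of active
#' cells per phase, averaged over batches.
#'
#' @param n_batches Seed batches (fields).
#' @param seed Master seed.
#' @param height,width,pixel_size_um Field geometry.
#' @param render Render movies or analyse noise-free traces.
#' @return List with `percent` (named per-phase mean percentages),
#'   `per_batch` (batch x phase matrix), and the encoded fractions.
#' @export
recover_patch_fractions <- function(n_batches = 5L, seed = 1L,
                                    height = 200L, width = 200L,
                                    pixel_size_um = 4, render = TRUE) {
  pr <- preset("patch_ach_caffeine")
  n_cells <- pr$arms[[1]]$n_cells
  fps <- pr$frame_rate_hz
  phases <- names(pr$arms)
  per_batch <- matrix(0, n_batches, length(phases),
                      dimnames = list(NULL, phases))
  for (b in seq_len(n_batches)) {
    bseed <- derive_seed(seed, 23L, b)
    map <- generate_cell_map(height, width, n_cells, pixel_size_um,
                             seed = derive_seed(bseed, 7L))
    sim <- simulate_patch_recording(pr, map, seed = bseed,
                                    frame_rate_hz = fps)
    if (render) {
      movie <- render_movie(sim$traces, map, frame_rate_hz = fps,
                            seed = derive_seed(bseed, 5L))
      mat <- extract_traces(movie, map)$traces
    } else {
      mat <- sim$traces
    }
    config <- analysis_config(stim_frame = 1L)
    bfr <- seq_len(config$baseline_frames)
    ff0_mat <- sweep(mat, 2, colMeans(mat[bfr, , drop = FALSE]), "/")
    smooth_mat <- smooth_columns(ff0_mat,
                                 savgol_coef(config$window, config$polyorder))
    for (i in seq_len(n_cells)) {
      ns <- mad(ff0_mat[bfr, i] - smooth_mat[bfr, i])
      peaks <- detect_peaks(smooth_mat[, i], fps, ns, config$k_sigma,
                            config$min_amplitude)
      for (ph in phases) {
        w <- sim$windows[[ph]]
        active <- any(peaks$frame >= w[1] & peaks$frame <= w[2])
        per_batch[b, ph] <- per_batch[b, ph] + active
      }
    }
    per_batch[b, ] <- 100 * per_batch[b, ] / n_cells
  }
  encoded <- c(
    baseline = pr$arms$baseline$spontaneous_fraction * 100,
    ach = pr$arms$ach$responder_fraction * 100,
    caffeine = pr$arms$caffeine$spontaneous_fraction * 100
  )
  list(percent = colMeans(per_batch), per_batch = per_batch,
       encoded = encoded[phases], n_batches = n_batches)
}
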
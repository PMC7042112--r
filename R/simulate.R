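#' Simulate noise-free per-cell F/F0 traces for one recording
#'
#' Generates the ground-truth Ca2+ activity of every cell in `map` under one
#' condition arm. Responding cells carry a stimulus-locked transient whose
#' true amplitude is drawn hierarchically: an animal-level mean from
#' `mean_peak_amp +/- between_animal_sd` (truncated positive) unless supplied
#' via `animal_mean`, then a cell-level amplitude from a lognormal
#' distribution with that mean and the arm's cell-level coefficient of
#' variation. The initial transient is followed by a Poisson train of smaller
#' oscillation transients at `oscillation_rate_hz`. Cells flagged as
#' spontaneously active carry at least one baseline event; for
#' `stimulus = "none"` arms spontaneous events occur anywhere in the record.
#'
#' For `stimulus = "uncaging"` only cells inside the photolysis disc
#' (70 um diameter at the field centre by default) are eligible to respond,
#' mirroring localized flash photolysis.
#'
#' The noise-free baseline of every trace is exactly 1 before its first
#' event.
#'
#' @param arm A [condition_arm()].
#' @param map A [cell_map()].
#' @param frame_rate_hz Acquisition rate, Hz.
#' @param n_frames Number of frames (defaults to the arm's).
#' @param seed Integer seed; output is a pure function of it and the inputs.
#' @param animal_mean Optional fixed animal-level true mean amplitude
#'   (shared across the technical replicates of one animal).
#' @param uncage_center,uncage_diameter_um Photolysis disc geometry for
#'   uncaging arms; the default disc sits at the field centre.
#' @return A list with `traces` (frames x cells matrix of noise-free F/F0),
#'   `truth` (the ground-truth record: per-event table, per-cell flags, the
#'   animal-level true mean, eligible cell ids and the seed used).
#' @export
simulate_traces <- function(arm, map, frame_rate_hz = 10,
                            n_frames = arm$n_frames, seed = 1L,
                            animal_mean = NULL,
                            uncage_center = NULL, uncage_diameter_um = 70) {
  stopifnot(inherits(arm, "condition_arm"), inherits(map, "cell_map"))
  if (arm$stim_frame >= n_frames) stop("stim_frame must be < n_frames")
  n_cells <- map$n_cells
  with_seed(seed, {
    eligible <- seq_len(n_cells)
    if (arm$stimulus == "uncaging") {
      if (is.null(uncage_center)) {
        uncage_center <- c(ncol(map$labels) / 2, nrow(map$labels) / 2)
      }
      eligible <- uncaging_mask(map, uncage_center, uncage_diameter_um)
      if (length(eligible) == 0) {
        stop("no cells inside the uncaging disc")
      }
    }
    if (is.null(animal_mean)) {
      animal_mean <- draw_animal_mean(arm$mean_peak_amp, arm$between_animal_sd)
    }
    responder <- logical(n_cells)
    if (arm$stimulus != "none" && arm$responder_fraction > 0) {
      responder[eligible] <-
        rbinom(length(eligible), 1L, arm$responder_fraction) == 1L
    }
    spont <- rbinom(n_cells, 1L, arm$spontaneous_fraction) == 1L

    events <- plan_events(arm, n_cells, responder, spont, animal_mean,
                          frame_rate_hz, n_frames)
    traces <- synthesize_traces(events, n_cells, n_frames, frame_rate_hz,
                                arm$rise_tau_s, arm$decay_tau_s)
    stim_amp <- events$amplitude[events$kind == "stim"]
    truth <- list(
      events = events,
      responder = responder,
      spont_active = spont,
      eligible = eligible,
      animal_mean_drawn = animal_mean,
      animal_true_mean = if (length(stim_amp)) mean(stim_amp) else NA_real_,
      seed = as.integer(seed)
    )
    list(traces = traces, truth = truth)
  })
}

# Truncated-positive normal draw for the animal-level mean.
draw_animal_mean <- function(mean, sd) {
  if (sd == 0) return(mean)
  repeat {
    m <- rnorm(1, mean, sd)
    if (m > 0) return(m)
  }
}

# Event table for one recording: cell_id, kind (stim/osc/spont), onset_s,
# amplitude, frame/time_s of the true apex.
plan_events <- function(arm, n_cells, responder, spont, animal_mean,
                        fps, n_frames) {
  cv <- if (arm$mean_peak_amp > 0) {
    arm$between_cell_sd / arm$mean_peak_amp
  } else 0
  sdlog <- sqrt(log(1 + cv^2))
  t_end <- (n_frames - 1) / fps
  t_stim <- (arm$stim_frame - 1) / fps
  # events stop 3 s before the record/phase end (perfusion switch margin),
  # so that an event's apex cannot smear past its own window
  t_last <- t_end - 3
  cid <- integer(); kind <- character(); onset <- numeric(); ampl <- numeric()
  add <- function(i, k, on, am) {
    n <- length(on)
    cid <<- c(cid, rep.int(i, n)); kind <<- c(kind, rep.int(k, n))
    onset <<- c(onset, on); ampl <<- c(ampl, am)
  }
  for (i in seq_len(n_cells)) {
    if (responder[i]) {
      amp <- rlnorm(1, log(animal_mean) - sdlog^2 / 2, sdlog)
      add(i, "stim", t_stim, amp)
      # oscillation train after the initial transient: renewal process with
      # a 3 s refractory (store refill) and mean interval 1/rate, so
      # successive peaks stay resolvable and subordinate to the initial
      # transient
      if (arm$oscillation_rate_hz > 0 && t_stim + 3 < t_last) {
        refract <- 3
        exp_mean <- max(1 / arm$oscillation_rate_hz - refract, 0.5)
        tt <- t_stim
        repeat {
          tt <- tt + refract + rexp(1, 1 / exp_mean)
          if (tt >= t_last) break
          frac <- pmin(0.35 * exp(rnorm(1, 0, 0.25)), 0.7)
          add(i, "osc", tt, amp * frac)
        }
      }
    }
    if (spont[i]) {
      # spontaneous activity: whole record for unstimulated arms, otherwise
      # the pre-stimulus baseline (first 150 frames at most)
      w_end <- if (arm$stimulus == "none") t_last else {
        (min(150, arm$stim_frame - 1) - 1) / fps - 1
      }
      if (w_end > 0.5) {
        n_ev <- max(1L, rpois(1, 0.05 * w_end))
        add(i, "spont", sort(runif(n_ev, 0, w_end)),
            0.3 * exp(rnorm(n_ev, 0, 0.25)))
      }
    }
  }
  if (length(cid) == 0) {
    return(data.frame(cell_id = integer(), kind = character(),
                      onset_s = numeric(), amplitude = numeric(),
                      frame = integer(), time_s = numeric()))
  }
  ev <- data.frame(cell_id = cid, kind = kind, onset_s = onset,
                   amplitude = ampl)
  apex <- transient_peak_time(ev$onset_s, arm$rise_tau_s, arm$decay_tau_s)
  ev$time_s <- apex
  ev$frame <- pmin(as.integer(round(apex * fps)) + 1L, n_frames)
  ev[order(ev$cell_id, ev$onset_s), , drop = FALSE]
}

# Sum transient kernels into a frames x cells matrix with baseline 1.
synthesize_traces <- function(events, n_cells, n_frames, fps,
                              rise_tau_s, decay_tau_s) {
  tgrid <- (seq_len(n_frames) - 1) / fps
  traces <- matrix(1, n_frames, n_cells)
  if (nrow(events)) {
    horizon <- 8 * decay_tau_s
    for (k in seq_len(nrow(events))) {
      i0 <- max(1L, as.integer(floor(events$onset_s[k] * fps)) + 1L)
      i1 <- min(n_frames, as.integer(ceiling((events$onset_s[k] + horizon) * fps)) + 1L)
      idx <- i0:i1
      traces[idx, events$cell_id[k]] <- traces[idx, events$cell_id[k]] +
        transient_kernel(tgrid[idx], events$onset_s[k], events$amplitude[k],
                         rise_tau_s, decay_tau_s)
    }
  }
  traces
}

#' Simulate one seed batch of a condition preset
#'
#' Draws `n_animals` animals with a shared standard-normal animal deviate
#' across arms (the paired before/after design: each artery is its own
#' control), one cell field per animal, and `n_tech_reps` recordings per
#' animal and arm. All randomness derives from `seed`.
#'
#' @param preset A [condition_preset()] or preset name.
#' @param seed Master seed for the batch.
#' @param arms Which arms to simulate (default all).
#' @param height,width,pixel_size_um Field geometry.
#' @param uncage_diameter_um Photolysis disc diameter for uncaging arms.
#' @return A list with one element per arm; each is a list of recordings
#'   carrying `animal`, `tech_rep`, `traces`, `truth`, and the shared
#'   `map` per animal in `maps`.
#' @export
simulate_experiment <- function(preset, seed = 1L, arms = NULL,
                                height = 512L, width = 512L,
                                pixel_size_um = 0.4,
                                uncage_diameter_um = 70) {
  if (is.character(preset)) preset <- preset(preset)
  if (is.null(arms)) arms <- names(preset$arms)
  stopifnot(all(arms %in% names(preset$arms)))
  n_animals <- max(vapply(preset$arms[arms], `[[`, 1L, "n_animals"))
  fps <- preset$frame_rate_hz

  arm1 <- preset$arms[[arms[1]]]
  maps <- lapply(seq_len(n_animals), function(a) {
    generate_cell_map(height, width, arm1$n_cells, pixel_size_um,
                      seed = derive_seed(seed, 7L, a),
                      center_bias = arm1$stimulus == "uncaging")
  })
  # shared animal-level deviates; redrawn jointly if any arm mean would be
  # non-positive (truncation applied to the pair)
  z <- with_seed(derive_seed(seed, 11L), {
    vapply(seq_len(n_animals), function(a) {
      repeat {
        zz <- rnorm(1)
        ok <- all(vapply(preset$arms[arms], function(arm) {
          arm$mean_peak_amp + zz * arm$between_animal_sd > 0
        }, TRUE))
        if (ok) return(zz)
      }
    }, 1)
  })

  out <- lapply(seq_along(arms), function(jj) {
    j <- match(arms[jj], names(preset$arms))  # index in the full preset
    arm <- preset$arms[[j]]
    recs <- list()
    for (a in seq_len(arm$n_animals)) {
      am <- arm$mean_peak_amp + z[a] * arm$between_animal_sd
      for (r in seq_len(arm$n_tech_reps)) {
        sim <- simulate_traces(
          arm, maps[[a]], frame_rate_hz = fps, seed = derive_seed(seed, j, a, r),
          animal_mean = am, uncage_diameter_um = uncage_diameter_um
        )
        recs[[length(recs) + 1L]] <- list(
          animal = a, tech_rep = r, arm = arm$name,
          traces = sim$traces, truth = sim$truth
        )
      }
    }
    recs
  })
  names(out) <- arms
  list(preset = preset$name, arms = out, maps = maps,
       frame_rate_hz = fps, seed = as.integer(seed))
}

#' Simulate an endothelial-patch recording
#'
#' One continuous recording per animal in which the phases of the preset
#' (`baseline`, agonist, `caffeine` for the registered patch preset) are
#' concatenated in arm order; each phase's events are generated by the same
#' machinery as [simulate_traces()] restricted to its window.
#'
#' @param preset A [condition_preset()] whose arms are sequential phases.
#' @param map A [cell_map()].
#' @param seed Integer seed.
#' @param frame_rate_hz Acquisition rate, Hz.
#' @return A list with `traces` (frames x cells), `windows` (named list of
#'   `c(first, last)` frame per phase), and `truth` with per-phase per-cell
#'   activity flags and the event table.
#' @export
simulate_patch_recording <- function(preset, map, seed = 1L,
                                     frame_rate_hz = 10) {
  if (is.character(preset)) preset <- preset(preset)
  n_cells <- map$n_cells
  phase_len <- vapply(preset$arms, `[[`, 1L, "n_frames")
  offsets <- c(0L, cumsum(phase_len))
  n_total <- sum(phase_len)
  arm1 <- preset$arms[[1]]
  windows <- lapply(seq_along(preset$arms),
                    function(j) c(offsets[j] + 1L, offsets[j + 1L]))
  names(windows) <- names(preset$arms)

  with_seed(seed, {
    all_events <- list()
    flags <- list()
    for (j in seq_along(preset$arms)) {
      arm <- preset$arms[[j]]
      responder <- logical(n_cells)
      if (arm$stimulus != "none" && arm$responder_fraction > 0) {
        responder <- rbinom(n_cells, 1L, arm$responder_fraction) == 1L
      }
      spont <- rbinom(n_cells, 1L, arm$spontaneous_fraction) == 1L
      am <- draw_animal_mean(arm$mean_peak_amp, arm$between_animal_sd)
      ev <- plan_events(arm, n_cells, responder, spont, am,
                        frame_rate_hz, arm$n_frames)
      if (nrow(ev)) {
        ev$onset_s <- ev$onset_s + offsets[j] / frame_rate_hz
        ev$time_s <- ev$time_s + offsets[j] / frame_rate_hz
        ev$frame <- ev$frame + offsets[j]
        ev$phase <- names(preset$arms)[j]
        all_events[[j]] <- ev
      }
      flags[[j]] <- data.frame(
        cell_id = seq_len(n_cells), phase = names(preset$arms)[j],
        active = responder | spont
      )
    }
    events <- if (length(all_events)) do.call(rbind, all_events) else
      data.frame()
    traces <- synthesize_traces(events, n_cells, n_total, frame_rate_hz,
                                arm1$rise_tau_s, arm1$decay_tau_s)
    list(
      traces = traces, windows = windows,
      truth = list(events = events, flags = do.call(rbind, flags),
                   seed = as.integer(seed))
    )
  })
}
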
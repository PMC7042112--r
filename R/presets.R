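#' Condition arm specification
#'
#' One experimental arm (e.g. "control" or "FK506-treated") of a condition
#' preset: the true effect sizes, replication structure, and stimulus
#' paradigm from which synthetic recordings are generated.
#'
#' `between_animal_sd` is the SD of the per-animal true mean peak amplitude;
#' presets derive it from a reported SEM as `SEM * sqrt(n_animals)`.
#' `between_cell_sd` is the SD of cell-level amplitudes around the animal
#' mean (cell amplitudes are lognormal with that mean and SD).
#'
#' @param name Arm label.
#' @param mean_peak_amp True population mean peak amplitude, dF/F0.
#' @param between_animal_sd SD of per-animal means, dF/F0.
#' @param between_cell_sd SD of per-cell amplitudes around the animal mean.
#' @param responder_fraction Fraction of (stimulated) cells that respond.
#' @param spontaneous_fraction Fraction of cells with spontaneous baseline
#'   activity.
#' @param oscillation_rate_hz Rate of the Poisson oscillation train that
#'   follows the initial stimulus-locked transient.
#' @param rise_tau_s,decay_tau_s Transient kinetics, s.
#' @param stimulus One of `"uncaging"`, `"agonist_flow"`, `"none"`.
#' @param stim_frame 1-based frame of stimulus onset.
#' @param n_animals,n_tech_reps,n_cells Replication structure.
#' @param n_frames Frames per recording.
#' @param note Free-text provenance note for the encoded values.
#' @return An object of class `condition_arm`.
#' @export
condition_arm <- function(name, mean_peak_amp, between_animal_sd,
                          between_cell_sd = 0.4 * mean_peak_amp,
                          responder_fraction = 1,
                          spontaneous_fraction = 0.1,
                          oscillation_rate_hz = 0.2,
                          rise_tau_s = 0.3, decay_tau_s = 3,
                          stimulus = c("uncaging", "agonist_flow", "none"),
                          stim_frame = 150L,
                          n_animals = 5L, n_tech_reps = 3L, n_cells = 30L,
                          n_frames = 1000L, note = "") {
  stimulus <- match.arg(stimulus)
  stopifnot(
    between_animal_sd >= 0, between_cell_sd >= 0,
    responder_fraction >= 0, responder_fraction <= 1,
    spontaneous_fraction >= 0, spontaneous_fraction <= 1,
    oscillation_rate_hz >= 0,
    decay_tau_s > rise_tau_s, rise_tau_s > 0,
    n_animals >= 1, n_tech_reps >= 1, n_cells >= 1,
    stim_frame < n_frames
  )
  if (stimulus != "none" && !(mean_peak_amp > 0)) {
    stop("mean_peak_amp must be > 0 for a stimulated arm")
  }
  structure(
    list(
      name = name, mean_peak_amp = mean_peak_amp,
      between_animal_sd = between_animal_sd,
      between_cell_sd = between_cell_sd,
      responder_fraction = responder_fraction,
      spontaneous_fraction = spontaneous_fraction,
      oscillation_rate_hz = oscillation_rate_hz,
      rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
      stimulus = stimulus, stim_frame = as.integer(stim_frame),
      n_animals = as.integer(n_animals),
      n_tech_reps = as.integer(n_tech_reps),
      n_cells = as.integer(n_cells),
      n_frames = as.integer(n_frames),
      note = note
    ),
    class = "condition_arm"
  )
}

#' Condition preset
#'
#' A named, ordered collection of [condition_arm()] specs sharing one
#' replication structure (paired arms are simulated with a shared per-animal
#' deviate, matching the paired before/after design of the experiments the
#' presets encode).
#'
#' @param name Preset identifier.
#' @param arms Named list of [condition_arm()] objects.
#' @param frame_rate_hz Acquisition rate, Hz.
#' @return An object of class `condition_preset`.
#' @export
condition_preset <- function(name, arms, frame_rate_hz = 10) {
  stopifnot(length(arms) >= 1, all(vapply(arms, inherits, TRUE, "condition_arm")))
  if (is.null(names(arms)) || any(names(arms) == "")) {
    names(arms) <- vapply(arms, `[[`, "", "name")
  }
  structure(
    list(name = name, arms = arms, frame_rate_hz = frame_rate_hz),
    class = "condition_preset"
  )
}

#' @export
print.condition_preset <- function(x, ...) {
  cat(sprintf("<condition_preset> %s (%d arms, %g fps)\n",
              x$name, length(x$arms), x$frame_rate_hz))
  for (a in x$arms) {
    cat(sprintf(
      "  %-22s mean %.3g (animal SD %.3g), resp %.2f, spont %.2f, %s, n=%d x %d reps x %d cells\n",
      a$name, a$mean_peak_amp, a$between_animal_sd, a$responder_fraction,
      a$spontaneous_fraction, a$stimulus, a$n_animals, a$n_tech_reps, a$n_cells
    ))
  }
  invisible(x)
}

# Reported mean +/- SEM at n animals -> condition_arm arguments.
reported <- function(mean, sem, n) {
  list(mean_peak_amp = mean, between_animal_sd = sem * sqrt(n), n_animals = n)
}

#' Named condition presets
#'
#' Returns one of the registered condition presets. Arm means and the
#' between-animal SDs are set so that the true population mean and its SEM at
#' the registered number of animals equal the reported condition summaries
#' the presets encode (treated throughout as peak dF/F0 above a baseline of
#' 1). Paired arms share animals.
#'
#' Registered presets: `ip3_fk506`, `ach_fk506`, `ip3_cypermethrin`,
#' `ach_cypermethrin`, `ip3_okadaic`, `ip3_okadaic_fk506`, `ip3_rapamycin`,
#' `ryanodine_panel`, `patch_ach_caffeine`.
#'
#' @param name Preset identifier.
#' @return A [condition_preset()].
#' @export
preset <- function(name) {
  reg <- preset_registry()
  if (!name %in% names(reg)) {
    stop(sprintf("unknown preset '%s'; available: %s",
                 name, paste(names(reg), collapse = ", ")))
  }
  reg[[name]]()
}

#' @rdname preset
#' @export
preset_names <- function() names(preset_registry())

uncaging_arm <- function(name, mean, sem, n, note) {
  do.call(condition_arm, c(
    reported(mean, sem, n),
    list(name = name, stimulus = "uncaging", stim_frame = 150L,
         n_frames = 1000L, n_cells = 30L, responder_fraction = 1,
         spontaneous_fraction = 0.1, note = note)
  ))
}

agonist_arm <- function(name, mean, sem, n, note, n_frames = 2000L,
                        stim_frame = 300L, responder_fraction = 0.96) {
  do.call(condition_arm, c(
    reported(mean, sem, n),
    list(name = name, stimulus = "agonist_flow", stim_frame = stim_frame,
         n_frames = n_frames, n_cells = 100L,
         responder_fraction = responder_fraction,
         spontaneous_fraction = 0.1, note = note)
  ))
}

preset_registry <- function() {
  list(
    ip3_fk506 = function() condition_preset("ip3_fk506", list(
      control = uncaging_arm("control", 1.41, 0.10, 5,
        "IP3-uncaging control arm: reported peak dF/F0 1.41 +/- 0.10 SEM, n = 5"),
      treated = uncaging_arm("treated", 1.81, 0.20, 5,
        "IP3-uncaging after FK506 10 uM: reported 1.81 +/- 0.20 SEM, n = 5")
    )),
    ach_fk506 = function() condition_preset("ach_fk506", list(
      control = agonist_arm("control", 0.78, 0.10, 6,
        "ACh 50 nM control arm: reported peak dF/F0 0.78 +/- 0.1 SEM, n = 6"),
      treated = agonist_arm("treated", 0.85, 0.10, 6,
        "ACh after FK506 10 uM: reported 0.85 +/- 0.1 SEM, n = 6")
    )),
    ip3_cypermethrin = function() condition_preset("ip3_cypermethrin", list(
      control = uncaging_arm("control", 1.45, 0.14, 7,
        "IP3-uncaging control arm: reported 1.45 +/- 0.14 SEM, n = 7 (body text; figure legend disagrees on n)"),
      treated = uncaging_arm("treated", 1.73, 0.14, 7,
        "IP3-uncaging after cypermethrin 10 uM: reported 1.73 +/- 0.14 SEM, n = 7")
    )),
    ach_cypermethrin = function() condition_preset("ach_cypermethrin", list(
      control = agonist_arm("control", 0.88, 0.11, 5,
        "ACh control arm: reported 0.88 +/- 0.11 SEM, n = 5 (body text; figure legend disagrees on n)"),
      treated = agonist_arm("treated", 1.05, 0.12, 5,
        "ACh after cypermethrin 10 uM: reported 1.05 +/- 0.12 SEM, n = 5")
    )),
    ip3_okadaic = function() condition_preset("ip3_okadaic", list(
      control = uncaging_arm("control", 1.30, 0.12, 6,
        "IP3-uncaging control arm: reported 1.30 +/- 0.12 SEM, n = 6"),
      treated = uncaging_arm("treated", 1.52, 0.17, 6,
        "IP3-uncaging after okadaic acid 5 uM: reported 1.52 +/- 0.17 SEM, n = 6")
    )),
    ip3_okadaic_fk506 = function() condition_preset("ip3_okadaic_fk506", list(
      control = uncaging_arm("control", 1.52, 0.17, 6,
        "IP3-uncaging after okadaic acid alone: reported 1.52 +/- 0.17 SEM, n = 6"),
      treated = uncaging_arm("treated", 1.33, 0.19, 6,
        "IP3-uncaging after okadaic acid + FK506: reported 1.33 +/- 0.19 SEM, n = 6")
    )),
    ip3_rapamycin = function() condition_preset("ip3_rapamycin", list(
      control = uncaging_arm("control", 1.45, 0.25, 5,
        "IP3-uncaging control arm: reported 1.45 +/- 0.25 SEM, n = 5"),
      treated = uncaging_arm("treated", 1.48, 0.23, 5,
        "IP3-uncaging after rapamycin 10 uM: reported 1.48 +/- 0.23 SEM, n = 5 (null result)")
    )),
    # Intact-artery RyR panel; summary values reported in arbitrary
    # fluorescence units are encoded as dF/F0 equivalents. The ryanodine /
    # caffeine arms sit below the detector floor by design: they encode
    # essentially-no-response conditions and are qualitative.
    ryanodine_panel = function() condition_preset("ryanodine_panel", list(
      ach_baseline = agonist_arm("ach_baseline", 0.30, 0.06, 5,
        "baseline ACh response: reported 0.3 +/- 0.06 AFU, n = 5",
        n_frames = 1000L, stim_frame = 300L),
      ryanodine = agonist_arm("ryanodine", 0.05, 0.02, 5,
        "ryanodine 30 uM alone: reported 0.05 +/- 0.02 AFU (near-null)",
        n_frames = 1000L, stim_frame = 300L, responder_fraction = 0.25),
      ryanodine_caffeine = agonist_arm("ryanodine_caffeine", 0.006, 0.003, 5,
        "ryanodine in the presence of caffeine: reported 0.006 +/- 0.003 AFU (near-null)",
        n_frames = 1000L, stim_frame = 300L, responder_fraction = 0.25),
      ryanodine_inc_caffeine = agonist_arm("ryanodine_inc_caffeine", 0.001, 0.001, 5,
        "caffeine after 15-min ryanodine incubation: reported 0.001 +/- 0.001 AFU (near-null)",
        n_frames = 1000L, stim_frame = 300L, responder_fraction = 0.25),
      ach_ryanodine = agonist_arm("ach_ryanodine", 0.54, 0.08, 5,
        "ACh in the presence of ryanodine: reported 0.54 +/- 0.08 AFU, n = 5",
        n_frames = 1000L, stim_frame = 300L)
    )),
    # Dissociated aortic endothelial patches: one continuous recording with
    # sequential baseline / ACh / caffeine windows. Activity fractions encode
    # the reported 48% baseline, 96% ACh, 16% caffeine (n = 5). The ACh
    # response amplitude is not reported for patches; 1.0 dF/F0 is a
    # representative robust agonist response.
    patch_ach_caffeine = function() condition_preset("patch_ach_caffeine", list(
      baseline = condition_arm("baseline", mean_peak_amp = 0.3,
        between_animal_sd = 0, spontaneous_fraction = 0.48,
        responder_fraction = 0, stimulus = "none", stim_frame = 1L,
        n_animals = 5L, n_tech_reps = 1L, n_cells = 100L, n_frames = 600L,
        note = "baseline window: reported 48% of patch cells spontaneously active, n = 5"),
      ach = condition_arm("ach", mean_peak_amp = 1.0,
        between_animal_sd = 0.15, responder_fraction = 0.96,
        spontaneous_fraction = 0, stimulus = "agonist_flow", stim_frame = 20L,
        n_animals = 5L, n_tech_reps = 1L, n_cells = 100L, n_frames = 600L,
        note = "ACh window: reported 96% of patch cells responding, n = 5"),
      caffeine = condition_arm("caffeine", mean_peak_amp = 0.3,
        between_animal_sd = 0, spontaneous_fraction = 0.16,
        responder_fraction = 0, stimulus = "none", stim_frame = 1L,
        n_animals = 5L, n_tech_reps = 1L, n_cells = 100L, n_frames = 600L,
        note = "caffeine window: reported 16% of patch cells active, n = 5")
    ))
  )
}
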
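---
title: "Measuring single-cell Ca2+ release in en face endothelium: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-cell Ca2+ release in en face endothelium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Pharmacological studies of endothelial IP~3~ receptor regulation compare
evoked Ca^2+^ release — reported by a fluorescent indicator such as Cal-520 —
before and after drug incubation in the *same* preparation. The raw data are
fluorescence movie stacks (10 frames s^-1^; 512 × 512 pixel fields holding
tens to a hundred endothelial cells) under two stimulation paradigms:

* **Localized IP~3~ uncaging** — a ~70 µm flash-photolysis disc releases
  caged IP~3~ in a subgroup of cells 15 s into a 1,000-frame record. Only
  cells directly inside the disc are analysed.
* **Agonist perfusion** — ACh under flow drives muscarinic IP~3~ production
  across the whole field during 2,000-frame records.

`endocal` implements the measurement chain for these experiments, and a
synthetic-movie generator whose condition presets encode published condition
summaries as ground truth, so that the chain can be validated end-to-end by
parameter recovery: simulated recordings with known per-cell event times and
amplitudes are pushed through the identical code path a real movie would
take, and the recovered condition means are compared with the encoded
truths.

## The measurement chain

1. **ROI extraction** (`extract_traces`). The raw trace of a cell is the
   arithmetic mean of movie intensity over the cell's pixels in a label map,
   frame by frame. Extraction is linear in the movie.
2. **Baseline normalization** (`normalize_f_f0`). Each trace is divided by
   the mean of its first 100 frames (F~0~), giving F/F~0~ with baseline 1.
3. **Smoothing** (`savgol_smooth`). A 21-point, third-order Savitzky–Golay
   filter; each point becomes the centre value of a least-squares cubic
   fitted to its 21-point neighbourhood. The filter reproduces cubic trends
   exactly and preserves DC. Edges are mirror-padded; polynomial
   reproduction is asserted only at interior points. A 20-point moving mean
   (`moving_average`) is available as the alternate smoother used for
   dissociated endothelial patch recordings.
4. **Peak detection** (`detect_peaks`). Candidate events are the
   positive-to-negative zero crossings of the discrete derivative of the
   smoothed trace (plateaus resolve to their first frame — equivalently, an
   exhaustive local-maximum scan, which is how the suite cross-checks it).
   A candidate is retained when its amplitude (smoothed F/F~0~ − 1) **and**
   its topographic prominence both reach `max(k_sigma × sigma_noise,
   min_amplitude)`, defaults `k_sigma = 3`, `min_amplitude = 0.05` ΔF/F~0~.
   `sigma_noise` is a robust (MAD × 1.4826) SD of the residual between the
   raw and smoothed F/F~0~ over the baseline window.
5. **Per-cell metrics** (`summarize_cell`): peak amplitude (maximum smoothed
   F/F~0~ in the response window − 1, reported when at least one retained
   peak lies in the window), oscillation count, mean F/F~0~, response
   duration (first-to-last crossing of the detection threshold level), a
   responder flag (any retained peak in the window), and a
   spontaneous-activity flag (any retained peak in the first 150 frames).
6. **Hierarchy and statistics** (`aggregate_cells`, `paired_t_log`,
   `anova2_tukey`). Cells average into technical replicates (three repeat
   recordings per condition), replicates into animals; per-animal means are
   the statistical unit (n = animals). Condition comparisons log-transform
   the per-animal means, run a paired two-sided t test (or a two-way ANOVA
   with Tukey contrasts for factorial layouts), and back-transform the
   means, i.e. report geometric means; raw means ± SEM are reported
   alongside.

### Why the detector uses prominence as well as amplitude

A pure amplitude threshold cannot distinguish a genuine oscillation from a
noise ripple riding on the *elevated tail* of a large transient: every tiny
local maximum on a tail that is still above threshold would count as an
event. With realistic photon noise this produces on the order of one
spurious peak per large transient, which would ruin oscillation counts and
the detector's false-discovery rate while leaving amplitudes untouched. The
detector therefore requires topographic prominence — height above the
higher of the two bases toward the nearest higher point — to reach the same
threshold as the amplitude. An isolated transient has prominence equal to
its amplitude, so the criterion is inactive exactly where the simple rule is
sound; tail ripples have prominence of a few noise SDs and are rejected. The
suite verifies ≥95% sensitivity and ≤5% false discovery for 0.3 ΔF/F~0~
transients at default render noise.

## The synthetic generator

### Cell fields

`generate_cell_map` places spindle-shaped elliptical cells (~10 × 40 µm,
jittered, randomly oriented; every cell ≥ 20 px, 4-connected) by rejection
sampling, shrinking gradually under crowding as a confluent monolayer does.
Photolysis fields use centre-biased placement (`center_bias = TRUE`),
because the light guide is aimed at the imaged cell group; the included-cell
count then stays small relative to the field, as in the real uncaging
experiments.

### Events and traces

A Ca^2+^ transient is a peak-normalized difference of exponentials with
rise 0.3 s and decay 3 s by default — kinetics chosen so that oscillation
peaks ~5 s apart remain resolvable (published traces show no kinetic
parameters; these are representative values for a fast indicator at 10 fps).
A responding cell carries a stimulus-locked transient whose amplitude is
drawn hierarchically:

* animal level — normal with the arm's mean and between-animal SD,
  truncated positive; technical replicates of one animal share the draw;
* cell level — lognormal with the animal mean and the arm's cell-level CV
  (default 40%); positive support matches the log-scale statistics used
  downstream.

The initial transient is followed by an oscillation train: a renewal
process with a 3 s refractory period (store refill) and mean interval
1/`oscillation_rate_hz`, amplitudes ~35% of the cell's stimulus amplitude
(lognormal jitter, capped at 70%). The refractory period keeps stacked
oscillations subordinate to the stimulus transient, so the window maximum
measures the stimulus response. Spontaneously active cells carry at least
one baseline event (0.3 ΔF/F~0~ scale) in the pre-stimulus window, or
anywhere in the record for unstimulated arms; event trains end 3 s before a
record or phase boundary so an apex cannot smear into the next analysis
window. Noise-free traces have baseline exactly 1 before each cell's first
event, and the per-event table (cell, onset, apex frame, amplitude, kind)
plus all derived seeds form the ground truth.

### The forward imaging model

`render_movie` draws each pixel of cell *i* at frame *t* from
Poisson(`baseline_counts` × F~i~(t) × (1 − bleach)^t^), adds optional
Gaussian read noise, clips at zero and quantizes to integer counts.
Defaults: 500 photons/pixel at F/F~0~ = 1 (a bright EMCCD signal; a ~24 px
cell then has ~0.9% trace noise), background at F/F~0~ = 0.15, read noise 0
(EM-gain regime; set it positive to emulate a conventional camera), and no
photobleaching. At 10^6^ counts the render → extract round trip recovers
the input traces to 10^-3^ relative error, which the suite asserts.

Slow drift is modelled explicitly through `bleach_rate_per_frame` but is
**off by default**, deliberately: the condition summaries the presets
encode are themselves the outputs of a measurement pipeline, already
containing whatever drift the original recordings had, so baking drift
into the recovery conditions would double-count it and guarantee a known
bias in every recovered mean. With an F/F~0~ pipeline (no drift
correction, F~0~ from the leading 100 frames) and bleach rate *b*, a
transient of amplitude *A* at frame *t* is reported as approximately
`A·r − (1 − r)` with `r = (1 − b)^(t − 50)`; at `b = 5e-5` and a stimulus
at frame 300 that is a ~6% under-report for a 0.3 ΔF/F~0~ event, which the
suite verifies when bleaching is enabled. Recovery runs therefore probe an
unbiased chain, and drift sensitivity is a quantified, opt-in robustness
experiment.

### Condition presets

`preset()` registers the paired experimental conditions. Reported "±"
values are interpreted as SEM at the reported n and converted to
between-animal SDs (SD = SEM × √n). Reported condition values are treated
uniformly as peak ΔF/F~0~ above baseline 1 (sources mix "peak F/F~0~" and
"peak ΔF/F~0~" labels; amplitudes above 1 in F/F~0~ units are only
consistent with the Δ reading). The ryanodine-panel values reported in
arbitrary fluorescence units are encoded as ΔF/F~0~ equivalents; its
ryanodine/caffeine arms encode essentially-no-response conditions that sit
below the detection floor by design and are qualitative. Where a body-text
replicate count disagrees with a figure legend (the cypermethrin
conditions), the presets follow the body text and record the discrepancy in
their provenance notes. Uncaging arms default to 30-cell fields and
responder fraction 1 within the photolysis disc; agonist arms to 100-cell
fields and responder fraction 0.96 (the fraction of patch cells responding
to ACh, reused for intact-field agonist arms); spontaneous baseline
activity defaults to 10% of cells in intact arteries. The endothelial patch
preset is a single continuous recording with sequential baseline / ACh /
caffeine phases encoding 48% / 96% / 16% active cells; the patch ACh
amplitude is not reported and is set to a representative 1.0 ΔF/F~0~.

Paired arms share per-animal standard-normal deviates (each artery is its
own control), scaled by each arm's between-animal SD — so paired tests see
the same animal-level correlation structure as the real design.

## Parameter recovery and calibration

`recover_preset` repeats simulate → render → extract → process → aggregate
over master-seed batches and reports, per arm, the grand mean of per-animal
measured means with its Monte-Carlo SE and CI over batches, plus a
per-batch paired log t test. `recover_patch_fractions` scores the patch
preset with the any-activity rule per phase window. Non-responding cells
are excluded before aggregating peak amplitudes (their zeros encode "no
event", and log-scale statistics require positive means); the ground-truth
animal mean is defined the same way, as the mean over responding cells.

Calibration of the statistics is checked under a null preset (two identical
arms): over ≥500 seed batches the paired log t test rejects at α = 0.05 at
the nominal rate within binomial error, and the rapamycin preset — whose
two arms differ by 0.03 ΔF/F~0~ against a between-animal SD of ~0.5 — is
non-significant in the large majority of batches, mirroring the null result
it encodes.

## Problem sizes and numerical choices

Desk-scale validation runs use 4 µm/pixel fields (64 × 64 px for 30-cell
uncaging fields, 88 × 88 px for 100-cell agonist fields), which keep every
cell at the 20 px floor while preserving the field geometry in micrometres;
the acceptance script uses 12–16 seed batches per condition — more where
the comparison slack is tightest relative to the condition's between-animal
spread — and 18 patch batches (the caffeine-window fraction carries the
tightest absolute slack of all recovered quantities), so that each
recovered quantity's Monte-Carlo SE is several times smaller than its
comparison slack. The test
suite uses 4–5 batches per preset and compares against 3 × the run's own
Monte-Carlo SE. Seeds: every recording derives its seed from one master
seed via a fixed integer recurrence (`derive_seed`), recorded in the ground
truth; all generation is a pure function of (preset, seed).

Numerical conventions: frames and pixels are 1-based; windows are closed
intervals; "the first 150 frames" is frames 1–150; the uncaging stimulus
frame is 150 (15 s at 10 fps) and the response window runs from the
stimulus frame to the record end by default. Ties in peak detection
(plateaus) resolve to the first plateau frame. The ≥50% pixel-overlap rule
defines "directly photolysed" cells (configurable: any-overlap or
centroid-in alternatives).

## What passing recovery does and does not show

The generator emulates stimulus-locked transients, oscillation trains,
spontaneous activity, photon noise, slow bleaching and a dim background —
the features the measurement chain must be robust to. It does **not**
emulate tissue motion or contraction, cell segmentation error, indicator
photophysics (saturation, buffering), spatial Ca^2+^ waves within cells, or
cross-session cell re-registration; recovery on synthetic data therefore
validates the numerical chain, not those experimental failure modes. Real
recordings during strong arterial contraction are explicitly outside the
scope of quantitative analysis.
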
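#' Per-cell event summary over a response window
#'
#' Reduces one cell's trace and detected peaks to the summary metrics used
#' for condition comparisons: peak amplitude (maximum smoothed F/F0 in the
#' window minus 1, reported only when at least one retained peak lies in the
#' window), number of oscillation peaks, mean F/F0, response duration, and
#' the responder flag.
#'
#' Duration is the time from the first upward crossing of the detection
#' threshold level (1 + max(k_sigma * noise_sd, min_amplitude)) at or after
#' `stim_frame` to the last downward crossing inside the window (the window
#' end if still elevated); it is 0 when no peak lies in the window.
#'
#' @param ff0 An `ff0_trace` from [normalize_f_f0()].
#' @param smoothed Smoothed F/F0 vector for the same cell.
#' @param peaks Peak table from [detect_peaks()].
#' @param stim_frame First frame of the response window (1-based).
#' @param window_frames Window length in frames; defaults to the remainder
#'   of the record.
#' @param noise_sd,k_sigma,min_amplitude Threshold parameters (must match
#'   the ones used for detection).
#' @return A one-row data frame: `peak_amp`, `n_peaks`, `mean_ff0`,
#'   `duration_s`, `responder`.
#' @export
summarize_cell <- function(ff0, smoothed, peaks, stim_frame,
                           window_frames = NULL, noise_sd = 0,
                           k_sigma = 3, min_amplitude = 0.05) {
  stopifnot(inherits(ff0, "ff0_trace"))
  n <- length(ff0$values)
  if (stim_frame < 1 || stim_frame > n) stop("stim_frame outside the trace")
  last <- if (is.null(window_frames)) n else
    min(stim_frame + window_frames - 1L, n)
  if (last < stim_frame) stop("empty response window")
  win <- stim_frame:last
  in_win <- peaks$frame >= stim_frame & peaks$frame <= last
  n_peaks <- sum(in_win)
  peak_amp <- if (n_peaks > 0) max(smoothed[win]) - 1 else 0
  thr_level <- 1 + max(k_sigma * noise_sd, min_amplitude)
  duration_s <- 0
  if (n_peaks > 0) {
    above <- smoothed[win] >= thr_level
    if (any(above)) {
      duration_s <- (max(which(above)) - min(which(above))) /
        ff0$frame_rate_hz
    }
  }
  data.frame(
    peak_amp = peak_amp, n_peaks = n_peaks,
    mean_ff0 = mean(ff0$values[win]),
    duration_s = duration_s,
    responder = n_peaks >= 1
  )
}

#' Responder classification
#'
#' A cell counts as responding when any retained peak lies in the stimulus
#' window (any activity counts).
#'
#' @param summary One-row summary from [summarize_cell()].
#' @return Logical.
#' @export
classify_responder <- function(summary) {
  summary$n_peaks >= 1
}

#' Spontaneous baseline activity
#'
#' TRUE when at least one retained peak falls inside the baseline activity
#' window (the first 150 frames by default, i.e. before an uncaging stimulus
#' at 15 s and 10 fps).
#'
#' @param peaks Peak table from [detect_peaks()].
#' @param window `c(first, last)` frame window, 1-based inclusive.
#' @return Logical.
#' @export
spontaneous_activity <- function(peaks, window = c(1L, 150L)) {
  any(peaks$frame >= window[1] & peaks$frame <= window[2])
}

#' Percentage of active cells
#'
#' @param flags Logical vector, one element per cell.
#' @return Percentage in `[0, 100]`.
#' @export
percent_active <- function(flags) {
  if (length(flags) == 0) stop("no cells")
  100 * mean(flags)
}

#' Analysis configuration
#'
#' Bundles every tunable stage parameter with its default. Defaults follow
#' the acquisition and analysis conventions the package emulates: 100-frame
#' F0 baseline, 21-point third-order Savitzky-Golay smoothing, detection
#' threshold max(3 sigma, 0.05 dF/F0), spontaneous-activity window of the
#' first 150 frames, and a response window running to the end of the record.
#' Round-trips losslessly through YAML ([write_config()], [read_config()]).
#'
#' @param baseline_frames F0 window length, frames.
#' @param window,polyorder Savitzky-Golay parameters.
#' @param smoother `"savgol"` or `"movavg"` (patch pipeline, 20-point mean).
#' @param movavg_window Window for `smoother = "movavg"`.
#' @param k_sigma,min_amplitude Peak threshold parameters.
#' @param stim_frame First frame of the response window.
#' @param window_frames Response window length (NULL = rest of record).
#' @param spont_window Spontaneous-activity window `c(first, last)`.
#' @param alpha Significance level for downstream tests.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(baseline_frames = 100L, window = 21L,
                            polyorder = 3L, smoother = "savgol",
                            movavg_window = 20L, k_sigma = 3,
                            min_amplitude = 0.05, stim_frame = 150L,
                            window_frames = NULL, spont_window = c(1L, 150L),
                            alpha = 0.05) {
  structure(
    list(baseline_frames = as.integer(baseline_frames),
         window = as.integer(window), polyorder = as.integer(polyorder),
         smoother = smoother, movavg_window = as.integer(movavg_window),
         k_sigma = k_sigma, min_amplitude = min_amplitude,
         stim_frame = as.integer(stim_frame),
         window_frames = if (is.null(window_frames)) NULL else
           as.integer(window_frames),
         spont_window = as.integer(spont_window), alpha = alpha),
    class = "analysis_config"
  )
}

#' Analyze one recording into a per-cell summary table
#'
#' Runs the full trace-processing chain — F/F0 normalization, smoothing,
#' noise estimation, peak detection, and per-cell summarization — for every
#' cell of a recording.
#'
#' @param traces A `raw_traces` object from [extract_traces()] or a plain
#'   frames x cells matrix of (possibly already normalized) traces.
#' @param config An [analysis_config()].
#' @param frame_rate_hz Acquisition rate (taken from `traces` when it is a
#'   `raw_traces` object).
#' @param cell_ids Restrict analysis to these cells (e.g. the photolysed
#'   subset from [uncaging_mask()]).
#' @return Data frame, one row per analysed cell: `cell_id`, `peak_amp`,
#'   `n_peaks`, `mean_ff0`, `duration_s`, `responder`, `spont_active`,
#'   `noise_sd`.
#' @export
analyze_recording <- function(traces, config = analysis_config(),
                              frame_rate_hz = 10, cell_ids = NULL) {
  if (inherits(traces, "raw_traces")) {
    frame_rate_hz <- traces$frame_rate_hz
    mat <- traces$traces
  } else {
    mat <- as.matrix(traces)
  }
  if (is.null(cell_ids)) cell_ids <- seq_len(ncol(mat))
  mat <- mat[, cell_ids, drop = FALSE]
  b <- seq_len(config$baseline_frames)
  if (nrow(mat) <= config$baseline_frames) {
    stop("recording shorter than the baseline window")
  }
  f0 <- colMeans(mat[b, , drop = FALSE])
  if (any(!is.finite(f0)) || any(f0 <= 0)) {
    stop("non-positive baseline mean for cell(s) ",
         paste(cell_ids[!is.finite(f0) | f0 <= 0], collapse = ", "))
  }
  ff0_mat <- sweep(mat, 2, f0, "/")
  kern <- if (config$smoother == "movavg") {
    rep(1 / config$movavg_window, config$movavg_window)
  } else {
    savgol_coef(config$window, config$polyorder)
  }
  smooth_mat <- smooth_columns(ff0_mat, kern)
  rows <- lapply(seq_along(cell_ids), function(j) {
    ff0 <- structure(
      list(values = ff0_mat[, j], baseline_frames = config$baseline_frames,
           frame_rate_hz = frame_rate_hz),
      class = "ff0_trace"
    )
    smoothed <- smooth_mat[, j]
    ns <- mad(ff0$values[b] - smoothed[b])
    peaks <- detect_peaks(smoothed, frame_rate_hz, ns,
                          config$k_sigma, config$min_amplitude)
    out <- summarize_cell(ff0, smoothed, peaks, config$stim_frame,
                          config$window_frames, ns,
                          config$k_sigma, config$min_amplitude)
    out$cell_id <- cell_ids[j]
    out$spont_active <- spontaneous_activity(peaks, config$spont_window)
    out$noise_sd <- ns
    out
  })
  res <- do.call(rbind, rows)
  res[, c("cell_id", "peak_amp", "n_peaks", "mean_ff0", "duration_s",
          "responder", "spont_active", "noise_sd")]
}
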
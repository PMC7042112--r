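#' Baseline-normalize a raw trace to F/F0
#'
#' Divides a raw intensity trace by the mean of its first `baseline_frames`
#' frames (F0). By construction the mean of the normalized values over the
#' baseline window is exactly 1.
#'
#' @param raw Numeric vector of raw intensities.
#' @param baseline_frames Number of leading frames that define F0.
#' @param frame_rate_hz Acquisition rate, Hz.
#' @return An `ff0_trace`: list with `values`, `baseline_frames`,
#'   `frame_rate_hz`.
#' @export
normalize_f_f0 <- function(raw, baseline_frames = 100L, frame_rate_hz = 10) {
  raw <- as.numeric(raw)
  if (length(raw) <= baseline_frames) {
    stop("trace shorter than the baseline window")
  }
  f0 <- mean(raw[seq_len(baseline_frames)])
  if (!is.finite(f0) || f0 <= 0) {
    stop("non-positive baseline mean: trace unusable for F/F0")
  }
  structure(
    list(values = raw / f0, baseline_frames = as.integer(baseline_frames),
         frame_rate_hz = frame_rate_hz),
    class = "ff0_trace"
  )
}

#' Savitzky-Golay smoothing with mirror-padded edges
#'
#' Each point is replaced by the centre value of a least-squares polynomial
#' of degree `polyorder` fitted to the surrounding `window` points (the
#' default 21-point cubic filter). The filter reproduces polynomials up to
#' `polyorder` exactly at interior points. Edges are handled by mirror
#' padding.
#'
#' @param values Numeric vector (typically F/F0).
#' @param window Odd window length.
#' @param polyorder Polynomial degree, `< window`.
#' @return Smoothed vector, same length.
#' @export
savgol_smooth <- function(values, window = 21L, polyorder = 3L) {
  values <- as.numeric(values)
  smooth_columns(matrix(values), savgol_coef(window, polyorder))[, 1]
}

# Centre row of the Savitzky-Golay projection matrix (the smoothing
# convolution kernel).
savgol_coef <- function(window, polyorder) {
  if (window %% 2 == 0) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  signal::sgolay(p = polyorder, n = window)[(window + 1) %/% 2, ]
}

# Apply a symmetric FIR smoothing kernel to every column of a matrix with
# mirror padding at both ends.
smooth_columns <- function(mat, coef) {
  n <- nrow(mat)
  len <- length(coef)
  kl <- (len - 1L) %/% 2L
  kr <- len - 1L - kl
  if (n < len) stop("trace shorter than the smoothing window")
  padded <- rbind(mat[(kl + 1):2, , drop = FALSE], mat,
                  mat[(n - 1):(n - kr), , drop = FALSE])
  out <- stats::filter(padded, coef, sides = 2)
  matrix(as.numeric(out), ncol = ncol(mat))[(kl + 1):(kl + n), , drop = FALSE]
}

#' Moving-average smoothing (endothelial patch pipeline)
#'
#' Alternate smoother used for dissociated patch recordings: a simple
#' 20-point moving mean (mirror-padded; for an even window the extra point
#' falls on the trailing side).
#'
#' @param values Numeric vector.
#' @param window Window length in frames.
#' @return Smoothed vector, same length.
#' @export
moving_average <- function(values, window = 20L) {
  values <- as.numeric(values)
  smooth_columns(matrix(values), rep(1 / window, window))[, 1]
}

#' Robust baseline noise SD of an F/F0 trace
#'
#' Median-absolute-deviation estimate (scaled by 1.4826) of the residual
#' between the raw F/F0 trace and its smoothed version, over the baseline
#' window. Used to set the adaptive part of the peak detection threshold.
#'
#' @param ff0 An `ff0_trace` from [normalize_f_f0()].
#' @param smoothed Optional pre-computed smoothed trace.
#' @param window,polyorder Smoothing parameters if `smoothed` is missing.
#' @return Noise SD in dF/F0 units.
#' @export
estimate_noise_sd <- function(ff0, smoothed = NULL, window = 21L,
                              polyorder = 3L) {
  stopifnot(inherits(ff0, "ff0_trace"))
  if (is.null(smoothed)) smoothed <- savgol_smooth(ff0$values, window, polyorder)
  b <- seq_len(ff0$baseline_frames)
  resid <- ff0$values[b] - smoothed[b]
  mad(resid)
}

#' Detect Ca2+ event peaks on a smoothed F/F0 trace
#'
#' Candidate peaks are the positive-to-negative zero crossings of the
#' discrete derivative of the smoothed trace (for plateaus, the first
#' plateau frame). A candidate is retained when both its amplitude
#' (smoothed value minus 1) and its topographic prominence reach
#' `max(k_sigma * noise_sd, min_amplitude)`. The prominence criterion
#' rejects noise ripples riding on the elevated tail of a large transient,
#' which would otherwise pass a pure amplitude threshold.
#'
#' @param smoothed Smoothed F/F0 vector (output of [savgol_smooth()]).
#' @param frame_rate_hz Acquisition rate, Hz.
#' @param noise_sd Baseline noise SD from [estimate_noise_sd()].
#' @param k_sigma Noise multiplier of the adaptive threshold.
#' @param min_amplitude Absolute floor of the threshold, dF/F0.
#' @return A data frame of peaks in time order: `frame`, `time_s`,
#'   `amplitude`, `prominence`. Zero rows when nothing is detected.
#' @export
detect_peaks <- function(smoothed, frame_rate_hz = 10, noise_sd = 0,
                         k_sigma = 3, min_amplitude = 0.05) {
  s <- as.numeric(smoothed)
  thr <- max(k_sigma * noise_sd, min_amplitude)
  cand <- peak_candidates(s)
  if (length(cand) == 0) return(empty_peaks())
  prom <- peak_prominences(s, cand)
  amp <- s[cand] - 1
  keep <- amp >= thr & prom >= thr
  data.frame(
    frame = cand[keep],
    time_s = (cand[keep] - 1) / frame_rate_hz,
    amplitude = amp[keep],
    prominence = prom[keep]
  )
}

empty_peaks <- function() {
  data.frame(frame = integer(), time_s = numeric(),
             amplitude = numeric(), prominence = numeric())
}

# Positive-to-negative sign changes of diff(s); a plateau between a rise and
# a fall resolves to its first frame.
peak_candidates <- function(s) {
  d <- diff(s)
  sgn <- sign(d)
  nz <- which(sgn != 0)
  if (length(nz) < 2) return(integer())
  runs_sign <- sgn[nz]
  trans <- which(runs_sign[-length(runs_sign)] > 0 & runs_sign[-1] < 0)
  nz[trans] + 1L
}

# Topographic prominence of every candidate: height above the higher of the
# two bases, where each base is the lowest point between the peak and the
# nearest strictly higher point on that side (or the trace end). Computed on
# the candidate/valley skeleton: because every interior local maximum is a
# candidate, any region exceeding a candidate's height contains either a
# higher candidate or a trace endpoint, so walking the skeleton reproduces
# the pointwise definition.
peak_prominences <- function(s, cand) {
  n <- length(s)
  k <- length(cand)
  h <- s[cand]
  # walls: trace endpoints act as boundary heights
  nodes_pos <- c(1L, cand, n)
  nodes_h <- c(s[1], h, s[n])
  # valley minima between consecutive nodes
  valley <- vapply(seq_len(length(nodes_pos) - 1L), function(j) {
    min(s[nodes_pos[j]:nodes_pos[j + 1L]])
  }, 1)
  n_nodes <- length(nodes_pos)
  vapply(seq_len(k), function(j) {
    i <- j + 1L  # index in nodes
    # left: lowest point until the nearest strictly higher node or the start
    base_l <- Inf
    jj <- i - 1L
    repeat {
      base_l <- min(base_l, valley[jj])   # valley between nodes jj, jj+1
      if (nodes_h[jj] > nodes_h[i] || jj == 1L) break
      jj <- jj - 1L
    }
    # right: symmetric
    base_r <- Inf
    jj <- i + 1L
    repeat {
      base_r <- min(base_r, valley[jj - 1L])
      if (nodes_h[jj] > nodes_h[i] || jj == n_nodes) break
      jj <- jj + 1L
    }
    nodes_h[i] - max(base_l, base_r)
  }, 1)
}
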
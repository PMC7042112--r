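#' Fluorescence movie container
#'
#' @param frames Numeric or integer array `H x W x T` of non-negative
#'   intensities (photon counts for rendered movies).
#' @param frame_rate_hz Acquisition rate, Hz.
#' @param pixel_size_um Pixel size, um.
#' @param validate Check finiteness/non-negativity (skipped for frames the
#'   package rendered itself, which satisfy both by construction).
#' @return An object of class `ca_movie`.
#' @export
ca_movie <- function(frames, frame_rate_hz, pixel_size_um, validate = TRUE) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 1,
            frame_rate_hz > 0, pixel_size_um > 0)
  if (validate && (any(!is.finite(frames)) || any(frames < 0))) {
    stop("movie intensities must be finite and non-negative")
  }
  structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz,
         pixel_size_um = pixel_size_um),
    class = "ca_movie"
  )
}

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<ca_movie> %d x %d px, %d frames @ %g fps (%.2f um/px)\n",
              d[1], d[2], d[3], x$frame_rate_hz, x$pixel_size_um))
  invisible(x)
}

#' Render per-cell traces into a noisy fluorescence movie
#'
#' Forward imaging model: every pixel of cell `i` at frame `t` emits
#' `Poisson(baseline_counts * F_i(t) * (1 - bleach_rate_per_frame)^(t-1))`
#' photons, plus Gaussian read noise, clipped at zero and quantized to
#' integer counts. Background pixels fluoresce at a dim constant F/F0.
#' Deterministic for a fixed seed.
#'
#' @param traces Frames x cells matrix of noise-free F/F0 values.
#' @param map A [cell_map()] whose labels index the trace columns.
#' @param frame_rate_hz Acquisition rate, Hz.
#' @param baseline_counts Mean photon count per pixel at F/F0 = 1.
#' @param read_noise_sd Gaussian read noise SD, counts. The default 0
#'   models the EM-gain regime of an EMCCD, where effective read noise is
#'   negligible against shot noise; set it positive to emulate a
#'   conventional camera.
#' @param bleach_rate_per_frame Fractional photobleaching per frame (slow
#'   multiplicative drift). The default 0 keeps rendered recordings
#'   drift-free, so parameter recovery probes the measurement chain itself;
#'   set e.g. 5e-5 (5% over 1,000 frames) to study robustness to drift —
#'   an F/F0 pipeline with a leading baseline window then under-reports
#'   amplitudes by a predictable factor (see the methods vignette).
#' @param bg_ff0 Background F/F0 level (dim constant).
#' @param seed Integer seed.
#' @return A [ca_movie()] of integer photon counts.
#' @export
render_movie <- function(traces, map, frame_rate_hz = 10,
                         baseline_counts = 500, read_noise_sd = 0,
                         bleach_rate_per_frame = 0, bg_ff0 = 0.15,
                         seed = 1L) {
  stopifnot(inherits(map, "cell_map"), baseline_counts > 0,
            read_noise_sd >= 0, bleach_rate_per_frame >= 0,
            bleach_rate_per_frame < 1, bg_ff0 >= 0)
  traces <- as.matrix(traces)
  if (ncol(traces) != map$n_cells) {
    stop("traces must have one column per cell in the map")
  }
  h <- nrow(map$labels); w <- ncol(map$labels)
  n_frames <- nrow(traces)
  pix <- cell_pixel_index(map)
  npx <- lengths(pix)
  bg <- which(map$labels == 0L)
  decay <- (1 - bleach_rate_per_frame)^(seq_len(n_frames) - 1)

  with_seed(seed, {
    out <- matrix(0L, h * w, n_frames)
    for (t in seq_len(n_frames)) {
      out[bg, t] <- rpois(length(bg), baseline_counts * bg_ff0 * decay[t])
      for (i in seq_len(map$n_cells)) {
        out[pix[[i]], t] <-
          rpois(npx[i], baseline_counts * traces[t, i] * decay[t])
      }
    }
    if (read_noise_sd > 0) {
      out <- out + rnorm(length(out), 0, read_noise_sd)
      out <- round(pmax(out, 0))
      storage.mode(out) <- "integer"
    }
    dim(out) <- c(h, w, n_frames)
    ca_movie(out, frame_rate_hz, map$pixel_size_um, validate = FALSE)
  })
}
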
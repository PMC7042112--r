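#' Extract per-cell raw traces from a movie
#'
#' The raw trace of a cell is the arithmetic mean of the movie intensity over
#' the cell's pixels, frame by frame — the region-of-interest readout used
#' for en face endothelium. Extraction is linear in the movie.
#'
#' @param movie A [ca_movie()].
#' @param map A [cell_map()] of the same field size.
#' @return A `raw_traces` object: list with `traces` (frames x cells
#'   matrix), `cell_ids`, and `frame_rate_hz`.
#' @export
extract_traces <- function(movie, map) {
  stopifnot(inherits(movie, "ca_movie"), inherits(map, "cell_map"))
  d <- dim(movie$frames)
  if (d[1] != nrow(map$labels) || d[2] != ncol(map$labels)) {
    stop("movie and cell map field sizes differ")
  }
  if (map$n_cells == 0L) stop("cell map contains no labelled cells")
  lab <- map$labels
  sel <- which(lab > 0L)
  m <- matrix(movie$frames, d[1] * d[2], d[3])
  sums <- rowsum(m[sel, , drop = FALSE], lab[sel])
  npx <- tabulate(lab[sel], nbins = map$n_cells)
  traces <- unname(t(sums / npx))
  structure(
    list(traces = traces, cell_ids = seq_len(map$n_cells),
         frame_rate_hz = movie$frame_rate_hz),
    class = "raw_traces"
  )
}

#' Cells inside the photolysis (uncaging) disc
#'
#' Returns the ids of cells considered directly photolysed: those whose
#' pixel overlap fraction with the illumination disc is at least
#' `overlap_threshold`. Alternative inclusion rules: `"any"` (any overlap)
#' and `"centroid"` (cell centroid inside the disc).
#'
#' @param map A [cell_map()].
#' @param center Disc centre as `c(x, y)` in pixels (x = column, y = row,
#'   1-based).
#' @param diameter_um Disc diameter in micrometres (70 um for the flash
#'   photolysis light guide the default emulates).
#' @param overlap_threshold Minimum overlap fraction under
#'   `rule = "fraction"`.
#' @param rule Inclusion rule.
#' @return Integer vector of included cell ids (possibly empty).
#' @export
uncaging_mask <- function(map, center, diameter_um = 70,
                          overlap_threshold = 0.5,
                          rule = c("fraction", "any", "centroid")) {
  rule <- match.arg(rule)
  stopifnot(inherits(map, "cell_map"), diameter_um > 0,
            overlap_threshold > 0, overlap_threshold <= 1)
  h <- nrow(map$labels); w <- ncol(map$labels)
  r_px <- diameter_um / 2 / map$pixel_size_um
  cx <- center[1]; cy <- center[2]
  if (cx + r_px < 1 || cx - r_px > w || cy + r_px < 1 || cy - r_px > h) {
    stop("uncaging disc lies entirely outside the field")
  }
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  in_disc <- (xx - cx)^2 + (yy - cy)^2 <= r_px^2
  ids <- seq_len(map$n_cells)
  if (rule == "centroid") {
    keep <- vapply(ids, function(i) {
      p <- which(map$labels == i)
      mx <- mean(xx[p]); my <- mean(yy[p])
      (mx - cx)^2 + (my - cy)^2 <= r_px^2
    }, TRUE)
    return(ids[keep])
  }
  n_in <- tabulate(map$labels[in_disc & map$labels > 0L], nbins = map$n_cells)
  n_tot <- tabulate(map$labels[map$labels > 0L], nbins = map$n_cells)
  frac <- ifelse(n_tot > 0, n_in / n_tot, 0)
  thr <- if (rule == "any") .Machine$double.eps else overlap_threshold
  ids[frac >= thr & n_in > 0]
}
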
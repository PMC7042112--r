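#' Movie and cell-map TIFF I/O
#'
#' Movies are written as multi-page unsigned 16-bit TIFF stacks, cell maps
#' as single-page 16-bit integer label images. Frame rate and pixel size are
#' carried in a JSON sidecar ([write_sidecar()]), since plain TIFF does not
#' hold them reliably.
#'
#' @param movie A [ca_movie()]; values must fit in 16 bits.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "ca_movie"))
  if (max(movie$frames) > 65535) stop("intensities exceed 16-bit range")
  pages <- lapply(seq_len(dim(movie$frames)[3]),
                  function(t) movie$frames[, , t] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param frame_rate_hz,pixel_size_um Acquisition metadata (supply directly
#'   or from the sidecar).
#' @export
read_movie_tiff <- function(path, frame_rate_hz = 10, pixel_size_um = 0.4) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]]
  ca_movie(frames, frame_rate_hz, pixel_size_um)
}

#' @rdname write_movie_tiff
#' @param map A [cell_map()].
#' @export
write_cell_map_tiff <- function(map, path) {
  stopifnot(inherits(map, "cell_map"))
  if (map$n_cells > 65535) stop("too many labels for 16 bits")
  tiff::writeTIFF(map$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_cell_map_tiff <- function(path, pixel_size_um = 0.4) {
  labels <- tiff::readTIFF(path, as.is = TRUE)
  cell_map(labels, pixel_size_um)
}

#' JSON sidecar with acquisition and generation metadata
#'
#' @param path Sidecar file path.
#' @param meta Named list (frame rate, pixel size, preset, seed, ...).
#' @export
write_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_sidecar
#' @export
read_sidecar <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Ground-truth event table CSV
#'
#' One row per true event: `animal`, `tech_rep`, `cell_id`, `frame`,
#' `amplitude` (plus `kind` and onset time).
#'
#' @param truth `truth` element of [simulate_traces()] output.
#' @param path Output CSV.
#' @param animal,tech_rep Design coordinates of the recording.
#' @export
write_ground_truth_csv <- function(truth, path, animal = 1L, tech_rep = 1L) {
  ev <- truth$events
  out <- data.frame(animal = animal, tech_rep = tech_rep,
                    cell_id = ev$cell_id, frame = ev$frame,
                    amplitude = ev$amplitude, kind = ev$kind,
                    onset_s = ev$onset_s)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Trace tables as CSV
#'
#' Long format: `cell_id`, `frame`, `time_s`, `value`.
#'
#' @param traces A `raw_traces` object or frames x cells matrix.
#' @param path Output CSV.
#' @param frame_rate_hz Acquisition rate when `traces` is a bare matrix.
#' @export
write_traces_csv <- function(traces, path, frame_rate_hz = 10) {
  if (inherits(traces, "raw_traces")) {
    mat <- traces$traces
    frame_rate_hz <- traces$frame_rate_hz
    ids <- traces$cell_ids
  } else {
    mat <- as.matrix(traces)
    ids <- seq_len(ncol(mat))
  }
  n <- nrow(mat)
  out <- data.frame(
    cell_id = rep(ids, each = n),
    frame = rep(seq_len(n), length(ids)),
    time_s = rep((seq_len(n) - 1) / frame_rate_hz, length(ids)),
    value = as.vector(mat)
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path, frame_rate_hz = 10) {
  df <- read.csv(path)
  ids <- sort(unique(df$cell_id))
  n <- max(df$frame)
  mat <- matrix(NA_real_, n, length(ids))
  for (j in seq_along(ids)) {
    sub <- df[df$cell_id == ids[j], ]
    mat[sub$frame, j] <- sub$value
  }
  colnames(mat) <- ids
  structure(list(traces = mat, cell_ids = ids,
                 frame_rate_hz = frame_rate_hz),
            class = "raw_traces")
}

#' Write / read an analysis configuration as YAML
#'
#' @param config An [analysis_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}
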
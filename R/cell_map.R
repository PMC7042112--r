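#' Cell label maps
#'
#' A cell map assigns every pixel of the imaged field to a cell (labels
#' `1..n`) or to background (`0`). It stands in for the regions of interest
#' that are placed manually on each endothelial cell in real recordings.
#'
#' @param labels Integer matrix (rows = y, columns = x); 0 is background and
#'   cells are labelled consecutively `1..n`.
#' @param pixel_size_um Pixel size in micrometres.
#' @return An object of class `cell_map`.
#' @export
cell_map <- function(labels, pixel_size_um) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  stopifnot(pixel_size_um > 0, all(labels >= 0L))
  n <- max(labels)
  ids <- sort(unique(labels[labels > 0L]))
  if (n > 0L && !identical(ids, seq_len(n))) {
    stop("cell labels must be consecutive 1..n")
  }
  structure(
    list(labels = labels, pixel_size_um = pixel_size_um, n_cells = n),
    class = "cell_map"
  )
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf(
    "<cell_map> %d x %d px (%.2f um/px), %d cells\n",
    nrow(x$labels), ncol(x$labels), x$pixel_size_um, x$n_cells
  ))
  invisible(x)
}

#' Generate a synthetic endothelial cell field
#'
#' Places `n_cells` disjoint, roughly elliptical cells (defaults approximate
#' the ~10 x 40 um spindle shape of en face mesenteric endothelium, with
#' random orientation and mild size jitter) on an `height` x `width` pixel
#' field by rejection sampling. Each cell is a 4-connected region of at least
#' 20 pixels, and placement is deterministic for a fixed seed.
#'
#' @param height,width Field size in pixels.
#' @param n_cells Number of cells to place.
#' @param pixel_size_um Pixel size in micrometres (0.4 matches a 40x
#'   objective on a 512 x 512 EMCCD crop; coarser values give desk-scale
#'   fields).
#' @param seed Integer seed; the map is a pure function of it.
#' @param cell_len_um,cell_wid_um Mean major/minor axis length of a cell.
#' @param max_tries Placement attempts per cell before giving up.
#' @param center_bias When `TRUE`, cell centres are drawn from a truncated
#'   Gaussian around the field centre instead of uniformly — emulating
#'   photolysis fields, where the light guide is aimed at the imaged group
#'   of cells.
#' @return A [cell_map()].
#' @export
generate_cell_map <- function(height, width, n_cells, pixel_size_um = 0.4,
                              seed = 1L, cell_len_um = 40, cell_wid_um = 10,
                              max_tries = 4000L, center_bias = FALSE) {
  stopifnot(n_cells >= 1, height >= 4, width >= 4, pixel_size_um > 0)
  a0 <- cell_len_um / 2 / pixel_size_um   # semi-major axis, px
  b0 <- cell_wid_um / 2 / pixel_size_um   # semi-minor axis, px
  with_seed(seed, {
    labels <- matrix(0L, height, width)
    for (id in seq_len(n_cells)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        # crowded monolayers pack smaller cells: shrink gradually when
        # placement keeps failing, down to the 20 px minimum
        shrink <- max(0.97^(try %/% 50), 0.25)
        a <- a0 * shrink * runif(1, 0.8, 1.2)
        b <- max(b0 * shrink * runif(1, 0.8, 1.2), 1.3)
        th <- runif(1, 0, pi)
        if (center_bias) {
          cy <- clamp(rnorm(1, height / 2, height / 5), 1 + b, height - b)
          cx <- clamp(rnorm(1, width / 2, width / 5), 1 + b, width - b)
        } else {
          cy <- runif(1, 1 + b, height - b)
          cx <- runif(1, 1 + b, width - b)
        }
        px <- ellipse_pixels(cy, cx, a, b, th, height, width)
        if (length(px) < 20L) next
        if (any(labels[px] != 0L)) next
        labels[px] <- id
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf(
          "could not place cell %d of %d after %d tries: field too dense",
          id, n_cells, max_tries
        ))
      }
    }
    cell_map(labels, pixel_size_um)
  })
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Linear pixel indices of an ellipse centred at (cy, cx) with semi-axes a, b
# (a along direction `th`), clipped to the field. Rasterized on the bounding
# box; convex, so 4-connected for b >= ~1.3 px.
ellipse_pixels <- function(cy, cx, a, b, th, height, width) {
  r <- ceiling(max(a, b))
  ys <- max(1, floor(cy - r)):min(height, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(width, ceiling(cx + r))
  yy <- matrix(ys, length(ys), length(xs))
  xx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  u <- (xx - cx) * cos(th) + (yy - cy) * sin(th)
  v <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  (xx[inside] - 1L) * height + yy[inside]
}

# Pixel indices (linear, column-major) for each cell id.
cell_pixel_index <- function(map) {
  lab <- map$labels
  sel <- which(lab > 0L)
  split(sel, lab[sel])
}
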
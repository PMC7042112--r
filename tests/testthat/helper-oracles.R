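# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Mean trace per cell by an explicit per-pixel loop.
oracle_extract <- function(frames, labels) {
  ids <- sort(unique(labels[labels > 0]))
  n_frames <- dim(frames)[3]
  out <- matrix(NA_real_, n_frames, length(ids))
  for (j in seq_along(ids)) {
    sel <- which(labels == ids[j], arr.ind = TRUE)
    for (t in seq_len(n_frames)) {
      acc <- 0
      for (r in seq_len(nrow(sel))) {
        acc <- acc + frames[sel[r, 1], sel[r, 2], t]
      }
      out[t, j] <- acc / nrow(sel)
    }
  }
  out
}

# Pointwise topographic prominence of index i in s.
oracle_prominence <- function(s, i) {
  n <- length(s)
  hi_l <- if (i > 1) which(s[seq_len(i - 1)] > s[i]) else integer()
  l <- if (length(hi_l)) max(hi_l) else 0L
  left <- min(s[(l + 1):i])
  hi_r <- if (i < n) which(s[(i + 1):n] > s[i]) else integer()
  r <- if (length(hi_r)) i + min(hi_r) else n + 1L
  right <- min(s[i:(r - 1)])
  s[i] - max(left, right)
}

# Exhaustive scan for local maxima (plateaus resolve to their first frame)
# passing the same amplitude + prominence threshold as the detector.
oracle_peaks <- function(s, thr) {
  n <- length(s)
  cand <- integer()
  for (i in 2:(n - 1)) {
    if (s[i] > s[i - 1]) {
      j <- i
      while (j < n && s[j + 1] == s[j]) j <- j + 1
      if (j < n && s[j + 1] < s[j]) cand <- c(cand, i)
    }
  }
  keep <- vapply(cand, function(i) {
    (s[i] - 1) >= thr && oracle_prominence(s, i) >= thr
  }, TRUE)
  cand[keep]
}

# Centre value of an explicit least-squares polynomial fit to one window.
oracle_savgol_point <- function(x, i, window, polyorder) {
  k <- (window - 1) %/% 2
  idx <- (i - k):(i + k)
  fit <- lm(y ~ poly(t, polyorder, raw = TRUE),
            data = data.frame(t = idx - i, y = x[idx]))
  unname(predict(fit, newdata = data.frame(t = 0)))
}

# Balanced two-way ANOVA sums of squares from the mean decomposition.
oracle_anova2_ss <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  g <- mean(y)
  cell <- tapply(y, list(A, B), mean)
  ma <- tapply(y, A, mean); mb <- tapply(y, B, mean)
  r <- length(y) / (nlevels(A) * nlevels(B))
  ss_a <- r * nlevels(B) * sum((ma - g)^2)
  ss_b <- r * nlevels(A) * sum((mb - g)^2)
  ss_int <- r * sum((sweep(sweep(cell, 1, ma - g), 2, mb - g) - g)^2)
  ss_res <- sum((y - cell[cbind(A, B)])^2)
  c(A = ss_a, B = ss_b, interaction = ss_int, residual = ss_res)
}

empty_peaks_df <- function() {
  data.frame(frame = integer(), time_s = numeric(),
             amplitude = numeric(), prominence = numeric())
}

# Small deterministic helpers for fixtures.
tiny_map <- function(labels_mat, px = 1) {
  cell_map(labels_mat, px)
}

flat_movie <- function(value, h, w, n_frames, fps = 10, px = 1) {
  ca_movie(array(value, c(h, w, n_frames)), fps, px)
}
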
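test_that("F/F0 normalization is an exact ratio and scale-invariant", {
  expect_true(all(normalize_f_f0(rep(7, 200))$values == 1))

  raw <- c(rep(2, 100), 3, rep(2, 50))
  ff0 <- normalize_f_f0(raw)
  expect_equal(ff0$values[101], 1.5)

  set.seed(2)
  raw2 <- runif(300, 50, 150)
  ff0a <- normalize_f_f0(raw2)
  expect_equal(ff0a$values, raw2 / mean(raw2[1:100]), tolerance = 1e-12)
  ff0b <- normalize_f_f0(raw2 * 37.5)
  expect_equal(ff0a$values, ff0b$values, tolerance = 1e-12)
  expect_lt(abs(mean(ff0a$values[1:100]) - 1), 1e-9)
})

test_that("normalization rejects unusable traces", {
  expect_error(normalize_f_f0(rep(1, 50)), "shorter")
  expect_error(normalize_f_f0(c(rep(0, 100), rep(1, 50))), "baseline")
})

test_that("Savitzky-Golay reproduces cubic polynomials at interior points", {
  t <- seq_len(200)
  x <- 2 + 0.5 * t - 0.01 * t^2 + 1e-4 * t^3
  s <- savgol_smooth(x, 21, 3)
  interior <- 11:190
  expect_lt(max(abs(s[interior] - x[interior])), 1e-8)
  # DC preservation
  expect_equal(savgol_smooth(rep(3.7, 60), 21, 3), rep(3.7, 60),
               tolerance = 1e-12)
  expect_equal(moving_average(rep(2.5, 60), 20), rep(2.5, 60),
               tolerance = 1e-12)
})

test_that("each smoothed point equals an explicit windowed regression", {
  set.seed(8)
  x <- 1 + cumsum(rnorm(101, 0, 0.1))
  s <- savgol_smooth(x, 21, 3)
  for (i in c(25, 50, 75)) {
    expect_lt(abs(s[i] - oracle_savgol_point(x, i, 21, 3)), 1e-8)
  }
})

test_that("smoothing parameter validation", {
  expect_error(savgol_smooth(rnorm(100), window = 20), "odd")
  expect_error(savgol_smooth(rnorm(10), window = 21), "shorter")
  expect_error(savgol_smooth(rnorm(100), window = 21, polyorder = 21))
})

test_that("noise estimation: exact zero, known SD, and homogeneity", {
  arm <- condition_arm("q", mean_peak_amp = 1, between_animal_sd = 0.1,
                       stimulus = "agonist_flow", stim_frame = 150L,
                       n_frames = 400L)
  map <- generate_cell_map(48, 48, 5, 4, seed = 1)
  sim <- simulate_traces(arm, map, 10, seed = 2)
  ff0 <- normalize_f_f0(sim$traces[, 1])
  expect_lt(estimate_noise_sd(ff0), 1e-9)

  set.seed(5)
  ests <- replicate(20, {
    raw <- 100 * (1 + rnorm(400, 0, 0.02))
    estimate_noise_sd(normalize_f_f0(raw))
  })
  expect_lt(abs(mean(ests) - 0.02) / 0.02, 0.2)

  set.seed(6)
  noise <- rnorm(400, 0, 0.01)
  e1 <- estimate_noise_sd(normalize_f_f0(100 * (1 + noise)))
  e2 <- estimate_noise_sd(normalize_f_f0(100 * (1 + 2 * noise)))
  expect_equal(e2 / e1, 2, tolerance = 0.05)
})

test_that("monotone traces contain no peaks", {
  s <- savgol_smooth(seq(1, 3, length.out = 100))
  expect_identical(nrow(detect_peaks(s, 10, 0)), 0L)
})

test_that("a single noise-free transient yields one exact peak", {
  tt <- seq(0, 60, by = 0.1)
  x <- 1 + transient_kernel(tt, 20, 0.5)
  s <- savgol_smooth(x)
  pk <- detect_peaks(s, 10, 0)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$frame, which.max(s))
  expect_lt(abs(pk$amplitude - 0.5), 0.5 * 0.05)  # smoothing distortion < 5%
})

test_that("detector equals the exhaustive local-maximum oracle", {
  set.seed(33)
  for (k in 1:50) {
    s <- savgol_smooth(1 + cumsum(rnorm(250, 0, 0.05)))
    noise_sd <- runif(1, 0, 0.03)
    pk <- detect_peaks(s, 10, noise_sd)
    thr <- max(3 * noise_sd, 0.05)
    expect_identical(pk$frame, oracle_peaks(s, thr))
  }
})

test_that("plateau peaks resolve to the first plateau frame", {
  s <- c(1, 1.2, 1.5, 1.5, 1.5, 1.2, 1, 1, 1, 1, 1, 1)
  pk <- detect_peaks(s, 10, 0)
  expect_identical(pk$frame, 3L)
})

test_that("peak count is non-increasing in the thresholds", {
  set.seed(12)
  s <- savgol_smooth(1 + abs(cumsum(rnorm(400, 0, 0.04))))
  n_by_k <- vapply(c(0, 1, 3, 6, 10),
                   function(k) nrow(detect_peaks(s, 10, 0.02, k_sigma = k)), 1L)
  expect_true(all(diff(n_by_k) <= 0))
  n_by_amp <- vapply(c(0.01, 0.05, 0.2, 0.5),
                     function(a) nrow(detect_peaks(s, 10, 0, min_amplitude = a)), 1L)
  expect_true(all(diff(n_by_amp) <= 0))
})

test_that("detected peaks match ground truth on noise-free recordings", {
  arm <- preset("ip3_fk506")$arms$control
  map <- generate_cell_map(64, 64, 30, 4, seed = 3, center_bias = TRUE)
  sim <- simulate_traces(arm, map, 10, seed = 8)
  ev <- sim$truth$events
  for (i in sim$truth$eligible) {
    ff0 <- normalize_f_f0(sim$traces[, i])
    s <- savgol_smooth(ff0$values)
    pk <- detect_peaks(s, 10, estimate_noise_sd(ff0, smoothed = s))
    truth_i <- ev[ev$cell_id == i & ev$amplitude >= 0.1, ]
    # every sizeable true event has a detected peak within 2 frames
    for (f in truth_i$frame) {
      expect_true(any(abs(pk$frame - f) <= 2))
    }
  }
})

test_that("sensitivity >= 95% and FDR <= 5% at default render noise", {
  lab <- matrix(0L, 16, 16); lab[5:9, 4:12] <- 1L
  map <- tiny_map(lab, px = 4)
  tt <- seq(0, 39.9, by = 0.1)
  hits <- 0; false_pos <- 0; n_events <- 0; n_det <- 0
  for (s in 1:100) {
    x <- matrix(1 + transient_kernel(tt, 15, 0.3), ncol = 1)
    mv <- render_movie(x, map, 10, seed = s)
    tr <- extract_traces(mv, map)$traces[, 1]
    ff0 <- normalize_f_f0(tr)
    sm <- savgol_smooth(ff0$values)
    pk <- detect_peaks(sm, 10, estimate_noise_sd(ff0, smoothed = sm))
    n_events <- n_events + 1
    true_frame <- which.max(x[, 1])
    hit <- any(abs(pk$frame - true_frame) <= 3)
    hits <- hits + hit
    n_det <- n_det + nrow(pk)
    false_pos <- false_pos + (nrow(pk) - hit)
  }
  expect_gte(hits / n_events, 0.95)
  expect_lte(false_pos / max(n_det, 1), 0.05)
})
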
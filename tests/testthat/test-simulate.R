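# One small map reused across simulation tests.
sim_map <- generate_cell_map(64, 64, 20, 4, seed = 5)

test_that("a null arm produces identically flat traces", {
  arm <- condition_arm("null", mean_peak_amp = 1, between_animal_sd = 0,
                       responder_fraction = 0, spontaneous_fraction = 0,
                       stimulus = "agonist_flow", stim_frame = 50L,
                       n_frames = 300L)
  sim <- simulate_traces(arm, sim_map, 10, seed = 2)
  expect_true(all(sim$traces == 1))
  expect_identical(nrow(sim$truth$events), 0L)
})

test_that("noise-free baseline is exactly 1 before each cell's first event", {
  arm <- preset("ip3_fk506")$arms$control
  map <- generate_cell_map(64, 64, 30, 4, seed = 1, center_bias = TRUE)
  sim <- simulate_traces(arm, map, 10, seed = 9)
  ev <- sim$truth$events
  for (i in seq_len(map$n_cells)) {
    first <- suppressWarnings(min(ev$onset_s[ev$cell_id == i]))
    upto <- if (is.finite(first)) floor(first * 10) else 1000L
    expect_true(all(sim$traces[seq_len(upto), i] == 1))
  }
})

test_that("simulation is a pure function of its seed", {
  arm <- preset("ip3_fk506")$arms$control
  map <- generate_cell_map(64, 64, 30, 4, seed = 2, center_bias = TRUE)
  s1 <- simulate_traces(arm, map, 10, seed = 4)
  s2 <- simulate_traces(arm, map, 10, seed = 4)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$truth$events, s2$truth$events)
})

test_that("ground-truth animal mean is the average over responding cells", {
  arm <- preset("ach_fk506")$arms$control
  sim <- simulate_traces(arm, sim_map, 10, n_frames = 500L, seed = 31)
  ev <- sim$truth$events
  stim <- ev[ev$kind == "stim", ]
  expect_identical(sort(unique(stim$cell_id)),
                   which(sim$truth$responder))
  expect_equal(sim$truth$animal_true_mean, mean(stim$amplitude))
})

test_that("caffeine-style arm activates the encoded fraction of cells", {
  arm <- preset("patch_ach_caffeine")$arms$caffeine
  n_active <- 0; n_tot <- 0
  for (s in 1:30) {
    sim <- simulate_traces(arm, sim_map, 10, seed = 100 + s)
    ev <- sim$truth$events
    n_active <- n_active + length(unique(ev$cell_id))
    n_tot <- n_tot + sim_map$n_cells
  }
  p_hat <- n_active / n_tot
  se <- sqrt(0.16 * 0.84 / n_tot)
  expect_lt(abs(p_hat - 0.16), 4 * se)
})

test_that("hierarchical amplitudes recover the arm mean over many seeds", {
  arm <- condition_arm("lln", mean_peak_amp = 1.41,
                       between_animal_sd = 0.10 * sqrt(5),
                       stimulus = "agonist_flow", stim_frame = 100L,
                       n_frames = 200L, oscillation_rate_hz = 0)
  means <- vapply(1:200, function(s) {
    simulate_traces(arm, sim_map, 10, seed = s)$truth$animal_true_mean
  }, 1)
  mc_se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 1.41), 4 * mc_se)
  # empirical SEM of per-animal means at the encoded n matches the reported
  # SEM the preset encodes (SD = SEM * sqrt(n))
  expect_lt(abs(sd(means) / sqrt(5) - 0.10), 0.02)
})

test_that("paired arms share animal deviates", {
  pr <- preset("ip3_fk506")
  sim <- simulate_experiment(pr, seed = 6, height = 64, width = 64,
                             pixel_size_um = 4)
  ctrl <- vapply(sim$arms$control, function(r) r$truth$animal_mean_drawn, 1)
  trt <- vapply(sim$arms$treated, function(r) r$truth$animal_mean_drawn, 1)
  z_ctrl <- (unique(ctrl) - 1.41) / (0.10 * sqrt(5))
  z_trt <- (unique(trt) - 1.81) / (0.20 * sqrt(5))
  expect_equal(z_ctrl, z_trt, tolerance = 1e-10)
  # technical replicates of one animal share the animal mean
  an <- vapply(sim$arms$control, function(r) r$animal, 1)
  expect_identical(length(unique(ctrl)), length(unique(an)))
})

test_that("patch recordings plant activity in the right phase windows", {
  pr <- preset("patch_ach_caffeine")
  map <- generate_cell_map(128, 128, 40, 4, seed = 8)
  sim <- simulate_patch_recording(pr, map, seed = 3)
  expect_identical(nrow(sim$traces), 1800L)
  ev <- sim$truth$events
  for (ph in names(sim$windows)) {
    w <- sim$windows[[ph]]
    sub <- ev[ev$phase == ph, ]
    expect_true(all(sub$frame >= w[1] & sub$frame <= w[2]))
  }
})

test_that("invalid arm configurations are rejected", {
  expect_error(condition_arm("bad", mean_peak_amp = -1,
                             between_animal_sd = 0.1,
                             stimulus = "uncaging"))
  expect_error(condition_arm("bad", mean_peak_amp = 1,
                             between_animal_sd = 0.1,
                             responder_fraction = 1.2))
  expect_error(condition_arm("bad", mean_peak_amp = 1,
                             between_animal_sd = 0.1,
                             stim_frame = 2000L, n_frames = 1000L))
})

test_that("unknown presets list the registry", {
  expect_error(preset("nope"), "ip3_fk506")
  expect_true(all(c("ip3_fk506", "ip3_rapamycin", "patch_ach_caffeine")
                  %in% preset_names()))
})

test_that("registered presets encode the reported condition summaries", {
  pr <- preset("ip3_fk506")
  expect_equal(pr$arms$control$mean_peak_amp, 1.41)
  expect_equal(pr$arms$treated$mean_peak_amp, 1.81)
  expect_identical(pr$arms$control$n_animals, 5L)
  # between-animal SD reproduces the reported SEM at the reported n
  expect_equal(pr$arms$control$between_animal_sd / sqrt(5), 0.10)
  rp <- preset("ip3_rapamycin")
  expect_equal(rp$arms$control$mean_peak_amp, 1.45)
  expect_equal(rp$arms$treated$mean_peak_amp, 1.48)
  pa <- preset("patch_ach_caffeine")
  expect_equal(pa$arms$ach$responder_fraction, 0.96)
  expect_equal(pa$arms$caffeine$spontaneous_fraction, 0.16)
  expect_equal(pa$arms$baseline$spontaneous_fraction, 0.48)
  expect_identical(preset("ip3_cypermethrin")$arms$control$n_animals, 7L)
})
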
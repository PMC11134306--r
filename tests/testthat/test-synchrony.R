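# Sliding correlation, regime segmentation, synchrony-distance profiles.

test_that("sliding correlation hits the analytic cases", {
  fhz <- 15
  set.seed(2)
  x <- rnorm(1000)
  r_same <- sliding_correlation(x, x, fhz, window_s = 4)
  expect_true(all(r_same[!is.na(r_same)] > 1 - 1e-9))
  r_anti <- sliding_correlation(x, -x, fhz, window_s = 4)
  expect_true(all(r_anti[!is.na(r_anti)] < -1 + 1e-9))
  expect_true(all(abs(r_same[!is.na(r_same)]) <= 1))
  # window = full length reduces to the global Pearson r
  y <- rnorm(1000)
  r_full <- sliding_correlation(x, y, 1, window_s = 1000)
  expect_equal(r_full[!is.na(r_full)], cor(x, y), tolerance = 1e-12)
  # edges undefined
  expect_true(is.na(r_same[1]) && is.na(r_same[1000]))
})

test_that("sliding-correlation null SD matches the Fisher approximation", {
  set.seed(4)
  win <- 450
  tn <- 270000
  x <- rnorm(tn); y <- rnorm(tn)
  r <- sliding_correlation(x, y, 15, window_s = 30)
  # thin to ~independent windows
  idx <- seq(250, tn - 250, by = win)
  obs_sd <- sd(r[idx], na.rm = TRUE)
  expect_lt(abs(obs_sd - 1 / sqrt(win - 2)) / (1 / sqrt(win - 2)), 0.2)
})

test_that("regime segmentation partitions defined frames", {
  fhz <- 10
  # square wave alternating 0.2 / 0.8, 30 s per level
  lv <- rep(c(0.2, 0.8), each = 30 * fhz, times = 4)
  seg <- segment_regimes(matrix(lv, 1), fhz)
  expect_true(all(seg$low_period_s == 30))
  expect_true(!any(seg$high & seg$low))
  defined <- !is.na(seg$average)
  expect_true(all(xor(seg$high[defined], seg$low[defined])))
  # constant trace: no frame strictly below the mean
  seg2 <- segment_regimes(matrix(0.5, 1, 100), fhz)
  expect_equal(sum(seg2$low), 0)
})

test_that("planted release bursts coincide with low-synchrony intervals", {
  cfg <- scenario_config("synchrony_events", seed = 5)
  sim <- simulate_ne_field(cfg)
  geom <- neflow:::build_fields_from_centers(sim$truth$cell_centers,
                                             sim$movie$h, sim$movie$w,
                                             cfg$local_radius_um,
                                             cfg$soma_radius_um, cfg$px_um)
  n <- cfg$n_cells
  syn <- matrix(NA_real_, n, nrow(sim$movie$data))
  for (i in seq_len(n)) {
    loc <- rowMeans(sim$movie$data[, geom$local_px[[i]], drop = FALSE])
    glo <- rowMeans(sim$movie$data[, geom$global_px[[i]], drop = FALSE])
    syn[i, ] <- sliding_correlation(loc, glo, cfg$frame_hz)
  }
  seg <- segment_regimes(syn, cfg$frame_hz)
  onsets <- sim$truth$events$onset_frame[sim$truth$events$kind == "release"]
  pad <- round(15 * cfg$frame_hz)
  near_low <- vapply(onsets, function(f) {
    win <- max(1, f - pad):min(length(seg$low), f + pad)
    any(seg$low[win])
  }, logical(1))
  expect_gte(mean(near_low), 0.7)
})

test_that("synchrony-distance profile counts pairs and flags shared traces", {
  set.seed(9)
  tr <- matrix(rnorm(300), 1)[rep(1, 3), ]
  centers <- data.frame(x_px = c(10, 30, 50), y_px = c(10, 40, 20))
  prof <- synchrony_distance_profile(tr, centers, px_um = 1.47)
  expect_equal(nrow(prof), 3)
  expect_true(all(prof$r > 1 - 1e-9))
})
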
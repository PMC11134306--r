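# Preprocessing: filtering/binning, registration, field geometry,
# bleed-through correction, standardization, trace extraction.

make_movie <- function(g, r, h, w, frame_hz = 30, px_um = 1.47) {
  structure(list(green = g, red = r, h = h, w = w, frame_hz = frame_hz,
                 px_um = px_um), class = "two_channel_movie")
}

test_that("median filter rejects impulses and binning halves the rate", {
  h <- 4; w <- 4; tn <- 8
  g <- matrix(2, tn, h * w)
  m <- make_movie(g, g, h, w)
  out <- median_filter_and_bin(m)
  expect_equal(out$frame_hz, 15)
  expect_equal(nrow(out$green), 4)
  expect_true(all(out$green == 2))

  # single-frame spike at one pixel is removed
  g2 <- matrix(0, tn, h * w); g2[4, 7] <- 10
  out2 <- median_filter_and_bin(make_movie(g2, g2, h, w))
  expect_true(all(out2$green == 0))

  # interior ramp: median preserves it, pairs average to 1.5, 3.5, 5.5, 7.5
  g3 <- matrix(0, tn, h * w); g3[, 5] <- 1:8
  out3 <- median_filter_and_bin(make_movie(g3, g3, h, w))
  expect_equal(out3$green[, 5], c(1.5, 3.5, 5.5, 7.5))
})

test_that("registration recovers planted drift and is lossless for no shift", {
  sim <- small_sim()
  cfg2 <- sim$cfg
  cfg2$drift_px_per_min <- 3
  cfg2$noise_sd <- 0.01
  two <- render_two_channel(sim$movie, sim$ca, sim$truth, cfg2)
  # short early reference: with ongoing drift the long-average reference is
  # smeared and only relative shifts would be identifiable
  reg <- register_translation(two, reference_s = 5)
  err <- sqrt(mean((reg$shifts - two$shifts)^2))
  expect_lt(err, 0.5)

  # unshifted movie: all shifts ~0
  reg0 <- register_translation(sim$two)
  expect_lt(max(abs(reg0$shifts)), 0.5)

  # residual displacement after correction < 0.5 px
  reg2 <- register_translation(reg$movie, reference_s = 5)
  expect_lt(sqrt(mean(reg2$shifts^2)), 0.5)
})

test_that("registration followed by inverse shift is lossless for integer shifts", {
  h <- 32; w <- 32
  set.seed(7)
  base <- neflow:::blur_frames(matrix(rnorm(h * w), 1), h, w, 3)
  fr <- matrix(base, h, w)
  shifted <- neflow:::shift_frame(fr, 2, -3)
  back <- neflow:::shift_frame(shifted, -2, 3)
  interior <- back[6:(h - 6), 6:(w - 6)] - fr[6:(h - 6), 6:(w - 6)]
  expect_lt(max(abs(interior)), 1e-6)
})

test_that("field geometry partitions the FOV and annuli are disjoint", {
  h <- 64; w <- 64; px_um <- 1.47
  labels <- matrix(0L, h, w)
  labels[neflow:::disk_mask(h, w, 32, 20, 3.4)] <- 1L
  labels[neflow:::disk_mask(h, w, 32, 44, 3.4)] <- 2L
  geom <- build_fields(labels, radius_um = 15, px_um = px_um)
  # annulus pixel count close to analytic disk-minus-soma area
  r_px <- 15 / px_um
  expected <- pi * r_px^2 - sum(labels == 1L)
  expect_lt(abs(length(geom$local_px[[1]]) - expected) / expected, 0.15)
  # disjointness
  expect_length(intersect(geom$local_px[[1]], geom$local_px[[2]]), 0)
  expect_length(intersect(geom$local_px[[1]], geom$soma_px[[2]]), 0)
  # exact partition arithmetic per cell
  for (k in 1:2) {
    expect_equal(length(geom$global_px[[k]]),
                 h * w - length(geom$soma_px[[k]]) - length(geom$local_px[[k]]))
  }
  # two cells 5 um apart: annuli share no pixel
  labels2 <- matrix(0L, h, w)
  labels2[neflow:::disk_mask(h, w, 32, 30, 1.5)] <- 1L
  labels2[neflow:::disk_mask(h, w, 32, 30 + 5 / px_um, 1.5)] <- 2L
  geom2 <- build_fields(labels2, radius_um = 15, px_um = px_um)
  expect_length(intersect(geom2$local_px[[1]], geom2$local_px[[2]]), 0)
})

test_that("bleed-through correction residualizes exactly", {
  set.seed(11)
  tn <- 500; p <- 25
  red <- matrix(rnorm(tn * p), tn, p)
  indep <- matrix(rnorm(tn * p), tn, p)
  green <- 0.2 * red + indep
  m <- make_movie(green, red, 5, 5)
  out <- bleedthrough_correct(m)
  # corrected green orthogonal to ORIGINAL red at every pixel
  for (j in seq_len(p)) {
    expect_lt(abs(cor(out$green[, j], red[, j])), 1e-10)
  }
  # correction never increases |correlation| with the other channel
  r_before <- abs(sapply(seq_len(p), function(j) cor(green[, j], red[, j])))
  r_after <- abs(sapply(seq_len(p), function(j) cor(out$green[, j], red[, j])))
  expect_true(all(r_after <= r_before + 1e-12))
  # independent channels: correction is ~ centering
  m2 <- make_movie(indep, red, 5, 5)
  out2 <- bleedthrough_correct(m2)
  for (j in seq_len(p)) {
    expect_gt(cor(out2$green[, j], indep[, j]), 0.99)
  }
})

test_that("standardize meets its contract and matches the analytic filter gain", {
  fhz <- 15
  set.seed(5)
  x <- cumsum(rnorm(1200))
  s <- standardize(x, fhz)
  expect_lt(abs(mean(s)), 1e-9)
  expect_lt(abs(sd(s) - 1), 1e-6)
  # idempotence up to tolerance
  s2 <- standardize(s, fhz)
  expect_gt(cor(s, s2), 0.99)
  # pure ramp -> zero variance after detrend -> error
  expect_error(standardize(seq_len(600) * 0.5, fhz), "zero variance")
  # sinusoid attenuation matches the Gaussian transfer function exp(-(2 pi f sigma)^2/2)
  tt <- seq(0, 120, by = 1 / fhz)
  f <- 0.5
  x <- sin(2 * pi * f * tt)
  sm <- neflow:::smooth_time(x, fhz)
  # project interior samples onto the quadrature pair to isolate the 0.5 Hz
  # component (sd-based estimates are swamped by leakage at -43 dB gain)
  keep <- 200:1500
  basis <- cbind(sin(2 * pi * f * tt[keep]), cos(2 * pi * f * tt[keep]))
  amp <- sqrt(sum(qr.coef(qr(basis), sm[keep])^2))
  gain_theory <- exp(-(2 * pi * f * 1)^2 / 2)
  expect_lt(abs(amp - gain_theory) / gain_theory, 0.02)
})

test_that("extract_traces averages masks and standardizes every trace", {
  sim <- small_sim()
  geom <- build_fields(sim$two$soma_labels, 15, sim$cfg$px_um)
  ts <- extract_traces(sim$two, geom)
  n <- nrow(ts$cell_ca)
  for (m in list(ts$cell_ca, ts$local_ne, ts$global_ne, ts$pop_ca)) {
    expect_true(all(abs(rowMeans(m)) < 1e-9))
    expect_true(all(abs(apply(m, 1, sd) - 1) < 1e-6))
  }
  # uniform frame value -> every raw trace equals it
  g <- matrix(3.3, 50, 64 * 64)
  mu <- make_movie(g, g, 64, 64, frame_hz = 15)
  # bypass standardization check by inspecting raw means
  raw <- rowMeans(g[, geom$soma_px[[1]], drop = FALSE])
  expect_true(all(raw == 3.3))
})
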
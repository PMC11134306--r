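# Optic flow: preprocessing invariants, Horn-Schunck against the
# phase-correlation oracle, critical-point classification.

test_that("flow preprocessing z-scores every live pixel", {
  set.seed(2)
  h <- 24; w <- 24; tn <- 200
  m <- neflow:::new_ne_movie(matrix(rnorm(tn * h * w), tn), h, w, 15, 1.47)
  out <- preprocess_for_flow(m, sigma_px = 2, kernel_s = 0.2,
                             var_floor_frac = 0)
  sds <- apply(out$data, 2, sd)
  expect_true(all(abs(sds - 1) < 1e-6))
  # moderated normalization shrinks, never inflates
  outm <- preprocess_for_flow(m, sigma_px = 2, kernel_s = 0.2)
  expect_true(all(apply(outm$data, 2, sd) <= 1 + 1e-9))
  # constant movie: zero-variance pixels flagged as NA, no error
  mc <- neflow:::new_ne_movie(matrix(1, tn, h * w), h, w, 15, 1.47)
  outc <- preprocess_for_flow(mc, sigma_px = 2, kernel_s = 0.2)
  expect_true(all(is.na(outc$data)))
})

test_that("spatial blur of an impulse matches the analytic Gaussian", {
  h <- 65; w <- 65
  X <- matrix(0, 1, h * w)
  X[1, neflow:::pixel_index(33, 33, h)] <- 1
  bl <- neflow:::blur_frames(X, h, w, 4)
  img <- matrix(bl[1, ], h, w)
  ii <- 20:46
  expected <- outer(dnorm(ii - 33, sd = 4), dnorm(ii - 33, sd = 4))
  expect_equal(img[ii, ii], expected, tolerance = 1e-3)
  expect_equal(img[33, 33], 1 / (2 * pi * 16), tolerance = 1e-3)
})

test_that("identical frames give a zero flow field", {
  set.seed(4)
  f <- matrix(rnorm(32 * 32), 32)
  fl <- horn_schunck(f, f, alpha = 1, n_iter = 100, tol = 1e-6)
  expect_lt(max(abs(fl$u)), 1e-8)
  expect_lt(max(abs(fl$v)), 1e-8)
  expect_error(horn_schunck(f * NA, f, 1, 10, 1e-4), "non-finite")
})

test_that("Horn-Schunck matches the phase-correlation oracle on a shifted blob", {
  h <- 96; w <- 96
  g1 <- 3 * neflow:::gaussian_image(h, w, 48, 44, 7)
  g2 <- 3 * neflow:::gaussian_image(h, w, 48, 45, 7)
  oracle <- phase_correlation_shift(g1, g2)
  expect_equal(unname(oracle), c(0, 1))
  fl <- horn_schunck(g1, g2, alpha = 1, n_iter = 2000, tol = 1e-6)
  sup <- g1 > 0.2 * max(g1)
  expect_lt(abs(mean(fl$u[sup]) - oracle["dx"]) / abs(oracle["dx"]), 0.2)
  expect_lt(abs(mean(fl$v[sup]) - 0), 0.05)
})

test_that("flow magnitude decreases monotonically toward the smooth limit", {
  h <- 64; w <- 64
  g1 <- 3 * neflow:::gaussian_image(h, w, 32, 30, 6)
  g2 <- 3 * neflow:::gaussian_image(h, w, 32, 31, 6)
  mags <- sapply(c(0.5, 2, 8), function(a) {
    fl <- horn_schunck(g1, g2, alpha = a, n_iter = 300, tol = 1e-6)
    mean(sqrt(fl$u^2 + fl$v^2))
  })
  expect_true(all(diff(mags) < 0))
})

test_that("critical-point classifier labels all five analytic fields", {
  h <- 48; w <- 48; cx <- 30.3; cy <- 17.7
  cases <- list(
    source = matrix(c(1, 0, 0, 1), 2),
    sink = matrix(c(-1, 0, 0, -1), 2),
    saddle = matrix(c(1, 0, 0, -1), 2),
    `spiral-in` = matrix(c(-0.1, 1, -1, -0.1), 2),
    `spiral-out` = matrix(c(0.1, 1, -1, 0.1), 2))
  for (nm in names(cases)) {
    f <- linear_field(h, w, cx, cy, cases[[nm]])
    cp <- find_critical_points(f$u, f$v)
    expect_equal(nrow(cp), 1)
    expect_equal(cp$type, nm)
    expect_lt(abs(cp$x - cx), 1)
    expect_lt(abs(cp$y - cy), 1)
  }
  # uniform flow: no critical point
  cp0 <- find_critical_points(matrix(1, h, w), matrix(0.5, h, w))
  expect_equal(nrow(cp0), 0)
})
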
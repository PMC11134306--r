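# Spatial autocorrelation, double-exponential fits, field correlations.

test_that("grid autocorrelation: global signal gives r = 1, noise gives r ~ 0", {
  h <- 40; w <- 40; tn <- 400
  set.seed(6)
  shared <- rnorm(tn)
  m_shared <- neflow:::new_ne_movie(matrix(shared, tn, h * w), h, w, 15, 1.47)
  prof <- grid_autocorrelation(m_shared, patch_um = 10,
                               standardize_patches = FALSE)
  expect_true(all(prof$profile$r > 1 - 1e-9))
  expect_equal(prof$profile$r[prof$profile$distance_um == 0], 1)

  # independent noise per patch: |mean r| < 2/sqrt(T) at nonzero distances
  patch_px <- round(10 / 1.47)
  ny <- h %/% patch_px; nx <- w %/% patch_px
  patches <- matrix(rnorm(tn * ny * nx), tn)
  px_y <- pmin(ny, ((seq_len(h) - 1L) %/% patch_px) + 1L)
  px_x <- pmin(nx, ((seq_len(w) - 1L) %/% patch_px) + 1L)
  idx <- outer(px_y, (px_x - 1L) * ny, "+")
  m_noise <- neflow:::new_ne_movie(patches[, as.vector(idx)], h, w, 15, 1.47)
  prof2 <- grid_autocorrelation(m_noise, patch_um = 10,
                                standardize_patches = FALSE)
  nonzero <- prof2$profile$distance_um > 0
  expect_lt(abs(mean(prof2$profile$r[nonzero])), 2 / sqrt(tn))
})

test_that("binned r decreases with distance for diffusive event movies", {
  cfg <- sim_config(fov_px = c(96, 96), duration_s = 120, n_cells = 4,
                    n_varicosities = 20, release_rate_hz = 0.02,
                    global_drive_amp = 0, noise_sd = 0, seed = 8)
  sim <- simulate_ne_field(cfg)
  prof <- grid_autocorrelation(sim$movie)
  df <- prof$profile[prof$profile$distance_um > 0 & prof$profile$n_pairs >= 20, ]
  expect_lt(cor(df$distance_um, df$r, method = "spearman"), 0)
})

test_that("double-exponential fit recovers noiseless parameters", {
  d <- seq(0, 150, by = 5)
  r <- 0.5 * exp(-d / 10) + 0.3 * exp(-d / 80)
  fit <- fit_double_exponential(data.frame(distance_um = d, r = r))
  expect_equal(fit$a1, 0.5, tolerance = 1e-4)
  expect_equal(fit$lambda1, 10, tolerance = 1e-3)
  expect_equal(fit$a2, 0.3, tolerance = 1e-4)
  expect_equal(fit$lambda2, 80, tolerance = 1e-3)
  expect_lte(fit$lambda1, fit$lambda2)

  # single-exponential data: nested model, residual near zero
  r1 <- 0.6 * exp(-d / 30)
  fit1 <- fit_double_exponential(data.frame(distance_um = d, r = r1))
  expect_lt(fit1$rss, 1e-6)

  # all-equal r flagged degenerate
  fit2 <- fit_double_exponential(data.frame(distance_um = d, r = rep(0.4, length(d))))
  expect_true(fit2$degenerate)
  expect_equal(fit2$a1 + fit2$a2, 0.4, tolerance = 1e-6)
})

test_that("plume length scale is recovered from generator movies", {
  cfg <- sim_config(fov_px = c(128, 128), duration_s = 150, n_cells = 4,
                    n_varicosities = 30, release_rate_hz = 0.02,
                    diffusion_sigma_um = 12, global_drive_amp = 0,
                    noise_sd = 0, colocation_p = 0, seed = 12)
  sim <- simulate_ne_field(cfg)
  prof <- grid_autocorrelation(sim$movie, standardize_patches = FALSE)
  fit <- fit_double_exponential(prof)
  sig_hat <- estimate_plume_scale(fit)
  expect_lt(abs(sig_hat - 12) / 12, 0.25)
})

test_that("field correlation distributions have the expected structure", {
  sim <- small_sim()
  geom <- build_fields(sim$two$soma_labels, 15, sim$cfg$px_um)
  ts <- extract_traces(bleedthrough_correct(sim$two), geom)
  fc <- field_correlation_distributions(ts)
  n <- nrow(ts$cell_ca)
  expect_length(fc$local_local, n * (n - 1) / 2)
  expect_length(fc$local_global, n)
  # strong shared drive: local:global exceeds local:local on average
  expect_gt(fc$mean_local_global, fc$mean_local_local)
  expect_true(all(abs(c(fc$local_local, fc$local_global)) <= 1))
})
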
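# Generator contracts: determinism, plume closed form, mass conservation,
# condition semantics, cell coupling, rendering.

test_that("config validation enforces the invariants", {
  expect_error(sim_config(bleedthrough_frac = 0.6), "bleedthrough")
  expect_error(sim_config(reuptake_tau_s = -1), "positive")
  expect_error(sim_config(condition = "unknown"))
  expect_error(sim_config(colocation_p = 1.4), "colocation_p")
})

test_that("identical (config, seed) pairs are bit-identical", {
  cfg <- sim_config(fov_px = c(48, 48), duration_s = 20, n_cells = 2,
                    n_varicosities = 4, release_rate_hz = 0.05, seed = 21)
  a <- simulate_ne_field(cfg); b <- simulate_ne_field(cfg)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth$events, b$truth$events)
  ca_a <- simulate_cells(a$movie, a$truth, cfg)
  ca_b <- simulate_cells(b$movie, b$truth, cfg)
  expect_identical(unclass(ca_a), unclass(ca_b))
})

test_that("no-source config yields a constant-baseline movie and empty events", {
  cfg <- sim_config(fov_px = c(48, 48), duration_s = 20, n_cells = 2,
                    release_rate_hz = 0, reuptake_rate_hz = 0,
                    global_drive_amp = 0, noise_sd = 0,
                    expression_texture = 0, seed = 1)
  sim <- simulate_ne_field(cfg)
  expect_equal(nrow(sim$truth$events), 0)
  expect_true(all(sim$movie$data == cfg$baseline))
})

test_that("a planted release matches the closed-form plume", {
  cfg <- sim_config(fov_px = c(96, 96), duration_s = 30, n_cells = 2,
                    diffusion_sigma_um = 12, release_amp = 1,
                    global_drive_amp = 0, noise_sd = 0,
                    expression_texture = 0,
                    planted_events = data.frame(kind = "release",
                                                onset_s = 100 / 15,
                                                x_px = 48, y_px = 48),
                    seed = 2)
  sim <- simulate_ne_field(cfg)
  ev <- sim$truth$events
  expect_equal(nrow(ev), 1)
  f <- ev$onset_frame + 1L
  t_rel <- (f - ev$onset_frame) / cfg$frame_hz
  tc <- neflow:::plume_timecourse(t_rel, 12 / 1.47, 1, cfg$spread_s,
                                  cfg$diffusion_um2_s / 1.47^2,
                                  cfg$reuptake_tau_s)
  frame <- matrix(sim$movie$data[f, ] - cfg$baseline, 96, 96)
  expected <- tc$amp * neflow:::gaussian_image(96, 96, 48, 48, tc$sigma)
  expect_lt(max(abs(frame - expected)), 1e-6)
  expect_equal(max(frame), cfg$release_amp, tolerance = 0.02)
  # events lie inside the FOV, onset < offset
  expect_true(all(ev$onset_frame < ev$offset_frame))
  expect_true(all(ev$x_px >= 1 & ev$x_px <= 96 & ev$y_px >= 1 & ev$y_px <= 96))
})

test_that("plume mass is conserved during the spread phase", {
  cfg <- sim_config(fov_px = c(128, 128), duration_s = 30, n_cells = 2,
                    diffusion_sigma_um = 8, global_drive_amp = 0,
                    noise_sd = 0, expression_texture = 0,
                    planted_events = data.frame(kind = "release", onset_s = 5,
                                                x_px = 64, y_px = 64),
                    seed = 2)
  sim <- simulate_ne_field(cfg)
  f0 <- sim$truth$events$onset_frame
  spread_f <- floor(cfg$spread_s * cfg$frame_hz)
  masses <- rowSums(sim$movie$data[f0:(f0 + spread_f), ]) -
    cfg$baseline * ncol(sim$movie$data)
  expect_lt(max(abs(masses / masses[1] - 1)), 0.01)
})

test_that("desipramine accumulates NE relative to saline on the same seed", {
  mk <- function(cond) {
    cfg <- sim_config(fov_px = c(48, 48), duration_s = 90, n_cells = 2,
                      n_varicosities = 8, release_rate_hz = 0.02,
                      condition = cond, noise_sd = 0, seed = 31)
    simulate_ne_field(cfg)
  }
  sal <- mk("saline"); desi <- mk("desipramine")
  tn <- nrow(sal$movie$data)
  tail_f <- ceiling(0.9 * tn):tn
  expect_gt(mean(desi$movie$data[tail_f, ]), mean(sal$movie$data[tail_f, ]))
})

test_that("cell coupling contracts hold in the decoupled and identity limits", {
  sim <- small_sim()
  cfg0 <- sim$cfg
  cfg0$beta_local <- 0; cfg0$beta_globalCa <- 0
  cfg0$duration_s <- 600
  big <- simulate_ne_field(cfg0)
  ca0 <- simulate_cells(big$movie, big$truth, cfg0)
  ann <- big$truth$phasic
  r <- abs(cor(ca0[1, ], ann[1, ]))
  expect_lt(r, 0.05)

  # identity coupling: beta_local = 1, no noise, no kernel
  cfg1 <- sim$cfg
  cfg1$beta_local <- 1; cfg1$beta_globalCa <- 0; cfg1$cell_noise_sd <- 0
  cfg1$ca_tau_s <- 0
  ca1 <- simulate_cells(sim$movie, sim$truth, cfg1)
  ph <- sim$truth$phasic[2, ]
  expect_equal(ca1[2, ], (ph - mean(ph)) / sd(ph), tolerance = 1e-10)
})

test_that("rendering adds bleed-through that per-pixel regression recovers", {
  cfg <- sim_config(fov_px = c(64, 64), duration_s = 400, n_cells = 4,
                    release_rate_hz = 0, reuptake_rate_hz = 0,
                    global_drive_amp = 0.5, bleedthrough_frac = 0.2,
                    noise_sd = 0, cell_noise_sd = 1, beta_local = 0,
                    beta_globalCa = 0, seed = 41)
  sim <- simulate_ne_field(cfg)
  ca <- simulate_cells(sim$movie, sim$truth, cfg)
  two <- render_two_channel(sim$movie, ca, sim$truth, cfg)
  # soma pixel: green = NE + 0.2 * red, red varies with independent cell noise
  px <- which(two$soma_labels == 1)[1]
  red_raw <- 0.5 + 0.2 * ca[1, ]
  slope <- coef(lm(two$green[, px] ~ red_raw))[2]
  expect_lt(abs(slope - 0.2) / 0.2, 0.1)

  # bleedthrough 0, noise 0: green equals the NE field exactly off-soma
  cfg0 <- cfg; cfg0$bleedthrough_frac <- 0
  two0 <- render_two_channel(sim$movie, ca, sim$truth, cfg0)
  off <- which(two0$soma_labels == 0L)
  expect_equal(two0$green[, off], sim$movie$data[, off], tolerance = 1e-12)
})

test_that("event lists round-trip through JSON serialization", {
  sim <- small_sim()
  path <- tempfile(fileext = ".json")
  write_truth_json(sim$truth, path)
  back <- read_truth_json(path)
  expect_equal(back$events$onset_frame, sim$truth$events$onset_frame)
  expect_equal(back$events$x_px, sim$truth$events$x_px, tolerance = 1e-12)
  expect_equal(back$cell_centers$x_px, sim$truth$cell_centers$x_px,
               tolerance = 1e-12)
})
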
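# Event calling from constructed pattern tables, event maps, distance
# traces, and regression of synchrony on distance.

pat_row <- function(frame, type, x, y, z, div = 0.01) {
  data.frame(frame = frame, type = type, x = x, y = y,
             divergence = div, z = z)
}

test_that("a high source followed by a high sink forms one release event", {
  pat <- rbind(pat_row(10:12, "source", 30, 30, 2, div = c(0.01, 0.02, 0.01)),
               pat_row(40:42, "sink", 30.5, 30.5, 1.8, div = -0.015))
  cp <- classify_and_pair(pat, frame_hz = 15, px_um = 1.47)
  expect_equal(nrow(cp$events), 1)
  expect_equal(cp$events$kind, "release")
  expect_equal(cp$events$onset_frame, 11)   # peak divergence
  expect_equal(cp$events$offset_frame, 40)
  expect_equal(nrow(cp$unpaired), 0)

  # low source + low sink -> reuptake
  pat2 <- rbind(pat_row(10:12, "source", 30, 30, -2),
                pat_row(40:42, "sink", 30.5, 30.5, -1.6, div = -0.01))
  cp2 <- classify_and_pair(pat2, 15, 1.47)
  expect_equal(cp2$events$kind, "reuptake")
})

test_that("type-mismatched pairs stay unpaired and patterns are conserved", {
  pat <- rbind(pat_row(10:12, "source", 30, 30, 2),
               pat_row(40:42, "sink", 30.5, 30.5, -1.8))
  cp <- classify_and_pair(pat, 15, 1.47)
  expect_equal(nrow(cp$events), 0)
  expect_equal(nrow(cp$unpaired), 2)
  # conservation: paired episodes + unpaired = all episodes
  expect_equal(2 * nrow(cp$events) + nrow(cp$unpaired), nrow(cp$episodes))

  # sink too far away in space
  pat3 <- rbind(pat_row(10:12, "source", 30, 30, 2),
                pat_row(40:42, "sink", 80, 80, 1.8))
  cp3 <- classify_and_pair(pat3, 15, 1.47, max_dist_um = 20)
  expect_equal(nrow(cp3$events), 0)
  # below-threshold patterns are dropped entirely
  pat4 <- pat_row(10:12, "source", 30, 30, 0.5)
  cp4 <- classify_and_pair(pat4, 15, 1.47)
  expect_equal(nrow(cp4$episodes), 0)
})

test_that("event maps reproduce the analytic correlation directions", {
  ev <- data.frame(kind = c("release", "reuptake"),
                   onset_frame = c(10, 50), offset_frame = c(30, 70),
                   x = c(20, 20), y = c(20, 20))
  m <- event_maps_and_correlations(ev, 48, 48, 100)
  expect_equal(m$spatial_r, 1, tolerance = 1e-12)
  # disjoint halves -> negative spatial correlation
  ev2 <- data.frame(kind = c("release", "reuptake"),
                    onset_frame = c(10, 50), offset_frame = c(30, 70),
                    x = c(10, 38), y = c(24, 24))
  m2 <- event_maps_and_correlations(ev2, 48, 48, 100)
  expect_lt(m2$spatial_r, 0)
  # non-overlapping actives -> negative temporal correlation
  expect_lt(m2$temporal_r, 0)
  # single-kind catalogs leave correlations missing
  m3 <- event_maps_and_correlations(ev[1, ], 48, 48, 100)
  expect_true(is.na(m3$spatial_r) && is.na(m3$temporal_r))
})

test_that("distance-to-event traces follow the active-event geometry", {
  ev <- data.frame(onset_frame = c(10, 15), offset_frame = c(20, 30),
                   x = c(10, 40), y = c(10, 10))
  d <- distance_to_event(ev, c(10, 10), 40, px_um = 2)
  expect_equal(d[12], 0)                       # event 1 on the cell
  expect_equal(d[25], 30 * 2)                  # only event 2 active
  expect_true(is.na(d[5]) && is.na(d[35]))     # nothing active
  expect_equal(d[17], 0)                       # min of the two distances
})

test_that("log regression of synchrony on distance is exact when noiseless", {
  set.seed(10)
  d <- runif(500, 1, 80)
  syn <- 0.1 * log(d + 1) + 0.2
  fit <- log_regression_synchrony(d, syn)
  expect_equal(fit$slope, 0.1, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_error(log_regression_synchrony(rep(3, 100), rnorm(100)),
               "degenerate")
  # null calibration: independent synchrony -> ~5% significant slopes
  sig <- replicate(200, {
    fit <- log_regression_synchrony(runif(200, 1, 80), rnorm(200))
    fit$slope_p < 0.05
  })
  expect_lt(abs(mean(sig) - 0.05), 0.05)
})

test_that("expression control residualizes out a planted confound", {
  set.seed(3)
  h <- 30; w <- 30
  expr <- outer(rep(1, h), seq(0.5, 1.5, length.out = w))
  noise_a <- matrix(rnorm(h * w, sd = 0.05), h)
  noise_b <- matrix(rnorm(h * w, sd = 0.05), h)
  map_a <- expr + noise_a
  map_b <- expr + noise_b
  ec <- expression_control(map_a, map_b, expr)
  expect_lt(ec$r, ec$raw_r)    # corrected r drops once the gradient is removed
  expect_lt(abs(ec$r), 0.2)
  # uniform expression map: corrected equals raw
  expect_message(ec2 <- expression_control(map_a, map_b, matrix(1, h, w)),
                 "constant")
  expect_equal(ec2$r, ec2$raw_r)
})

test_that("noise control refuses a uselessly small null", {
  expect_error(noise_control(NULL, n = 5), "n < 20")
})
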
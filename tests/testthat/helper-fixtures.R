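# Shared fixtures: all synthetic, built in code at test time.

# small saline movie with events and cells, cached per session
small_sim <- local({
  cache <- NULL
  function(seed = 3) {
    if (is.null(cache)) {
      cfg <- sim_config(fov_px = c(64, 64), duration_s = 60, n_cells = 4,
                        n_varicosities = 8, release_rate_hz = 0.02,
                        noise_sd = 0.02, seed = seed)
      sim <- simulate_ne_field(cfg)
      ca <- simulate_cells(sim$movie, sim$truth, cfg)
      two <- render_two_channel(sim$movie, ca, sim$truth, cfg)
      cache <<- list(cfg = cfg, movie = sim$movie, truth = sim$truth,
                     ca = ca, two = two)
    }
    cache
  }
})

# analytic linear velocity fields around a center
linear_field <- function(h, w, cx, cy, J) {
  u <- matrix(0, h, w); v <- matrix(0, h, w)
  for (j in seq_len(w)) {
    dx <- j - cx
    dy <- seq_len(h) - cy
    u[, j] <- J[1, 1] * dx + J[1, 2] * dy
    v[, j] <- J[2, 1] * dx + J[2, 2] * dy
  }
  list(u = u, v = v)
}

# phase-correlation translation oracle (independent of Horn-Schunck)
phase_correlation_shift <- function(f1, f2) {
  F1 <- stats::fft(f1); F2 <- stats::fft(f2)
  R <- F2 * Conj(F1)
  R <- R / pmax(Mod(R), 1e-12)
  cc <- Re(stats::fft(R, inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  wrap <- function(i, n) if (i - 1 > n / 2) i - 1 - n else i - 1
  c(dy = wrap(pk[1], nrow(f1)), dx = wrap(pk[2], ncol(f1)))
}
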
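# Synthetic two-channel movie generator with known ground truth.
#
# The NE field is baseline + shared slow drive + release plumes - reuptake
# dips, all multiplied by a sensor-expression gain map. A release plume is a
# spatial Gaussian that appears at its onset frame with peak `release_amp`,
# spreads diffusively (mass-conserving) for `spread_s` seconds, and is then
# cleared with first-order kinetics (time constant `reuptake_tau_s`).
# Reuptake dips have the same spatial form with negative amplitude and
# preferentially reuse recent release sites after a delay. Cells couple to the
# phasic (event-plume) component of their perineuronal annulus.

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic movie generator.
#' Defaults describe a saline-condition field of view at the acquisition scale
#' used throughout the package: 256 x 256 px at 1.47 um/px, 15 Hz.
#'
#' @param fov_px integer pair, frame height and width in pixels
#' @param px_um microns per pixel
#' @param frame_hz frame rate after temporal binning, Hz
#' @param duration_s recording length, seconds
#' @param n_cells number of simulated somata
#' @param n_varicosities number of release sites (axonal varicosities)
#' @param release_rate_hz Poisson release rate per varicosity, events/s
#' @param diffusion_sigma_um spatial scale of a release plume at onset, um
#' @param release_amp peak amplitude of a release plume (baseline units)
#' @param spread_s duration of the mass-conserving spread phase, s
#' @param diffusion_um2_s effective diffusion constant for plume spreading
#' @param reuptake_rate_hz rate of reuptake dips at random (non-release)
#'   locations, per varicosity
#' @param reuptake_tau_s first-order NE clearance time constant, s
#' @param reuptake_amp peak magnitude of a reuptake dip
#' @param reuptake_delay_s mean delay from a release offset to its co-located
#'   reuptake dip, s
#' @param colocation_p probability a release is followed by a reuptake dip at
#'   the same site
#' @param burst_period_s period of the release bout cycle, s; releases occur
#'   in bouts, reuptake dominates between them
#' @param burst_duty fraction of the bout cycle during which release occurs
#' @param global_drive_amp standard deviation of the shared slow NE drive
#' @param global_drive_tau_s correlation time of the shared drive, s
#' @param baseline tonic NE baseline level
#' @param beta_local planted coupling of cell activity to phasic annulus NE
#' @param beta_globalCa planted coupling to the population activity of the
#'   other cells
#' @param beta_interaction planted coupling to the local x global NE product,
#'   active only while the field is coherent (high-synchrony state)
#' @param cell_noise_sd standard deviation of the cell's private rate noise
#' @param cell_noise_tau_s correlation time of the private noise, s
#' @param ca_tau_s calcium indicator decay time constant, s (0 = no kernel)
#' @param soma_radius_um soma radius, um
#' @param local_radius_um outer radius of the perineuronal annulus, um
#' @param phasic_ref_sd reference scale for the phasic coupling; NULL
#'   standardizes each cell's phasic trace by its own SD. Pass a saline run's
#'   phasic SD to build matched drug pairs with identical physical gain.
#' @param neuropil_ca_gain gain of the shared population calcium signal
#'   painted into the red neuropil background
#' @param bleedthrough_frac fraction of each channel leaking into the other
#' @param noise_sd imaging noise SD added per channel at render time
#' @param drift_px_per_min slow rigid drift speed, px/min
#' @param expression_texture contrast of the static multiplicative sensor
#'   expression texture (smoothed random gain field; 0 = flat). Neuropil
#'   expression is textured in real tissue, which also gives the
#'   registration stage its anatomical landmarks
#' @param expression_gradient relative left-right gradient of sensor
#'   expression (0 = uniform)
#' @param condition `"saline"` or `"desipramine"`
#' @param desi_clearance_factor,desi_drive_factor,desi_reuptake_factor,desi_ramp_amp
#'   desipramine condition: clearance time constant multiplier, shared-drive
#'   attenuation, reuptake attenuation, and amplitude of the tonic
#'   accumulation ramp (baseline units reached at the end of the run)
#' @param planted_events optional data.frame (`kind`, `onset_s`, `x_px`,
#'   `y_px`) overriding stochastic event generation
#' @param seed integer RNG seed; identical (config, seed) pairs reproduce
#'   bit-identical output
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(fov_px = c(256L, 256L), px_um = 1.47, frame_hz = 15,
                       duration_s = 300, n_cells = 16, n_varicosities = 30,
                       release_rate_hz = 0.004, diffusion_sigma_um = 12,
                       release_amp = 1, spread_s = 2, diffusion_um2_s = 10,
                       reuptake_rate_hz = 0.002, reuptake_tau_s = 3,
                       reuptake_amp = 0.6, reuptake_delay_s = 8,
                       colocation_p = 0.8, burst_period_s = 60,
                       burst_duty = 0.5, global_drive_amp = 0.5,
                       global_drive_tau_s = 20, baseline = 1,
                       beta_local = 0.3, beta_globalCa = 0.5,
                       beta_interaction = 0, cell_noise_sd = 0.8,
                       cell_noise_tau_s = 4, ca_tau_s = 1,
                       soma_radius_um = 5, local_radius_um = 15,
                       phasic_ref_sd = NULL, neuropil_ca_gain = 0.03,
                       expression_texture = 0.15, bleedthrough_frac = 0.1,
                       noise_sd = 0.1, drift_px_per_min = 0,
                       expression_gradient = 0,
                       condition = c("saline", "desipramine"),
                       desi_clearance_factor = 8, desi_drive_factor = 0.3,
                       desi_reuptake_factor = 0.2, desi_ramp_amp = 1.5,
                       planted_events = NULL, seed = 1L) {
  condition <- match.arg(condition)
  cfg <- as.list(environment())
  cfg$fov_px <- as.integer(rep(fov_px, length.out = 2L))
  cfg$seed <- as.integer(seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("px_um", "frame_hz", "duration_s", "diffusion_sigma_um",
           "release_amp", "reuptake_tau_s", "reuptake_amp", "baseline",
           "soma_radius_um", "local_radius_um", "global_drive_tau_s",
           "cell_noise_tau_s", "burst_period_s")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("sim_config: `", f, "` must be a single positive number")
  }
  nonneg <- c("release_rate_hz", "reuptake_rate_hz", "global_drive_amp",
              "noise_sd", "cell_noise_sd", "drift_px_per_min", "ca_tau_s",
              "spread_s", "expression_texture")
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop("sim_config: `", f, "` must be non-negative")
  }
  if (cfg$bleedthrough_frac < 0 || cfg$bleedthrough_frac >= 0.5)
    stop("sim_config: `bleedthrough_frac` must lie in [0, 0.5)")
  if (cfg$colocation_p < 0 || cfg$colocation_p > 1)
    stop("sim_config: `colocation_p` must lie in [0, 1]")
  if (any(cfg$fov_px < 8L)) stop("sim_config: field of view too small")
  if (cfg$local_radius_um <= cfg$soma_radius_um)
    stop("sim_config: `local_radius_um` must exceed `soma_radius_um`")
  invisible(cfg)
}

#' Single-channel movie container
#'
#' Wraps a T x P matrix (time in rows, column-major pixel order) with its
#' calibration. Used for the NE channel throughout the flow and spatial
#' modules.
#'
#' @param data T x P numeric matrix, P = h*w
#' @param h,w frame dimensions in pixels
#' @param frame_hz frame rate
#' @param px_um microns per pixel
#' @return an object of class `ne_movie`
#' @export
ne_movie <- function(data, h, w, frame_hz, px_um) {
  stopifnot(ncol(data) == h * w)
  structure(list(data = data, h = as.integer(h), w = as.integer(w),
                 frame_hz = frame_hz, px_um = px_um),
            class = "ne_movie")
}

new_ne_movie <- ne_movie

#' @export
print.ne_movie <- function(x, ...) {
  cat(sprintf("<ne_movie> %d x %d px, %d frames @ %.2f Hz, %.2f um/px\n",
              x$h, x$w, nrow(x$data), x$frame_hz, x$px_um))
  invisible(x)
}

# Plume amplitude/scale time course. Returns sigma (px) and peak amplitude per
# active frame; mass (amp * 2*pi*sigma^2) is constant during the spread phase
# and decays with the clearance time constant afterwards.
plume_timecourse <- function(t_rel_s, sigma0_px, amp0, spread_s, d_px2_s, tau_s) {
  sig2 <- sigma0_px^2 + 2 * d_px2_s * t_rel_s
  amp <- amp0 * sigma0_px^2 / sig2 *
    exp(-pmax(0, t_rel_s - spread_s) / tau_s)
  list(sigma = sqrt(sig2), amp = amp)
}

# Frames after onset until the clearance factor falls below 5%
plume_duration_frames <- function(spread_s, tau_s, frame_hz) {
  ceiling((spread_s + tau_s * log(20)) * frame_hz)
}

#' Simulate the norepinephrine concentration field
#'
#' Generates the single-channel NE field (baseline + shared drive + release
#' plumes - reuptake dips, times the expression map) together with the ground
#' truth needed to validate every downstream stage.
#'
#' @param config a [sim_config()]
#' @return list with elements `movie` (an `ne_movie`) and `truth`, a list of
#'   class `ne_truth` holding the event table (`kind`, `onset_frame`,
#'   `offset_frame`, `x_px`, `y_px`, `amp`), cell centers, planted
#'   coefficients, per-cell phasic annulus traces, the varicosity map, the
#'   shared drive, and the expression map.
#' @export
simulate_ne_field <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  h <- cfg$fov_px[1]; w <- cfg$fov_px[2]
  p <- h * w
  tn <- round(cfg$duration_s * cfg$frame_hz)
  dt <- 1 / cfg$frame_hz
  desi <- cfg$condition == "desipramine"
  tau_eff <- cfg$reuptake_tau_s * if (desi) cfg$desi_clearance_factor else 1
  drive_amp <- cfg$global_drive_amp * if (desi) cfg$desi_drive_factor else 1
  reup_fac <- if (desi) cfg$desi_reuptake_factor else 1

  # varicosity map and event schedule ---------------------------------------
  margin <- 3
  vx <- stats::runif(cfg$n_varicosities, margin, w - margin)
  vy <- stats::runif(cfg$n_varicosities, margin, h - margin)
  events <- data.frame(kind = character(), onset_s = numeric(),
                       x_px = numeric(), y_px = numeric(), amp = numeric())
  if (!is.null(cfg$planted_events)) {
    pe <- cfg$planted_events
    stopifnot(all(c("kind", "onset_s", "x_px", "y_px") %in% names(pe)))
    amp <- ifelse(pe$kind == "release", cfg$release_amp,
                  -cfg$reuptake_amp * reup_fac)
    events <- data.frame(kind = pe$kind, onset_s = pe$onset_s,
                         x_px = pe$x_px, y_px = pe$y_px, amp = amp)
  } else {
    on_frac <- cfg$burst_duty
    for (v in seq_len(cfg$n_varicosities)) {
      n_rel <- stats::rpois(1L, cfg$release_rate_hz * cfg$duration_s)
      if (n_rel == 0) next
      # releases thinned to bout phases of the cycle
      cand <- stats::runif(ceiling(n_rel / on_frac) + 3L, 0, cfg$duration_s)
      keep <- (cand %% cfg$burst_period_s) < on_frac * cfg$burst_period_s
      t_rel <- sort(cand[keep])[seq_len(min(n_rel, sum(keep)))]
      t_rel <- t_rel[!is.na(t_rel)]
      for (tr in t_rel) {
        events <- rbind(events, data.frame(
          kind = "release", onset_s = tr, x_px = vx[v], y_px = vy[v],
          amp = cfg$release_amp))
        if (stats::runif(1) < cfg$colocation_p * reup_fac) {
          dly <- cfg$spread_s + cfg$reuptake_tau_s +
            stats::rexp(1, 1 / cfg$reuptake_delay_s)
          events <- rbind(events, data.frame(
            kind = "reuptake", onset_s = tr + dly, x_px = vx[v], y_px = vy[v],
            amp = -cfg$reuptake_amp * reup_fac))
        }
      }
    }
    n_ind <- stats::rpois(1L, cfg$reuptake_rate_hz * reup_fac *
                            cfg$n_varicosities * cfg$duration_s)
    if (n_ind > 0) {
      events <- rbind(events, data.frame(
        kind = "reuptake",
        onset_s = stats::runif(n_ind, 0, cfg$duration_s),
        x_px = stats::runif(n_ind, margin, w - margin),
        y_px = stats::runif(n_ind, margin, h - margin),
        amp = -cfg$reuptake_amp * reup_fac))
    }
  }
  events <- events[events$onset_s < cfg$duration_s - 1 / cfg$frame_hz, ,
                   drop = FALSE]
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  if (nrow(events) == 0 &&
      (cfg$release_rate_hz > 0 || !is.null(cfg$planted_events))) {
    warning("simulate_ne_field: no events fell inside the recording; ",
            "duration may be too short for the configured rates")
  }
  events$onset_frame <- pmax(1L, 1L + floor(events$onset_s * cfg$frame_hz))
  dur_f <- plume_duration_frames(cfg$spread_s, tau_eff, cfg$frame_hz)
  events$offset_frame <- pmin(tn, events$onset_frame + dur_f)

  # cell placement on a jittered grid ---------------------------------------
  r_loc_px <- cfg$local_radius_um / cfg$px_um
  cell_margin <- r_loc_px + 2
  ng <- ceiling(sqrt(cfg$n_cells))
  if (2 * cell_margin >= min(h, w) ||
      (min(h, w) - 2 * cell_margin) / max(1, ng - 1) < 2 * cfg$soma_radius_um / cfg$px_um + 2) {
    stop("simulate_ne_field: n_cells = ", cfg$n_cells,
         " cannot be packed into the field of view with local radius ",
         cfg$local_radius_um, " um (centers must clear the FOV margin and ",
         "each other's somata)")
  }
  gx <- seq(cell_margin, w - cell_margin, length.out = ng)
  gy <- seq(cell_margin, h - cell_margin, length.out = ng)
  grid <- expand.grid(y = gy, x = gx)[seq_len(cfg$n_cells), ]
  jit <- min(2, (gx[min(2, ng)] - gx[1]) / 8)
  centers <- data.frame(
    cell = seq_len(cfg$n_cells),
    x_px = grid$x + stats::runif(cfg$n_cells, -jit, jit),
    y_px = grid$y + stats::runif(cfg$n_cells, -jit, jit))

  # assemble the field -------------------------------------------------------
  drive <- if (drive_amp > 0) {
    smooth_time(ou_process(tn, cfg$global_drive_tau_s, dt, drive_amp), 0.5 * cfg$frame_hz)
  } else numeric(tn)
  ramp <- if (desi) cfg$desi_ramp_amp * cfg$baseline * seq(0, 1, length.out = tn) else numeric(tn)
  data <- matrix(cfg$baseline + drive + ramp, tn, p)

  # per-cell annulus pixel sets (for phasic traces)
  # annulus pixel sets from the same geometry builder the analysis uses
  # (overlap-trimmed), so the planted regressor equals the extracted trace
  ann_px <- build_fields_from_centers(centers, h, w, cfg$local_radius_um,
                                      cfg$soma_radius_um, cfg$px_um)$local_px
  phasic <- matrix(0, cfg$n_cells, tn)
  # static sensor-expression gain map: textured neuropil, optional gradient
  expr_map <- rep(1, p)
  if (cfg$expression_texture > 0) {
    tex <- as.vector(blur_frames(matrix(stats::rnorm(p), 1L), h, w, 2))
    tex <- (tex - mean(tex)) / stats::sd(tex)
    expr_map <- expr_map * pmax(0.2, 1 + cfg$expression_texture * tex)
  }
  if (cfg$expression_gradient != 0) {
    expr_map <- expr_map *
      (1 + cfg$expression_gradient * 2 * (((seq_len(p) - 1L) %/% h) / (w - 1) - 0.5))
  }
  sigma0_px <- cfg$diffusion_sigma_um / cfg$px_um
  d_px2_s <- cfg$diffusion_um2_s / cfg$px_um^2
  xs <- seq_len(w); ys <- seq_len(h)
  for (e in seq_len(nrow(events))) {
    f0 <- events$onset_frame[e]; f1 <- events$offset_frame[e]
    frames <- f0:f1
    tc <- plume_timecourse((frames - f0) * dt, sigma0_px, events$amp[e],
                           cfg$spread_s, d_px2_s, tau_eff)
    rmax <- 4 * max(tc$sigma)
    jx <- which(abs(xs - events$x_px[e]) <= rmax)
    jy <- which(abs(ys - events$y_px[e]) <= rmax)
    px <- as.vector(outer(jy, (jx - 1L) * h, "+"))
    dy2 <- (ys[jy] - events$y_px[e])^2
    dx2 <- (xs[jx] - events$x_px[e])^2
    # separable Gaussian + one block scatter (the per-frame row writes into
    # the big T x P matrix dominate the naive loop)
    M <- matrix(0, length(frames), length(px))
    for (k in seq_along(frames)) {
      s2 <- 2 * tc$sigma[k]^2
      M[k, ] <- tc$amp[k] * as.vector(outer(exp(-dy2 / s2), exp(-dx2 / s2)))
    }
    data[frames, px] <- data[frames, px] + M
    # phasic annulus contributions for nearby cells
    for (i in seq_len(cfg$n_cells)) {
      dc <- sqrt((centers$x_px[i] - events$x_px[e])^2 +
                 (centers$y_px[i] - events$y_px[e])^2)
      if (dc > rmax + r_loc_px) next
      api <- ann_px[[i]]
      ay <- ((api - 1L) %% h) + 1L
      ax <- ((api - 1L) %/% h) + 1L
      ad2 <- (ay - events$y_px[e])^2 + (ax - events$x_px[e])^2
      e_ann <- expr_map[api]
      E <- exp(-outer(ad2, 1 / (2 * tc$sigma^2)))
      phasic[i, frames] <- phasic[i, frames] +
        tc$amp * colMeans(e_ann * E)
    }
  }
  if (any(expr_map != 1)) {
    chunk0 <- max(1L, min(p, floor(2e7 / tn)))
    for (j0 in seq(1L, p, by = chunk0)) {
      idx <- j0:min(p, j0 + chunk0 - 1L)
      data[, idx] <- data[, idx, drop = FALSE] * rep(expr_map[idx], each = tn)
    }
  }

  truth <- structure(list(
    events = events[, c("kind", "onset_frame", "offset_frame",
                        "x_px", "y_px", "amp", "onset_s")],
    cell_centers = centers,
    planted_betas = data.frame(cell = centers$cell,
                               beta_local = cfg$beta_local,
                               beta_globalCa = cfg$beta_globalCa,
                               beta_interaction = cfg$beta_interaction),
    diffusion_sigma_um = cfg$diffusion_sigma_um,
    phasic = phasic,
    varicosities = data.frame(x_px = vx, y_px = vy),
    drive = drive,
    expression_map = expr_map,
    annulus_px = ann_px), class = "ne_truth")
  list(movie = new_ne_movie(data, h, w, cfg$frame_hz, cfg$px_um),
       truth = truth)
}

#' Simulate calcium activity of the cells
#'
#' Each cell's latent activity is `beta_local` times its standardized phasic
#' annulus NE, plus `beta_globalCa` times the standardized mean activity of
#' the other cells, plus (optionally) `beta_interaction` times the local x
#' global NE product gated to the field's own high-coherence state, plus
#' private slow rate noise; the sum is convolved with a single-exponential
#' calcium kernel.
#'
#' @param ne_movie the `ne_movie` from [simulate_ne_field()]
#' @param truth the matching `ne_truth`
#' @param config the same [sim_config()]
#' @return `n_cells x T` matrix of calcium traces; attributes `phasic_sd`
#'   (per-cell raw phasic SD used for scaling), `gate` (high-coherence state
#'   used for the interaction), and `latent` (pre-kernel activity)
#' @export
simulate_cells <- function(ne_movie, truth, config) {
  cfg <- config
  set.seed(cfg$seed + 1L)
  tn <- nrow(ne_movie$data)
  n <- cfg$n_cells
  dt <- 1 / cfg$frame_hz
  phasic <- truth$phasic
  phasic_sd <- apply(phasic, 1L, stats::sd)
  s_ref <- if (is.null(cfg$phasic_ref_sd)) phasic_sd else
    rep(cfg$phasic_ref_sd, n)
  degenerate <- !is.finite(s_ref) | s_ref < 1e-12
  s_ref[degenerate] <- 1
  xs <- (phasic - rowMeans(phasic)) / s_ref

  noise <- t(vapply(seq_len(n), function(i)
    ou_process(tn, cfg$cell_noise_tau_s, dt), numeric(tn)))
  u <- cfg$beta_local * xs + cfg$cell_noise_sd * noise

  # shared population drive: one exogenous latent seen by every cell (the
  # analysis proxies it by the mean calcium of the other cells)
  pop_signal <- ou_process(tn, 3, dt)
  pop <- matrix(rep(pop_signal, each = n), n, tn)

  gate <- rep(TRUE, tn)
  inter <- matrix(0, n, tn)
  if (cfg$beta_interaction != 0) {
    geom <- build_fields_from_centers(truth$cell_centers, ne_movie$h,
                                      ne_movie$w, cfg$local_radius_um,
                                      cfg$soma_radius_um, cfg$px_um)
    syn <- matrix(NA_real_, n, tn)
    green_total <- rowSums(ne_movie$data)
    p_all <- ne_movie$h * ne_movie$w
    for (i in seq_len(n)) {
      loc <- rowMeans(ne_movie$data[, geom$local_px[[i]], drop = FALSE])
      excl <- c(geom$soma_px[[i]], geom$local_px[[i]])
      glo <- (green_total -
                rowSums(ne_movie$data[, excl, drop = FALSE])) /
        (p_all - length(excl))
      # gate and product are built on the same standardized (detrended, 1 s
      # smoothed, z-scored) scale the analysis uses, so the planted regime
      # and interaction match what the fits see
      li <- standardize(loc, cfg$frame_hz)
      gi <- standardize(glo, cfg$frame_hz)
      syn[i, ] <- sliding_correlation(li, gi, cfg$frame_hz, window_s = 30)
      inter[i, ] <- li * gi
    }
    avg_syn <- colMeans(syn)
    gate <- !is.na(avg_syn) & avg_syn >= mean(avg_syn, na.rm = TRUE)
    inter <- sweep(inter, 2L, as.numeric(gate), "*")
  }

  y <- u + cfg$beta_globalCa * pop + cfg$beta_interaction * inter
  ca <- y
  if (cfg$ca_tau_s > 0) {
    a <- exp(-dt / cfg$ca_tau_s)
    for (i in seq_len(n)) {
      ca[i, ] <- stats::filter((1 - a) * y[i, ], a, method = "recursive")
    }
  }
  attr(ca, "phasic_sd") <- phasic_sd
  attr(ca, "gate") <- gate
  attr(ca, "latent") <- y
  ca
}

#' Render the two-channel movie
#'
#' Green channel: the NE field plus bleed-through from red. Red channel: a
#' neuropil background with calcium fluorescence painted into soma disks,
#' plus bleed-through from green. Gaussian imaging noise approximates shot
#' noise at high photon counts; optional slow rigid drift is applied to both
#' channels identically.
#'
#' @inheritParams simulate_cells
#' @param ca_traces matrix from [simulate_cells()]
#' @return object of class `two_channel_movie`: list with `green`, `red`
#'   (T x P matrices), `h`, `w`, `frame_hz`, `px_um`, `soma_labels` (h x w
#'   integer label image) and attribute `shifts` (planted per-frame drift)
#' @export
render_two_channel <- function(ne_movie, ca_traces, truth, config) {
  cfg <- config
  set.seed(cfg$seed + 2L)
  h <- ne_movie$h; w <- ne_movie$w; p <- h * w
  tn <- nrow(ne_movie$data)
  stopifnot(ncol(ca_traces) == tn)
  # copy the NE field chunkwise into a fresh matrix so later in-place edits
  # never trigger a whole-channel duplication of the caller's field
  green <- matrix(0, tn, p)
  chunk0 <- max(1L, min(p, floor(2e7 / tn)))
  for (j0 in seq(1L, p, by = chunk0)) {
    idx <- j0:min(p, j0 + chunk0 - 1L)
    green[, idx] <- ne_movie$data[, idx, drop = FALSE]
  }
  # red neuropil: textured static background plus diluted population calcium
  # dynamics (the indicator expresses on neuropil processes, giving the
  # structural contrast registration relies on)
  pop_mean <- colMeans(ca_traces)
  red <- matrix(0.3 + cfg$neuropil_ca_gain * (pop_mean - mean(pop_mean)),
                tn, p)
  if (cfg$expression_texture > 0) {
    tex <- as.vector(blur_frames(matrix(stats::rnorm(p), 1L), h, w, 2))
    tex <- pmax(0.2, 1 + 2 * cfg$expression_texture *
                  (tex - mean(tex)) / stats::sd(tex))
    for (j0 in seq(1L, p, by = chunk0)) {
      idx <- j0:min(p, j0 + chunk0 - 1L)
      red[, idx] <- red[, idx, drop = FALSE] *
        rep(tex[idx], each = tn)
    }
  }
  labels <- matrix(0L, h, w)
  r_soma_px <- cfg$soma_radius_um / cfg$px_um
  for (i in seq_len(nrow(truth$cell_centers))) {
    m <- disk_mask(h, w, truth$cell_centers$y_px[i],
                   truth$cell_centers$x_px[i], r_soma_px)
    labels[m] <- i
    red[, which(m)] <- 0.5 + 0.2 * ca_traces[i, ]
    # the NE sensor expresses on neuropil, not somata: soma pixels are dark
    # and NE-static in the green channel
    green[, which(m)] <- 0.4 * cfg$baseline
  }
  if (cfg$bleedthrough_frac > 0) {
    chunk <- max(1L, min(p, floor(2e7 / tn)))
    for (j0 in seq(1L, p, by = chunk)) {
      idx <- j0:min(p, j0 + chunk - 1L)
      g0 <- green[, idx, drop = FALSE]
      green[, idx] <- g0 + cfg$bleedthrough_frac * red[, idx, drop = FALSE]
      red[, idx] <- red[, idx, drop = FALSE] + cfg$bleedthrough_frac * g0
    }
  }
  shifts <- matrix(0, tn, 2L, dimnames = list(NULL, c("dy", "dx")))
  if (cfg$drift_px_per_min > 0) {
    theta <- pi / 6
    dpf <- cfg$drift_px_per_min / (60 * cfg$frame_hz)
    shifts[, "dy"] <- (seq_len(tn) - 1L) * dpf * sin(theta)
    shifts[, "dx"] <- (seq_len(tn) - 1L) * dpf * cos(theta)
    for (t in seq_len(tn)) {
      green[t, ] <- as.vector(shift_frame(matrix(green[t, ], h, w),
                                          shifts[t, 1L], shifts[t, 2L]))
      red[t, ] <- as.vector(shift_frame(matrix(red[t, ], h, w),
                                        shifts[t, 1L], shifts[t, 2L]))
    }
  }
  if (cfg$noise_sd > 0) {
    chunk <- max(1L, min(p, floor(2e7 / tn)))
    for (j0 in seq(1L, p, by = chunk)) {
      idx <- j0:min(p, j0 + chunk - 1L)
      n_el <- tn * length(idx)
      green[, idx] <- green[, idx, drop = FALSE] +
        stats::rnorm(n_el, sd = cfg$noise_sd)
      red[, idx] <- red[, idx, drop = FALSE] +
        stats::rnorm(n_el, sd = cfg$noise_sd)
    }
  }
  structure(list(green = green, red = red, h = h, w = w,
                 frame_hz = ne_movie$frame_hz, px_um = ne_movie$px_um,
                 soma_labels = labels, shifts = shifts),
            class = "two_channel_movie")
}

#' @export
print.two_channel_movie <- function(x, ...) {
  cat(sprintf("<two_channel_movie> %d x %d px x 2ch, %d frames @ %.2f Hz\n",
              x$h, x$w, nrow(x$green), x$frame_hz))
  invisible(x)
}

#' Build a trace set directly from generator output
#'
#' Skips rendering/registration/bleed-through and assembles the standardized
#' trace set from the clean NE field and the simulated calcium traces —
#' useful when the quantity under study does not involve the imaging model.
#'
#' @inheritParams simulate_cells
#' @param ca_traces matrix from [simulate_cells()]
#' @return a `trace_set`
#' @export
traceset_from_simulation <- function(ne_movie, ca_traces, truth, config) {
  geom <- build_fields_from_centers(truth$cell_centers, ne_movie$h,
                                    ne_movie$w, config$local_radius_um,
                                    config$soma_radius_um, config$px_um)
  n <- nrow(ca_traces)
  tn <- ncol(ca_traces)
  local_ne <- t(vapply(geom$local_px, function(px)
    rowMeans(ne_movie$data[, px, drop = FALSE]), numeric(tn)))
  green_total <- rowSums(ne_movie$data)
  p_all <- ne_movie$h * ne_movie$w
  global_ne <- t(vapply(seq_len(n), function(i) {
    excl <- c(geom$soma_px[[i]], geom$local_px[[i]])
    (green_total - rowSums(ne_movie$data[, excl, drop = FALSE])) /
      (p_all - length(excl))
  }, numeric(tn)))
  pop_ca <- t(vapply(seq_len(n), function(i)
    colMeans(ca_traces[-i, , drop = FALSE]), numeric(tn)))
  std <- function(m) t(apply(m, 1L, standardize, frame_hz = ne_movie$frame_hz,
                             kernel_s = 1))
  structure(list(cell_ca = std(ca_traces), local_ne = std(local_ne),
                 global_ne = std(global_ne), pop_ca = std(pop_ca),
                 raw_cell_ca = ca_traces, raw_local_ne = local_ne,
                 frame_hz = ne_movie$frame_hz, geometry = geom,
                 kernel_s = 1),
            class = "trace_set")
}

#' Simulate a pairwise-correlation table for the mixed-model comparison
#'
#' Generates correlation observations with a planted fixed drug effect and
#' random mouse- and cell-level intercepts and slopes, matching the design of
#' the drug-condition comparison (saline coded as the reference level and the
#' drug effect expressed as saline minus desipramine).
#'
#' @param n_mice,cells_per_mouse,obs_per_cell design sizes
#' @param drug_effect planted fixed effect of saline over desipramine
#' @param baseline_r mean correlation under desipramine
#' @param mouse_sd,cell_sd random intercept SDs; slope SDs are half these
#' @param resid_sd residual SD
#' @param seed RNG seed
#' @return data.frame with columns `correlation`, `drug`, `mouse`, `cell_id`
#' @export
simulate_correlation_table <- function(n_mice = 3, cells_per_mouse = 110,
                                       obs_per_cell = 13, drug_effect = 0.10,
                                       baseline_r = 0.45, mouse_sd = 0.05,
                                       cell_sd = 0.05, resid_sd = 0.2,
                                       seed = 1L) {
  set.seed(seed)
  rows <- list()
  k <- 0L
  for (m in seq_len(n_mice)) {
    m_int <- stats::rnorm(1, sd = mouse_sd)
    m_slp <- stats::rnorm(1, sd = mouse_sd / 2)
    for (c in seq_len(cells_per_mouse)) {
      c_int <- stats::rnorm(1, sd = cell_sd)
      c_slp <- stats::rnorm(1, sd = cell_sd / 2)
      for (drug in c("saline", "desipramine")) {
        d <- as.numeric(drug == "saline")
        mu <- baseline_r + m_int + c_int + d * (drug_effect + m_slp + c_slp)
        k <- k + 1L
        rows[[k]] <- data.frame(
          correlation = mu + stats::rnorm(obs_per_cell, sd = resid_sd),
          drug = drug,
          mouse = paste0("m", m),
          cell_id = paste0("m", m, "c", c))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$drug <- stats::relevel(factor(out$drug), ref = "desipramine")
  rownames(out) <- NULL
  out
}
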
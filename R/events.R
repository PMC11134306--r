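# Release/reuptake event calling from critical-point patterns, event maps and
# their spatial/temporal correlations, distance-to-event traces, and the
# processed-noise control.

#' Consolidate per-frame patterns into episodes
#'
#' A smooth expanding (or receding) region yields a critical point of the same
#' type at nearly the same location on many consecutive frames. Patterns of
#' one type are linked into an episode when they fall within `link_px` of the
#' episode's running center and within `max_gap_frames` of its last frame.
#' Episodes shorter than `min_frames` are discarded as flicker.
#'
#' @param patterns data.frame from [find_patterns()]
#' @param link_px linking radius in pixels
#' @param max_gap_frames tolerated frame gap inside one episode
#' @param min_frames minimum episode length
#' @return data.frame, one row per episode: `type`, `onset_frame`,
#'   `end_frame`, `peak_frame` (frame of maximum |divergence|), `x`, `y`,
#'   `z` (position and center z at the peak frame), `n_frames`
#' @export
consolidate_patterns <- function(patterns, link_px = 8, max_gap_frames = 3,
                                 min_frames = 2) {
  if (nrow(patterns) == 0L) {
    return(data.frame(type = character(), onset_frame = integer(),
                      end_frame = integer(), peak_frame = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      n_frames = integer()))
  }
  patterns <- patterns[order(patterns$frame), ]
  episodes <- list()   # each: list(type, frames, xs, ys, zs, divs)
  open <- list()
  for (k in seq_len(nrow(patterns))) {
    p <- patterns[k, ]
    matched <- FALSE
    if (length(open)) {
      for (e in seq_along(open)) {
        ep <- open[[e]]
        if (ep$type != p$type) next
        if (p$frame - ep$last_frame > max_gap_frames) next
        # track-following: link against the episode's last position, since
        # critical points drift slowly while a region grows or recedes
        nlast <- length(ep$xs)
        d <- sqrt((ep$xs[nlast] - p$x)^2 + (ep$ys[nlast] - p$y)^2)
        if (d <= link_px) {
          ep$frames <- c(ep$frames, p$frame)
          ep$xs <- c(ep$xs, p$x); ep$ys <- c(ep$ys, p$y)
          ep$zs <- c(ep$zs, p$z); ep$divs <- c(ep$divs, p$divergence)
          ep$last_frame <- p$frame
          open[[e]] <- ep
          matched <- TRUE
          break
        }
      }
    }
    if (!matched) {
      open[[length(open) + 1L]] <- list(type = p$type, frames = p$frame,
                                        xs = p$x, ys = p$y, zs = p$z,
                                        divs = p$divergence,
                                        last_frame = p$frame)
    }
    # close stale episodes to keep the open list short
    stale <- vapply(open, function(ep)
      p$frame - ep$last_frame > max_gap_frames, logical(1))
    episodes <- c(episodes, open[stale])
    open <- open[!stale]
  }
  episodes <- c(episodes, open)
  rows <- lapply(episodes, function(ep) {
    if (length(unique(ep$frames)) < min_frames) return(NULL)
    # report the position/z at peak |divergence|: the critical point is best
    # localized when the pattern is strongest
    pk <- which.max(abs(ep$divs))
    data.frame(type = ep$type,
               onset_frame = min(ep$frames),
               end_frame = max(ep$frames),
               peak_frame = ep$frames[pk],
               x = ep$xs[pk],
               y = ep$ys[pk],
               z = ep$zs[pk],
               n_frames = length(unique(ep$frames)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(type = character(), onset_frame = integer(),
                      end_frame = integer(), peak_frame = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      n_frames = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$onset_frame), ]
}

#' Classify patterns by fluorescence and pair sources with sinks
#'
#' High-fluorescence sources/sinks (center z above `+z_thresh`) mark the
#' onset/offset of a release event; low-fluorescence ones (below
#' `-z_thresh`) mark reuptake. Each high source episode is paired greedily
#' (earliest source first) with the nearest subsequent high sink episode
#' within `max_dist_um` and `max_gap_s`; each sink is used once. Low/low
#' pairs form reuptake events. Unpaired episodes are reported, not dropped.
#'
#' @param patterns per-frame data.frame from [find_patterns()]
#' @param frame_hz,px_um movie calibration
#' @param z_thresh fluorescence threshold in SD units
#' @param max_gap_s maximum source-to-sink delay, seconds
#' @param max_dist_um maximum source-to-sink distance, microns
#' @param ... passed to [consolidate_patterns()]
#' @return list `events` (data.frame `kind`, `onset_frame`, `offset_frame`,
#'   `x`, `y`, `duration_s`), `unpaired` (episode data.frame with `role`),
#'   `episodes` (all source/sink episodes after thresholding)
#' @export
classify_and_pair <- function(patterns, frame_hz, px_um, z_thresh = 1,
                              max_gap_s = 30, max_dist_um = 20, ...) {
  pat <- patterns[patterns$type %in% c("source", "sink") &
                    abs(patterns$z) >= z_thresh, , drop = FALSE]
  # consolidate high- and low-fluorescence patterns separately so that a
  # release blob and a co-located later dip never join one episode
  high <- consolidate_patterns(pat[pat$z > 0, , drop = FALSE], ...)
  low <- consolidate_patterns(pat[pat$z < 0, , drop = FALSE], ...)
  pair_set <- function(sub, kind) {
    src <- sub[sub$type == "source", , drop = FALSE]
    snk <- sub[sub$type == "sink", , drop = FALSE]
    src <- src[order(src$peak_frame), , drop = FALSE]
    used <- rep(FALSE, nrow(snk))
    ev <- list(); unp <- list()
    max_gap_f <- max_gap_s * frame_hz
    max_dist_px <- max_dist_um / px_um
    for (i in seq_len(nrow(src))) {
      d <- sqrt((snk$x - src$x[i])^2 + (snk$y - src$y[i])^2)
      ok <- !used & snk$peak_frame > src$peak_frame[i] &
        snk$peak_frame - src$peak_frame[i] <= max_gap_f & d <= max_dist_px
      if (any(ok)) {
        j <- which(ok)[which.min(d[ok])]
        used[j] <- TRUE
        ev[[length(ev) + 1L]] <- data.frame(
          kind = kind,
          onset_frame = src$peak_frame[i],
          offset_frame = snk$peak_frame[j],
          x = (src$x[i] + snk$x[j]) / 2,
          y = (src$y[i] + snk$y[j]) / 2,
          source_z = src$z[i], sink_z = snk$z[j])
      } else {
        unp[[length(unp) + 1L]] <- cbind(src[i, ], role = "source")
      }
    }
    if (any(!used)) {
      unp <- c(unp, list(cbind(snk[!used, , drop = FALSE], role = "sink")))
    }
    list(events = if (length(ev)) do.call(rbind, ev) else NULL,
         unpaired = if (length(unp)) do.call(rbind, unp) else NULL)
  }
  rel <- pair_set(high, "release")
  reu <- pair_set(low, "reuptake")
  events <- rbind(rel$events, reu$events)
  if (is.null(events)) {
    events <- data.frame(kind = character(), onset_frame = integer(),
                         offset_frame = integer(), x = numeric(),
                         y = numeric(), source_z = numeric(),
                         sink_z = numeric())
  }
  events$duration_s <- (events$offset_frame - events$onset_frame) / frame_hz
  events <- events[order(events$onset_frame), ]
  rownames(events) <- NULL
  unpaired <- rbind(rel$unpaired, reu$unpaired)
  list(events = events,
       unpaired = if (is.null(unpaired))
         cbind(high[0, ], role = character(0)) else unpaired,
       episodes = rbind(high, low))
}

#' Match detected events against ground truth
#'
#' Greedy one-to-one matching: detected events of the right kind within
#' `max_center_err_px` and `max_onset_err_s` of a planted event count as
#' recovered.
#'
#' @param detected events data.frame from [classify_and_pair()]
#' @param truth_events ground-truth event table (`kind`, `onset_frame`,
#'   `x_px`, `y_px`)
#' @param frame_hz frames per second
#' @param max_center_err_px,max_onset_err_s matching tolerances
#' @return list `recall`, `precision`, `n_matched`, `matches` (data.frame)
#' @export
match_events <- function(detected, truth_events, frame_hz,
                         max_center_err_px, max_onset_err_s) {
  used <- rep(FALSE, nrow(detected))
  matches <- list()
  for (i in seq_len(nrow(truth_events))) {
    te <- truth_events[i, ]
    derr <- sqrt((detected$x - te$x_px)^2 + (detected$y - te$y_px)^2)
    terr <- abs(detected$onset_frame - te$onset_frame) / frame_hz
    ok <- !used & detected$kind == te$kind &
      derr <= max_center_err_px & terr <= max_onset_err_s
    if (any(ok)) {
      j <- which(ok)[which.min(derr[ok] + terr[ok])]
      used[j] <- TRUE
      matches[[length(matches) + 1L]] <- data.frame(
        truth = i, detected = j, center_err_px = derr[j], onset_err_s = terr[j])
    }
  }
  n_matched <- length(matches)
  list(recall = n_matched / max(1L, nrow(truth_events)),
       precision = n_matched / max(1L, nrow(detected)),
       n_matched = n_matched,
       matches = if (n_matched) do.call(rbind, matches) else NULL)
}

#' Event heatmaps and their spatial/temporal correlations
#'
#' Release and reuptake event centers are splatted as Gaussians (sigma
#' `splat_px`), the two normalized maps are linearized and correlated
#' (spatial r), and the per-frame counts of active events (onset <= t <=
#' offset) of each kind are correlated (temporal r).
#'
#' @param events data.frame from [classify_and_pair()]
#' @param h,w field-of-view size in pixels
#' @param n_frames total number of frames
#' @param splat_px Gaussian splat SD in pixels
#' @return list `release_map`, `reuptake_map` (h x w), `spatial_r`,
#'   `temporal_r`, `release_count`, `reuptake_count`
#' @export
event_maps_and_correlations <- function(events, h, w, n_frames,
                                        splat_px = 2) {
  splat <- function(ev) {
    m <- matrix(0, h, w)
    for (i in seq_len(nrow(ev))) {
      m <- m + gaussian_image(h, w, ev$y[i], ev$x[i], splat_px)
    }
    if (sum(m) > 0) m / sum(m) else m
  }
  counts <- function(ev) {
    ct <- integer(n_frames)
    for (i in seq_len(nrow(ev))) {
      fr <- ev$onset_frame[i]:min(ev$offset_frame[i], n_frames)
      ct[fr] <- ct[fr] + 1L
    }
    ct
  }
  rel <- events[events$kind == "release", , drop = FALSE]
  reu <- events[events$kind == "reuptake", , drop = FALSE]
  rel_map <- splat(rel); reu_map <- splat(reu)
  spatial_r <- if (nrow(rel) && nrow(reu) && stats::sd(rel_map) > 0 &&
                   stats::sd(reu_map) > 0) {
    stats::cor(as.vector(rel_map), as.vector(reu_map))
  } else NA_real_
  rc <- counts(rel); uc <- counts(reu)
  temporal_r <- if (nrow(rel) && nrow(reu) && stats::sd(rc) > 0 &&
                    stats::sd(uc) > 0) stats::cor(rc, uc) else NA_real_
  list(release_map = rel_map, reuptake_map = reu_map,
       spatial_r = spatial_r, temporal_r = temporal_r,
       release_count = rc, reuptake_count = uc)
}

#' Distance to the nearest active event at every frame
#'
#' @param events data.frame with `onset_frame`, `offset_frame`, `x`, `y`
#' @param center list or vector `(x, y)` in pixels (a cell's annulus center)
#' @param n_frames number of frames
#' @param px_um microns per pixel
#' @return numeric vector: distance in microns to the nearest event active at
#'   each frame; NA where no event is active
#' @export
distance_to_event <- function(events, center, n_frames, px_um) {
  if (nrow(events) == 0L) stop("distance_to_event: no events")
  out <- rep(NA_real_, n_frames)
  d <- sqrt((events$x - center[[1]])^2 + (events$y - center[[2]])^2) * px_um
  for (i in seq_len(nrow(events))) {
    fr <- events$onset_frame[i]:min(events$offset_frame[i], n_frames)
    out[fr] <- pmin(out[fr], d[i], na.rm = TRUE)
  }
  out
}

#' Logarithmic regression of synchrony on distance to release
#'
#' Ordinary least squares of a cell's NE-synchrony trace on
#' `log(distance + 1 um)`, over frames where both are defined.
#'
#' @param distance_um distance trace from [distance_to_event()]
#' @param synchrony sliding-correlation trace for the same cell
#' @return list `intercept`, `slope`, `slope_p`, `r_squared`, `n`
#' @export
log_regression_synchrony <- function(distance_um, synchrony) {
  ok <- is.finite(distance_um) & is.finite(synchrony)
  if (sum(ok) < 30L)
    stop("log_regression_synchrony: fewer than 30 paired defined frames")
  x <- log(distance_um[ok] + 1)
  if (stats::sd(x) < 1e-12)
    stop("log_regression_synchrony: degenerate distances (all equal)")
  fit <- stats::lm(synchrony[ok] ~ x)
  sm <- summary(fit)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       slope_p = sm$coefficients[2, 4],
       r_squared = sm$r.squared,
       n = sum(ok))
}

#' Expression-heterogeneity control for the spatial correlation
#'
#' Partial correlation of the two linearized event maps controlling for the
#' linearized time-mean fluorescence map: both maps are residualized on the
#' expression map and the residuals correlated.
#'
#' @param map_a,map_b event maps (h x w)
#' @param expression_map time-mean fluorescence image (h x w)
#' @return list `r` (corrected), `raw_r`, `controlled` (FALSE when the
#'   expression map is constant and the plain correlation is returned)
#' @export
expression_control <- function(map_a, map_b, expression_map) {
  stopifnot(identical(dim(map_a), dim(map_b)),
            identical(dim(map_a), dim(expression_map)))
  a <- as.vector(map_a); b <- as.vector(map_b)
  e <- as.vector(expression_map)
  raw_r <- stats::cor(a, b)
  if (stats::sd(e) < 1e-12) {
    message("expression_control: constant expression map; returning plain r")
    return(list(r = raw_r, raw_r = raw_r, controlled = FALSE))
  }
  ra <- stats::residuals(stats::lm(a ~ e))
  rb <- stats::residuals(stats::lm(b ~ e))
  if (stats::sd(ra) < 1e-12 || stats::sd(rb) < 1e-12) {
    return(list(r = NA_real_, raw_r = raw_r, controlled = TRUE))
  }
  list(r = stats::cor(ra, rb), raw_r = raw_r, controlled = TRUE)
}

#' Run the flow -> events -> correlation pipeline on one movie
#'
#' Convenience wrapper used by the analysis drivers and the noise control.
#'
#' @param ne_movie an `ne_movie` (green channel)
#' @param sigma_px,kernel_s,var_floor_frac flow preprocessing parameters
#' @param alpha,n_iter,tol Horn-Schunck parameters
#' @param z_thresh,max_gap_s,max_dist_um pairing parameters
#' @param splat_px heatmap splat SD
#' @return list `events`, `unpaired`, `episodes`, `maps` (from
#'   [event_maps_and_correlations()]), `patterns`
#' @export
run_event_pipeline <- function(ne_movie, sigma_px = 12, kernel_s = 5,
                               var_floor_frac = 0.5, alpha = 1, n_iter = 200,
                               tol = 1e-4, z_thresh = 1, max_gap_s = 30,
                               max_dist_um = 20, splat_px = 2) {
  prep <- preprocess_for_flow(ne_movie, sigma_px, kernel_s, var_floor_frac)
  fl <- flow_series(prep, alpha, n_iter, tol)
  pat <- find_patterns(fl, prep)
  cp <- classify_and_pair(pat, ne_movie$frame_hz, ne_movie$px_um,
                          z_thresh, max_gap_s, max_dist_um)
  maps <- event_maps_and_correlations(cp$events, ne_movie$h, ne_movie$w,
                                      nrow(ne_movie$data), splat_px)
  c(cp, list(maps = maps, patterns = pat))
}

#' Processed-noise control
#'
#' Generates `n` random movies matching the template's per-pixel mean,
#' temporal SD and value distribution (by permuting each pixel's series over
#' time independently), runs the full flow/event/correlation pipeline on
#' each, and returns the null distribution of the spatial and temporal
#' release/reuptake correlations with two-tailed permutation p-values
#' (continuity-corrected, `p = (1 + #{|null| >= |obs|}) / (n + 1)`).
#'
#' @param ne_movie the observed movie (template)
#' @param observed list with `spatial_r` and `temporal_r` (observed values);
#'   NULL computes them from `ne_movie`
#' @param n number of random datasets
#' @param seed RNG seed
#' @param ... pipeline parameters passed to [run_event_pipeline()]
#' @return list `null_spatial`, `null_temporal` (numeric vectors),
#'   `p_spatial`, `p_temporal`, `observed`
#' @export
noise_control <- function(ne_movie, observed = NULL, n = 500, seed = 1L, ...) {
  if (n < 20L) stop("noise_control: n < 20 gives too coarse a p resolution")
  if (is.null(observed)) {
    obs <- run_event_pipeline(ne_movie, ...)$maps
    observed <- list(spatial_r = obs$spatial_r, temporal_r = obs$temporal_r)
  }
  set.seed(seed)
  tn <- nrow(ne_movie$data)
  null_sp <- null_tp <- rep(NA_real_, n)
  for (b in seq_len(n)) {
    perm <- apply(ne_movie$data, 2L, function(col) col[sample.int(tn)])
    res <- run_event_pipeline(
      new_ne_movie(perm, ne_movie$h, ne_movie$w, ne_movie$frame_hz,
                   ne_movie$px_um), ...)$maps
    null_sp[b] <- res$spatial_r
    null_tp[b] <- res$temporal_r
  }
  pval <- function(null, obs) {
    ok <- is.finite(null)
    if (!is.finite(obs) || !any(ok)) return(NA_real_)
    (1 + sum(abs(null[ok]) >= abs(obs))) / (sum(ok) + 1)
  }
  list(null_spatial = null_sp, null_temporal = null_tp,
       p_spatial = pval(null_sp, observed$spatial_r),
       p_temporal = pval(null_tp, observed$temporal_r),
       observed = observed)
}
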
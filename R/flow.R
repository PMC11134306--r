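# Optic-flow extraction: movie preprocessing, Horn-Schunck velocity fields,
# and critical-point (source/sink/saddle/spiral) detection.

#' Preprocess the NE channel for optic flow
#'
#' Spatial Gaussian blur, temporal Gaussian smoothing, per-pixel linear
#' detrend, per-pixel z-score over time. Pixels with zero temporal variance
#' are flagged (all-NA) and excluded downstream.
#'
#' The temporal kernel is a Gaussian whose full width at half maximum is
#' `kernel_s` seconds. The per-pixel normalization is moderated: each pixel's
#' SD is pooled with `var_floor_frac` times the median SD across pixels
#' (in quadrature), so that near-static pixels (field edges, regions between
#' events) cannot blow up to huge z-values and distort the flow field.
#' Pixels with exactly zero variance are flagged as NA.
#'
#' @param ne_movie an `ne_movie` (green channel)
#' @param sigma_px spatial blur SD in pixels
#' @param kernel_s temporal smoothing kernel width (FWHM), seconds
#' @param var_floor_frac variance-moderation fraction (0 disables)
#' @return an `ne_movie` with standardized per-pixel series; attribute
#'   `flow_prep` records the parameters
#' @export
preprocess_for_flow <- function(ne_movie, sigma_px = 12, kernel_s = 5,
                                var_floor_frac = 0.5) {
  x <- blur_frames(ne_movie$data, ne_movie$h, ne_movie$w, sigma_px)
  x <- smooth_time(x, kernel_s / 2.355 * ne_movie$frame_hz)
  x <- detrend_linear(x)
  mu <- colMeans(x)
  sd <- sqrt(colMeans(x^2) - mu^2) * sqrt(nrow(x) / (nrow(x) - 1))
  dead <- !is.finite(sd) | sd < 1e-12
  sd_used <- sqrt(sd^2 + (var_floor_frac * stats::median(sd[!dead]))^2)
  sd_used[dead | sd_used < 1e-12] <- NA_real_
  x <- sweep(sweep(x, 2L, mu), 2L, sd_used, "/")
  out <- new_ne_movie(x, ne_movie$h, ne_movie$w, ne_movie$frame_hz,
                      ne_movie$px_um)
  attr(out, "flow_prep") <- list(sigma_px = sigma_px, kernel_s = kernel_s,
                                 var_floor_frac = var_floor_frac,
                                 zscored = TRUE)
  out
}

#' Horn-Schunck optic flow between two frames
#'
#' Iterative Jacobi solution of the Horn-Schunck objective (brightness
#' constancy + alpha^2 smoothness), stopping at `n_iter` sweeps or when the
#' mean absolute velocity update falls below `tol`.
#'
#' @param f_t,f_t1 consecutive frames, h x w matrices
#' @param alpha smoothness weight
#' @param n_iter maximum iterations
#' @param tol convergence tolerance on the mean absolute update
#' @return list `u` (x-velocity), `v` (y-velocity) h x w matrices in
#'   px/frame, and `iterations`
#' @export
horn_schunck <- function(f_t, f_t1, alpha = 1, n_iter = 200, tol = 1e-4) {
  stopifnot(identical(dim(f_t), dim(f_t1)), alpha > 0)
  if (!all(is.finite(f_t)) || !all(is.finite(f_t1)))
    stop("horn_schunck: non-finite input")
  horn_schunck_cpp(f_t, f_t1, alpha, as.integer(n_iter), tol)
}

#' Velocity fields for a whole movie
#'
#' @param movie preprocessed `ne_movie` (see [preprocess_for_flow()])
#' @inheritParams horn_schunck
#' @return object of class `flow_series`: list of per-frame-pair fields
#'   (`u`, `v`), plus `h`, `w`, `frame_hz`
#' @export
flow_series <- function(movie, alpha = 1, n_iter = 200, tol = 1e-4) {
  tn <- nrow(movie$data)
  h <- movie$h; w <- movie$w
  dat <- movie$data
  dat[!is.finite(dat)] <- 0   # flagged zero-variance pixels
  fields <- vector("list", tn - 1L)
  for (t in seq_len(tn - 1L)) {
    fields[[t]] <- horn_schunck(matrix(dat[t, ], h, w),
                                matrix(dat[t + 1L, ], h, w),
                                alpha, n_iter, tol)
  }
  structure(list(fields = fields, h = h, w = w, frame_hz = movie$frame_hz),
            class = "flow_series")
}

#' Critical points of one velocity field
#'
#' Candidate critical points are grid cells in which both velocity components
#' change sign; the sub-pixel location solves the local linear (Jacobian)
#' model, and the type follows from the Jacobian eigenvalues: both real parts
#' positive = source, both negative = sink, opposite signs = saddle, complex
#' with negative/positive real part = spiral-in/spiral-out. Nearby duplicates
#' (within `merge_px`) are merged, keeping the strongest.
#'
#' @param u,v h x w velocity component matrices
#' @param min_strength minimum Jacobian spectral magnitude (px/frame per px);
#'   filters numerically flat points in near-zero flow
#' @param merge_px merge radius for duplicate detections
#' @return data.frame `type`, `x`, `y` (sub-pixel), `divergence`
#' @export
find_critical_points <- function(u, v, min_strength = 1e-4, merge_px = 3) {
  h <- nrow(u); w <- ncol(u)
  stopifnot(all(is.finite(u)), all(is.finite(v)))
  empty <- data.frame(type = character(), x = numeric(), y = numeric(),
                      divergence = numeric())
  # sign-change cells: corners (i,j),(i+1,j),(i,j+1),(i+1,j+1)
  u00 <- u[-h, -w]; u10 <- u[-1, -w]; u01 <- u[-h, -1]; u11 <- u[-1, -1]
  v00 <- v[-h, -w]; v10 <- v[-1, -w]; v01 <- v[-h, -1]; v11 <- v[-1, -1]
  umin <- pmin(u00, u10, u01, u11); umax <- pmax(u00, u10, u01, u11)
  vmin <- pmin(v00, v10, v01, v11); vmax <- pmax(v00, v10, v01, v11)
  cand <- which(umin <= 0 & umax >= 0 & vmin <= 0 & vmax >= 0, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  i <- cand[, 1L]; j <- cand[, 2L]
  ic <- pmin(pmax(i, 2L), h - 1L); jc <- pmin(pmax(j, 2L), w - 1L)
  # central-difference Jacobian entries at the cell centers (vectorized)
  idx <- function(ii, jj) (jj - 1L) * h + ii
  dudx <- (u[idx(ic, jc + 1L)] - u[idx(ic, jc - 1L)]) / 2
  dudy <- (u[idx(ic + 1L, jc)] - u[idx(ic - 1L, jc)]) / 2
  dvdx <- (v[idx(ic, jc + 1L)] - v[idx(ic, jc - 1L)]) / 2
  dvdy <- (v[idx(ic + 1L, jc)] - v[idx(ic - 1L, jc)]) / 2
  tr <- dudx + dvdy
  dt_ <- dudx * dvdy - dudy * dvdx
  disc <- tr^2 / 4 - dt_
  mag <- ifelse(disc >= 0,
                pmax(abs(tr / 2 + sqrt(pmax(disc, 0))),
                     abs(tr / 2 - sqrt(pmax(disc, 0)))),
                sqrt(pmax(dt_, 0)))
  keep <- mag >= min_strength
  if (!any(keep)) return(empty)
  k <- which(keep)
  # sub-pixel: solve J (dx, dy)' = -(uc, vc)' at each cell center
  ci <- cand[k, 1L]; cj <- cand[k, 2L]
  lin <- (cj - 1L) * (h - 1L) + ci  # corner matrices have h-1 rows
  uc <- (u00[lin] + u10[lin] + u01[lin] + u11[lin]) / 4
  vc <- (v00[lin] + v10[lin] + v01[lin] + v11[lin]) / 4
  a <- dudx[k]; b <- dudy[k]; cc_ <- dvdx[k]; d <- dvdy[k]
  det_ <- a * d - b * cc_
  ddx <- ifelse(abs(det_) > 1e-12, (-d * uc + b * vc) / det_, 0)
  ddy <- ifelse(abs(det_) > 1e-12, (cc_ * uc - a * vc) / det_, 0)
  ddx <- pmin(pmax(ddx, -1), 1); ddy <- pmin(pmax(ddy, -1), 1)
  x <- cj + 0.5 + ddx; y <- ci + 0.5 + ddy
  cplx <- disc[k] < -1e-18
  type <- ifelse(cplx, ifelse(tr[k] < 0, "spiral-in", "spiral-out"),
                 ifelse(dt_[k] < 0, "saddle",
                        ifelse(tr[k] > 0, "source", "sink")))
  res <- data.frame(type = type, x = x, y = y, divergence = tr[k],
                    strength = mag[k])
  res <- res[res$x >= 1 & res$x <= w & res$y >= 1 & res$y <= h, ]
  if (nrow(res) == 0L) return(empty)
  # merge near-duplicates, strongest first
  res <- res[order(-res$strength), ]
  keep <- rep(TRUE, nrow(res))
  for (k in seq_len(nrow(res))) {
    if (!keep[k]) next
    d <- sqrt((res$x - res$x[k])^2 + (res$y - res$y[k])^2)
    dup <- d < merge_px & seq_len(nrow(res)) > k & res$type == res$type[k]
    keep[dup] <- FALSE
  }
  res <- res[keep, c("type", "x", "y", "divergence")]
  rownames(res) <- NULL
  res
}

#' Critical-point patterns for every frame of a flow series
#'
#' @param flow a `flow_series`
#' @param preprocessed the standardized movie the flow was computed from
#'   (used to attach the fluorescence z-value at each pattern center)
#' @inheritParams find_critical_points
#' @return data.frame `frame`, `type`, `x`, `y`, `divergence`, `z`
#' @export
find_patterns <- function(flow, preprocessed, min_strength = 1e-4,
                          merge_px = 3) {
  h <- flow$h
  acc <- list(frame = list(), type = list(), x = list(), y = list(),
              divergence = list(), z = list())
  for (t in seq_along(flow$fields)) {
    cp <- find_critical_points(flow$fields[[t]]$u, flow$fields[[t]]$v,
                               min_strength, merge_px)
    if (nrow(cp) == 0L) next
    px <- pixel_index(pmin(pmax(round(cp$y), 1L), h),
                      pmin(pmax(round(cp$x), 1L), flow$w), h)
    k <- length(acc$frame) + 1L
    acc$frame[[k]] <- rep.int(t, nrow(cp))
    acc$type[[k]] <- cp$type
    acc$x[[k]] <- cp$x; acc$y[[k]] <- cp$y
    acc$divergence[[k]] <- cp$divergence
    acc$z[[k]] <- preprocessed$data[t, px]
  }
  res <- data.frame(frame = unlist(acc$frame),
                    type = unlist(acc$type),
                    x = unlist(acc$x), y = unlist(acc$y),
                    divergence = unlist(acc$divergence),
                    z = unlist(acc$z))
  res[order(res$frame), ]
}
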
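# Preprocessing: raw two-channel movies -> registered, bleed-through
# corrected, standardized trace sets and field geometries.

#' Three-frame temporal median filter and two-frame mean binning
#'
#' Removes single-frame impulses with a per-pixel running median over a
#' 3-frame window, then halves the frame rate with non-overlapping 2-frame
#' mean binning. An odd trailing frame is dropped with a message.
#'
#' @param movie a `two_channel_movie` or `ne_movie`
#' @return the same class of object with halved frame count and frame rate
#' @export
median_filter_and_bin <- function(movie) {
  chans <- intersect(c("green", "red", "data"), names(movie))
  tn <- nrow(movie[[chans[1]]])
  if (tn < 3L) stop("median_filter_and_bin: need at least 3 frames")
  if (tn %% 2L == 1L)
    message("median_filter_and_bin: odd trailing frame dropped")
  for (ch in chans) movie[[ch]] <- median3_bin2_cpp(movie[[ch]])
  movie$frame_hz <- movie$frame_hz / 2
  movie
}

#' Rigid translation registration against a temporal-average reference
#'
#' Estimates a per-frame rigid translation by FFT cross-correlation against
#' the temporal mean of the initial segment (default first 5 min, or the full
#' movie if shorter), with subpixel refinement by parabolic interpolation of
#' the correlation peak. The same shift is applied to every channel. Shifts
#' larger than 10% of the field of view are clamped and flagged with a
#' warning.
#'
#' Shifts are estimated on the structural channel (red: static somata give
#' anatomical contrast; the NE channel is dominated by the dynamics being
#' measured) and applied to all channels identically.
#'
#' @param movie a `two_channel_movie` or `ne_movie`
#' @param reference_s length of the initial segment averaged into the
#'   reference image, seconds
#' @param channel channel used to estimate the shifts
#' @param est_blur_px Gaussian blur (px) applied to the estimation copy only
#' @return list with `movie` (registered) and `shifts` (T x 2 matrix,
#'   columns `dy`, `dx`; the estimated displacement OF each frame relative to
#'   the reference, which the registration removed)
#' @export
register_translation <- function(movie, reference_s = 300,
                                 channel = c("red", "green", "data"),
                                 est_blur_px = 2) {
  chans <- intersect(c("green", "red", "data"), names(movie))
  channel <- intersect(channel, chans)[1]
  h <- movie$h; w <- movie$w
  tn <- nrow(movie[[chans[1]]])
  # estimate on a blurred copy: suppresses pixel noise so the anatomical
  # contrast, not shot noise, drives the correlation peak
  est <- blur_frames(movie[[channel]], h, w, est_blur_px)
  n_ref <- max(1L, min(tn, round(reference_s * movie$frame_hz)))
  ref <- matrix(colMeans(est[seq_len(n_ref), , drop = FALSE]), h, w)
  Fref <- Conj(stats::fft(ref - mean(ref)))
  max_shift <- 0.10 * min(h, w)
  shifts <- matrix(0, tn, 2L, dimnames = list(NULL, c("dy", "dx")))
  flagged <- logical(tn)
  wrap <- function(i, n) ifelse(i > n / 2, i - n, i)
  for (t in seq_len(tn)) {
    fr <- matrix(est[t, ], h, w)
    cc <- Re(stats::fft(stats::fft(fr - mean(fr)) * Fref, inverse = TRUE))
    pk <- arrayInd(which.max(cc), dim(cc))
    iy <- pk[1L]; ix <- pk[2L]
    # parabolic subpixel refinement around the integer peak (circular index)
    cidx <- function(i, n) ((i - 1L) %% n) + 1L
    py <- cc[cidx(c(iy - 1L, iy, iy + 1L), h), ix]
    px <- cc[iy, cidx(c(ix - 1L, ix, ix + 1L), w)]
    sub <- function(v) {
      d <- (v[1] - v[3]) / (2 * (v[1] - 2 * v[2] + v[3]))
      if (!is.finite(d) || abs(d) > 0.5) 0 else d
    }
    dy <- wrap(iy, h) - 1 + sub(py)
    dx <- wrap(ix, w) - 1 + sub(px)
    if (abs(dy) > max_shift || abs(dx) > max_shift) {
      flagged[t] <- TRUE
      dy <- sign(dy) * min(abs(dy), max_shift)
      dx <- sign(dx) * min(abs(dx), max_shift)
    }
    shifts[t, ] <- c(dy, dx)
    if (abs(dy) > 1e-9 || abs(dx) > 1e-9) {
      for (ch in chans) {
        movie[[ch]][t, ] <- as.vector(
          shift_frame(matrix(movie[[ch]][t, ], h, w), -dy, -dx))
      }
    }
  }
  if (any(flagged)) {
    warning("register_translation: ", sum(flagged),
            " frame(s) exceeded 10% of the FOV; shifts clamped")
  }
  attr(shifts, "flagged") <- flagged
  list(movie = movie, shifts = shifts)
}

#' Per-cell field geometry from soma masks
#'
#' Builds, for every cell, the local-NE annulus (a disk of `radius_um` around
#' the soma centroid minus the soma and minus any pixel already claimed by
#' another cell's soma or annulus, resolved in cell-index order) and the
#' global mask (field of view minus that cell's soma and annulus).
#'
#' @param soma_labels h x w integer label image (0 = background, i = cell i)
#' @param radius_um outer annulus radius, microns
#' @param px_um microns per pixel
#' @return object of class `field_geometry`: lists `soma_px`, `local_px`,
#'   `global_px` of pixel-index vectors, `centers` (data.frame), `h`, `w`,
#'   `radius_um`, `px_um`
#' @export
build_fields <- function(soma_labels, radius_um = 15, px_um = 1.47) {
  h <- nrow(soma_labels); w <- ncol(soma_labels)
  ids <- sort(unique(soma_labels[soma_labels > 0]))
  r_px <- radius_um / px_um
  soma_px <- local_px <- global_px <- vector("list", length(ids))
  centers <- data.frame(cell = ids, x_px = NA_real_, y_px = NA_real_)
  claimed <- soma_labels > 0
  for (k in seq_along(ids)) {
    sp <- which(soma_labels == ids[k])
    soma_px[[k]] <- sp
    cy <- mean(((sp - 1L) %% h) + 1L)
    cx <- mean(((sp - 1L) %/% h) + 1L)
    centers$y_px[k] <- cy; centers$x_px[k] <- cx
    ann <- disk_mask(h, w, cy, cx, r_px)
    ann[sp] <- FALSE
    ann[claimed] <- FALSE
    if (!any(ann)) {
      stop("build_fields: annulus of cell ", ids[k],
           " fully consumed by overlapping somata/annuli")
    }
    local_px[[k]] <- which(ann)
    claimed[ann] <- TRUE
  }
  for (k in seq_along(ids)) {
    g <- rep(TRUE, h * w)
    g[soma_px[[k]]] <- FALSE
    g[local_px[[k]]] <- FALSE
    global_px[[k]] <- which(g)
  }
  structure(list(soma_px = soma_px, local_px = local_px,
                 global_px = global_px, centers = centers, h = h, w = w,
                 radius_um = radius_um, px_um = px_um),
            class = "field_geometry")
}

# Geometry directly from center coordinates (generator-side convenience)
build_fields_from_centers <- function(centers, h, w, radius_um, soma_radius_um,
                                      px_um) {
  labels <- matrix(0L, h, w)
  r_soma <- soma_radius_um / px_um
  for (i in seq_len(nrow(centers))) {
    m <- disk_mask(h, w, centers$y_px[i], centers$x_px[i], r_soma)
    labels[m & labels == 0L] <- centers$cell[i]
  }
  build_fields(labels, radius_um, px_um)
}

#' Per-pixel bleed-through correction by residualization
#'
#' Replaces each pixel's time series in each channel by the residual of an
#' ordinary least-squares fit of that series on the other channel's series at
#' the same pixel. Residuals are exactly orthogonal to the regressor; pixels
#' whose regressor has zero variance keep their centered original series.
#'
#' @param movie a `two_channel_movie`
#' @return the movie with both channels replaced by residual series
#'   (zero-mean per pixel)
#' @export
bleedthrough_correct <- function(movie) {
  stopifnot(inherits(movie, "two_channel_movie"))
  p <- ncol(movie$green)
  chunk <- max(1L, min(p, floor(5e6 / nrow(movie$green))))
  for (j0 in seq(1L, p, by = chunk)) {
    idx <- j0:min(p, j0 + chunk - 1L)
    g <- sweep(movie$green[, idx, drop = FALSE], 2L,
               colMeans(movie$green[, idx, drop = FALSE]))
    r <- sweep(movie$red[, idx, drop = FALSE], 2L,
               colMeans(movie$red[, idx, drop = FALSE]))
    vg <- colMeans(g^2); vr <- colMeans(r^2)
    cgr <- colMeans(g * r)
    movie$green[, idx] <- g - sweep(r, 2L, ifelse(vr > 1e-14, cgr / vr, 0), "*")
    movie$red[, idx] <- r - sweep(g, 2L, ifelse(vg > 1e-14, cgr / vg, 0), "*")
  }
  movie
}

#' Detrend, smooth and z-score a trace
#'
#' The standardization applied to every trace before modeling: linear
#' detrend, temporal Gaussian smoothing with standard deviation `kernel_s`
#' seconds, then z-scoring over time (in that order).
#'
#' @param trace numeric vector
#' @param frame_hz sampling rate, Hz
#' @param kernel_s smoothing kernel SD in seconds
#' @return standardized trace (mean 0, SD 1)
#' @export
standardize <- function(trace, frame_hz, kernel_s = 1) {
  stopifnot(all(is.finite(trace)))
  if (length(trace) <= max(3, kernel_s * frame_hz))
    stop("standardize: trace shorter than the smoothing kernel")
  x <- detrend_linear(trace)
  x <- smooth_time(x, kernel_s * frame_hz)
  if (stats::sd(x) < 1e-12)
    stop("standardize: zero variance after detrending")
  zscore_cols(x)
}

#' Extract the standardized trace set
#'
#' Per cell: the soma-mean red (calcium) trace, the annulus-mean green
#' (local NE) trace, the global-mask-mean green trace, and the mean of all
#' other cells' soma red traces (population calcium). Raw pixels are averaged
#' first; each field trace is then standardized with [standardize()].
#'
#' @param movie a `two_channel_movie` (registered and bleed-through corrected)
#' @param geometry a `field_geometry`
#' @param kernel_s smoothing kernel SD passed to [standardize()]
#' @return object of class `trace_set`: matrices `cell_ca`, `local_ne`,
#'   `global_ne`, `pop_ca` (cells x T), plus `frame_hz` and the geometry
#' @export
extract_traces <- function(movie, geometry, kernel_s = 1) {
  stopifnot(inherits(geometry, "field_geometry"))
  if (geometry$h != movie$h || geometry$w != movie$w)
    stop("extract_traces: geometry does not match movie dimensions")
  n <- length(geometry$soma_px)
  if (n < 2L) stop("extract_traces: need at least 2 cells (population trace)")
  tn <- nrow(movie$green)
  raw_ca <- t(vapply(geometry$soma_px, function(px)
    rowMeans(movie$red[, px, drop = FALSE]), numeric(tn)))
  local_ne <- t(vapply(geometry$local_px, function(px)
    rowMeans(movie$green[, px, drop = FALSE]), numeric(tn)))
  # global mean via complement sums (avoids copying ~the whole movie per cell)
  green_total <- rowSums(movie$green)
  p_all <- geometry$h * geometry$w
  global_ne <- t(vapply(seq_len(n), function(i) {
    excl <- c(geometry$soma_px[[i]], geometry$local_px[[i]])
    (green_total - rowSums(movie$green[, excl, drop = FALSE])) /
      (p_all - length(excl))
  }, numeric(tn)))
  pop_ca <- matrix(NA_real_, n, tn)
  for (i in seq_len(n)) {
    pop_ca[i, ] <- colMeans(raw_ca[-i, , drop = FALSE])
  }
  std <- function(m) t(apply(m, 1L, standardize, frame_hz = movie$frame_hz,
                             kernel_s = kernel_s))
  structure(list(cell_ca = std(raw_ca), local_ne = std(local_ne),
                 global_ne = std(global_ne), pop_ca = std(pop_ca),
                 raw_cell_ca = raw_ca, raw_local_ne = local_ne,
                 frame_hz = movie$frame_hz, geometry = geometry,
                 kernel_s = kernel_s),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d cells x %d frames @ %.2f Hz\n",
              nrow(x$cell_ca), ncol(x$cell_ca), x$frame_hz))
  invisible(x)
}
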
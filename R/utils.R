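# Shared numeric helpers: movies are stored as T x P matrices (P = h*w pixels,
# column-major pixel index = (x-1)*h + y) so that every temporal operation is a
# column operation and every spatial operation is a reshape + BLAS multiply.

#' Pixel index helpers
#' @param h,w frame height and width in pixels
#' @param x,y column (x) and row (y) coordinates, 1-based
#' @return linear pixel index into a T x P movie matrix
#' @keywords internal
pixel_index <- function(y, x, h) (x - 1L) * h + y

#' Discrete Gaussian kernel
#'
#' Truncated at 4 sigma and renormalized to sum 1.
#' @param sigma standard deviation in samples; 0 returns a unit impulse
#' @keywords internal
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

#' Band matrix implementing renormalized Gaussian smoothing along one axis
#'
#' Row i of the returned n x n matrix holds the Gaussian weights for output
#' sample i; rows are renormalized near the edges so a constant input maps to
#' itself exactly.
#' @keywords internal
gaussian_band_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  idx <- seq_len(n)
  K <- stats::dnorm(outer(idx, idx, "-"), sd = sigma)
  K[abs(outer(idx, idx, "-")) > r] <- 0
  K / rowSums(K)
}

#' Gaussian smoothing along the time axis of a T x P matrix
#'
#' Edge effects are removed by renormalizing with the smoothed indicator, so a
#' constant series is preserved exactly. Uses FFT convolution, chunked over
#' columns to bound memory.
#' @param X numeric matrix (time in rows) or vector
#' @param sigma kernel standard deviation in frames
#' @keywords internal
smooth_time <- function(X, sigma) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, ncol = 1L)
  if (sigma <= 0) return(if (vec) X[, 1L] else X)
  tn <- nrow(X)
  if (tn <= 3000L && ncol(X) > 64L) {
    # one BLAS multiply beats chunked FFTs at these sizes
    out <- gaussian_band_matrix(tn, sigma) %*% X
    return(if (vec) out[, 1L] else out)
  }
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  L <- stats::nextn(tn + 2L * r, c(2, 3, 5))
  Kf <- stats::fft(c(k, rep(0, L - length(k))))
  w <- Re(stats::fft(stats::fft(c(rep(1, tn), rep(0, L - tn))) * Kf, inverse = TRUE)) / L
  w <- w[(r + 1L):(r + tn)]
  out <- X
  chunk <- max(1L, floor(4e6 / L))
  for (j0 in seq(1L, ncol(X), by = chunk)) {
    j1 <- min(ncol(X), j0 + chunk - 1L)
    pad <- rbind(X[, j0:j1, drop = FALSE], matrix(0, L - tn, j1 - j0 + 1L))
    sm <- Re(stats::mvfft(stats::mvfft(pad) * Kf, inverse = TRUE)) / L
    out[, j0:j1] <- sm[(r + 1L):(r + tn), , drop = FALSE] / w
  }
  if (vec) out[, 1L] else out
}

#' Remove a per-column linear trend
#' @param X numeric matrix (time in rows) or vector
#' @return matrix/vector of residuals around the fitted line
#' @keywords internal
detrend_linear <- function(X) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, ncol = 1L)
  tn <- nrow(X)
  tc <- seq_len(tn) - (tn + 1) / 2
  ss <- sum(tc^2)
  beta <- crossprod(tc, X) / ss          # 1 x P slopes
  mu <- colMeans(X)
  out <- X - outer(tc, drop(beta)) - rep(mu, each = tn)
  if (vec) out[, 1L] else out
}

#' Column z-scores
#' @param X matrix (time in rows) or vector
#' @param na_zero_var if TRUE, zero-variance columns become all-NA instead of
#'   an error (used per-pixel where dead pixels are expected)
#' @keywords internal
zscore_cols <- function(X, na_zero_var = FALSE) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, ncol = 1L)
  mu <- colMeans(X)
  sd <- sqrt(colMeans(X^2) - mu^2) * sqrt(nrow(X) / (nrow(X) - 1))
  bad <- !is.finite(sd) | sd < 1e-12
  if (any(bad) && !na_zero_var) stop("zscore_cols: zero-variance column")
  sd[bad] <- NA_real_
  out <- sweep(sweep(X, 2L, mu), 2L, sd, "/")
  if (vec) out[, 1L] else out
}

#' Separable Gaussian blur of every frame of a T x P movie matrix
#'
#' One BLAS multiply per image axis across all frames at once; edge rows are
#' renormalized (constant frames are preserved exactly).
#' @param X T x P matrix, P = h*w
#' @param h,w frame dimensions
#' @param sigma_px blur standard deviation in pixels
#' @keywords internal
blur_frames <- function(X, h, w, sigma_px) {
  if (sigma_px <= 0) return(X)
  tn <- nrow(X)
  Kh <- gaussian_band_matrix(h, sigma_px)
  Kw <- gaussian_band_matrix(w, sigma_px)
  A <- array(t(X), c(h, w, tn))
  dim(A) <- c(h, w * tn)
  A <- Kh %*% A
  dim(A) <- c(h, w, tn)
  A <- aperm(A, c(2L, 1L, 3L))
  dim(A) <- c(w, h * tn)
  A <- Kw %*% A
  dim(A) <- c(w, h, tn)
  A <- aperm(A, c(2L, 1L, 3L))
  dim(A) <- c(h * w, tn)
  t(A)
}

#' Shift one frame by (dy, dx) with bilinear interpolation
#'
#' Positive dy/dx move content down/right; out-of-range samples replicate the
#' nearest edge. Integer shifts are exact.
#' @param frame h x w matrix
#' @keywords internal
shift_frame <- function(frame, dy, dx) {
  h <- nrow(frame); w <- ncol(frame)
  ys <- seq_len(h) - dy
  xs <- seq_len(w) - dx
  y0 <- pmin(pmax(floor(ys), 1L), h); y1 <- pmin(y0 + 1L, h)
  x0 <- pmin(pmax(floor(xs), 1L), w); x1 <- pmin(x0 + 1L, w)
  fy <- pmin(pmax(ys - y0, 0), 1)
  fx <- pmin(pmax(xs - x0, 0), 1)
  a <- frame[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
       frame[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
       frame[y0, x1, drop = FALSE] * outer(1 - fy, fx) +
       frame[y1, x1, drop = FALSE] * outer(fy, fx)
  a
}

#' Ornstein-Uhlenbeck sample path
#'
#' Stationary unit-variance OU process, scaled by `amp`.
#' @param n length in samples
#' @param tau_s correlation time in seconds
#' @param dt_s sample interval in seconds
#' @param amp stationary standard deviation
#' @keywords internal
ou_process <- function(n, tau_s, dt_s, amp = 1) {
  a <- exp(-dt_s / tau_s)
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  innov <- stats::rnorm(n - 1L, sd = sqrt(1 - a^2))
  for (t in 2:n) x[t] <- a * x[t - 1L] + innov[t - 1L]
  amp * x
}

#' Disk and annulus pixel masks
#' @param h,w frame size; `cy`,`cx` center (pixels, may be fractional)
#' @param r_out outer radius in pixels; `r_in` inner radius (exclusive), 0 for
#'   a full disk
#' @return logical h x w matrix
#' @keywords internal
disk_mask <- function(h, w, cy, cx, r_out, r_in = 0) {
  d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+")
  d2 <= r_out^2 & d2 > r_in^2
}

#' Gaussian image evaluated on the pixel grid
#' @return h x w matrix with value 1 at the center
#' @keywords internal
gaussian_image <- function(h, w, cy, cx, sigma_px) {
  exp(-outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+") / (2 * sigma_px^2))
}

#' Pearson correlation tolerant of NA frames
#' @keywords internal
cor_complete <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  stats::cor(x[ok], y[ok])
}
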
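# NE synchrony: sliding local:global correlation, regime segmentation, and
# synchrony-vs-distance profiles.

#' Sliding-window Pearson correlation
#'
#' Pearson r between `x` and `y` inside a centered window at every frame
#' where the full window fits; edge frames are NA. Computed with running
#' sums, O(T). Windows in which either series has (numerically) zero
#' variance yield NA.
#'
#' @param x,y numeric vectors of equal length
#' @param frame_hz sampling rate, Hz
#' @param window_s window length in seconds
#' @return numeric vector of sliding r values (NA at undefined frames)
#' @export
sliding_correlation <- function(x, y, frame_hz, window_s = 30) {
  stopifnot(length(x) == length(y))
  tn <- length(x)
  win <- round(window_s * frame_hz)
  if (win < 3L) stop("sliding_correlation: window shorter than 3 frames")
  if (tn < win) stop("sliding_correlation: series shorter than the window")
  run <- function(v) {
    cs <- cumsum(c(0, v))
    cs[(win + 1L):(tn + 1L)] - cs[seq_len(tn - win + 1L)]
  }
  sx <- run(x); sy <- run(y)
  sxx <- run(x^2); syy <- run(y^2); sxy <- run(x * y)
  num <- sxy - sx * sy / win
  vx <- sxx - sx^2 / win
  vy <- syy - sy^2 / win
  den <- sqrt(pmax(vx, 0) * pmax(vy, 0))
  r <- ifelse(vx < win * 1e-12 | vy < win * 1e-12, NA_real_, num / den)
  r <- pmin(1, pmax(-1, r))
  out <- rep(NA_real_, tn)
  # center of window [i, i+win-1] is at i + floor((win-1)/2)
  out[seq_len(tn - win + 1L) + (win - 1L) %/% 2L] <- r
  out
}

#' Segment high/low NE-synchrony regimes
#'
#' Averages the per-cell synchrony traces framewise, then labels frames where
#' the average trace falls strictly below its own temporal mean as the low
#' regime and the remaining defined frames as the high regime. Contiguous low
#' runs are reported in seconds.
#'
#' @param synchrony matrix (cells x T) of sliding-correlation traces, or a
#'   single trace
#' @param frame_hz sampling rate, Hz
#' @return list `average` (trace), `high`, `low` (logical masks over frames;
#'   NA-frame entries are FALSE in both), `low_period_s` (run lengths)
#' @export
segment_regimes <- function(synchrony, frame_hz) {
  if (is.null(dim(synchrony))) synchrony <- matrix(synchrony, nrow = 1L)
  avg <- colMeans(synchrony)
  defined <- !is.na(avg)
  mu <- mean(avg[defined])
  low <- defined & avg < mu
  high <- defined & !low
  runs <- rle(as.integer(low))
  low_period_s <- runs$lengths[runs$values == 1L] / frame_hz
  list(average = avg, high = high, low = low, low_period_s = low_period_s)
}

#' Synchrony-trace correlation versus distance
#'
#' Pearson correlation between every pair of cells' synchrony traces
#' (NA frames excluded pairwise) against the distance between cell centers.
#'
#' @param synchrony matrix (cells x T) of synchrony traces
#' @param centers data.frame with `x_px`, `y_px`
#' @param px_um microns per pixel
#' @return data.frame `cell_i`, `cell_j`, `distance_um`, `r`
#' @export
synchrony_distance_profile <- function(synchrony, centers, px_um) {
  n <- nrow(synchrony)
  if (n < 3L) stop("synchrony_distance_profile: need >= 3 cells")
  stopifnot(nrow(centers) == n)
  out <- list(); k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k + 1L
      d <- sqrt((centers$x_px[i] - centers$x_px[j])^2 +
                (centers$y_px[i] - centers$y_px[j])^2) * px_um
      out[[k]] <- data.frame(cell_i = i, cell_j = j, distance_um = d,
                             r = cor_complete(synchrony[i, ], synchrony[j, ]))
    }
  }
  do.call(rbind, out)
}
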
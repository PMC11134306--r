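# Spatial structure of the NE channel: grid autocorrelation with a
# double-exponential distance model, and field-correlation distributions.

#' Grid spatial autocorrelation of the NE field
#'
#' Tiles the field of view into square patches, averages the NE signal within
#' each patch, computes all pairwise Pearson correlations between patch
#' traces, and bins them by center-to-center distance (rounded to 1 um).
#'
#' @param ne_movie an `ne_movie` (single channel); traces may be standardized
#'   first via `standardize_patches`
#' @param patch_um patch side length, microns
#' @param standardize_patches detrend/smooth/z-score each patch trace before
#'   correlating (mirrors the modeling standardization); recorded in the
#'   output
#' @return object of class `autocorr_profile`: data.frame `profile`
#'   (`distance_um`, `r`, `n_pairs`), patch size, and the call options
#' @export
grid_autocorrelation <- function(ne_movie, patch_um = 10,
                                 standardize_patches = TRUE) {
  h <- ne_movie$h; w <- ne_movie$w
  patch_px <- max(2L, round(patch_um / ne_movie$px_um))
  if (patch_px < 2L) stop("grid_autocorrelation: patch smaller than 2x2 px")
  ny <- h %/% patch_px; nx <- w %/% patch_px
  if (ny * nx < 2L) stop("grid_autocorrelation: fewer than 2 patches")
  # patch membership matrix: P x K, column-normalized
  pidx_y <- pmin(ny, ((seq_len(h) - 1L) %/% patch_px) + 1L)
  pidx_x <- pmin(nx, ((seq_len(w) - 1L) %/% patch_px) + 1L)
  keep_y <- seq_len(ny * patch_px); keep_x <- seq_len(nx * patch_px)
  px_patch <- outer(ifelse(seq_len(h) %in% keep_y, pidx_y, NA),
                    (pidx_x - 1L) * ny, "+")
  px_patch[, !(seq_len(w) %in% keep_x)] <- NA
  pv <- as.vector(px_patch)
  ok <- !is.na(pv)
  k <- ny * nx
  traces <- t(rowsum(t(ne_movie$data[, ok, drop = FALSE]), pv[ok]))
  counts <- tabulate(pv[ok], nbins = k)
  traces <- sweep(traces, 2L, counts, "/")
  if (standardize_patches) {
    traces <- apply(traces, 2L, standardize, frame_hz = ne_movie$frame_hz)
  }
  cy <- ((seq_len(k) - 1L) %% ny + 0.5) * patch_px * ne_movie$px_um
  cx <- ((seq_len(k) - 1L) %/% ny + 0.5) * patch_px * ne_movie$px_um
  cm <- stats::cor(traces)
  d <- sqrt(outer(cy, cy, "-")^2 + outer(cx, cx, "-")^2)
  iu <- which(upper.tri(d, diag = TRUE))
  db <- round(d[iu])
  rr <- cm[iu]
  agg <- tapply(rr, db, mean)
  npairs <- tapply(rr, db, length)
  profile <- data.frame(distance_um = as.numeric(names(agg)),
                        r = as.numeric(agg),
                        n_pairs = as.integer(npairs))
  profile <- profile[order(profile$distance_um), ]
  rownames(profile) <- NULL
  structure(list(profile = profile, patch_um = patch_um,
                 patch_px = patch_px,
                 standardized = standardize_patches),
            class = "autocorr_profile")
}

#' Fit a double-exponential distance model to an autocorrelation profile
#'
#' Least-squares fit of `r(d) = a1*exp(-d/lambda1) + a2*exp(-d/lambda2)` with
#' multi-start initialization; by convention `lambda1 <= lambda2`.
#'
#' @param profile an `autocorr_profile` or a data.frame with `distance_um`
#'   and `r`
#' @param weights optional per-bin weights (defaults to `n_pairs` if present)
#' @return list `a1`, `lambda1`, `a2`, `lambda2`, `rss`, `degenerate`
#'   (TRUE when the two scales collapse or one amplitude vanishes)
#' @export
fit_double_exponential <- function(profile, weights = NULL) {
  df <- if (inherits(profile, "autocorr_profile")) profile$profile else profile
  stopifnot(all(c("distance_um", "r") %in% names(df)))
  df <- df[is.finite(df$r), ]
  if (nrow(df) < 6L)
    stop("fit_double_exponential: need at least 6 distance bins")
  if (is.null(weights)) {
    weights <- if ("n_pairs" %in% names(df)) df$n_pairs else rep(1, nrow(df))
  }
  dmax <- max(df$distance_um[df$distance_um > 0])
  if (stats::sd(df$r) < 1e-12) {
    return(list(a1 = df$r[1] / 2, lambda1 = dmax, a2 = df$r[1] / 2,
                lambda2 = dmax, rss = 0, degenerate = TRUE))
  }
  starts <- expand.grid(l1 = dmax * c(0.05, 0.15, 0.4),
                        l2 = dmax * c(0.5, 1, 3))
  best <- NULL
  best_rss <- Inf
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ a1 * exp(-distance_um / l1) + a2 * exp(-distance_um / l2),
        data = df, weights = weights,
        start = list(a1 = max(df$r) * 0.6, l1 = starts$l1[s],
                     a2 = max(df$r) * 0.4, l2 = starts$l2[s]),
        lower = c(-2, 1e-3, -2, 1e-3), upper = c(2, 1e5, 2, 1e5),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best_rss) { best_rss <- rss; best <- fit }
  }
  if (is.null(best))
    stop("fit_double_exponential: no start converged (best rss = Inf)")
  cf <- stats::coef(best)
  if (cf[["l1"]] > cf[["l2"]]) cf <- cf[c("a2", "l2", "a1", "l1")]
  out <- list(a1 = unname(cf[[1]]), lambda1 = unname(cf[[2]]),
              a2 = unname(cf[[3]]), lambda2 = unname(cf[[4]]),
              rss = best_rss)
  out$degenerate <- with(out, abs(lambda1 / lambda2 - 1) < 0.05 ||
                           abs(a1) < 1e-3 || abs(a2) < 1e-3)
  out
}

#' Plume length scale implied by an autocorrelation profile
#'
#' For an isotropic Gaussian plume of spatial scale sigma, patch-trace
#' correlations decay as `exp(-d^2 / (4 sigma^2))`, whose 1/e distance is
#' `2 sigma`; over a sampled distance range an exponential approximating that
#' decay has its own 1/e scale at about `2 sigma` as well. The slow component
#' of the double-exponential fit absorbs the shared long-range floor (drive
#' plus summed far-field plume mass), so the estimator is half the fast
#' component's length scale, `lambda1 / 2`.
#'
#' @param fit result of [fit_double_exponential()]
#' @return estimated plume sigma in microns
#' @export
estimate_plume_scale <- function(fit) {
  min(fit$lambda1, fit$lambda2) / 2
}

#' Local-local and local-global correlation distributions
#'
#' All pairwise Pearson correlations between local NE traces, the per-cell
#' correlation between each local trace and its global trace, and a
#' two-sample Kolmogorov-Smirnov comparison of the two samples.
#'
#' @param traceset a `trace_set`
#' @return list `local_local` (vector), `local_global` (vector),
#'   `ks_statistic`, `p_value`, `mean_local_local`, `mean_local_global`
#' @export
field_correlation_distributions <- function(traceset) {
  l <- traceset$local_ne
  g <- traceset$global_ne
  n <- nrow(l)
  if (n < 2L) stop("field_correlation_distributions: need >= 2 cells")
  keep <- apply(l, 1L, stats::sd) > 1e-12
  if (!all(keep)) message("field_correlation_distributions: skipped ",
                          sum(!keep), " constant trace(s)")
  cm <- stats::cor(t(l[keep, , drop = FALSE]))
  ll <- cm[upper.tri(cm)]
  lg <- vapply(which(keep), function(i) stats::cor(l[i, ], g[i, ]), numeric(1))
  ks <- suppressWarnings(stats::ks.test(ll, lg))
  list(local_local = ll, local_global = lg,
       ks_statistic = unname(ks$statistic), p_value = ks$p.value,
       mean_local_local = mean(ll), mean_local_global = mean(lg))
}
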
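# Per-cell regression models of calcium on NE fields, synchrony-regime
# splits, the local-radius sweep, population-level tests, and the
# mixed-effects drug comparison.

#' Per-cell GLM of calcium on NE fields
#'
#' Ordinary least squares (Gaussian identity link; "GLM" in the encoding-model
#' sense) of one cell's standardized calcium trace on four forced-entry
#' predictors: local NE, global NE, population calcium, and the local x
#' global NE product (product of the standardized traces).
#'
#' @param traceset a `trace_set`
#' @param cell cell index
#' @param frame_mask logical vector selecting the frames to fit (default all)
#' @return object of class `cell_model_fit`: data.frame `coefficients`
#'   (`term`, `beta`, `se`, `t`, `p`), plus `cell`, `n_frames`, `regime`
#' @export
fit_cell_glm <- function(traceset, cell, frame_mask = NULL) {
  tn <- ncol(traceset$cell_ca)
  if (is.null(frame_mask)) frame_mask <- rep(TRUE, tn)
  stopifnot(length(frame_mask) == tn)
  if (sum(frame_mask) < 40L)
    stop("fit_cell_glm: frame mask selects fewer than 40 frames")
  y <- traceset$cell_ca[cell, frame_mask]
  X <- cbind(local_ne = traceset$local_ne[cell, frame_mask],
             global_ne = traceset$global_ne[cell, frame_mask],
             global_ca = traceset$pop_ca[cell, frame_mask])
  X <- cbind(X, local_x_global = X[, 1L] * X[, 2L])
  cc <- stats::cor(X)
  collinear <- which(abs(cc) > 1 - 1e-6 & upper.tri(cc), arr.ind = TRUE)
  if (nrow(collinear)) {
    stop("fit_cell_glm: predictors `", colnames(X)[collinear[1, 1]],
         "` and `", colnames(X)[collinear[1, 2]], "` are collinear")
  }
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)$coefficients
  co <- data.frame(term = colnames(X),
                   beta = sm[-1L, 1L], se = sm[-1L, 2L],
                   t = sm[-1L, 3L], p = sm[-1L, 4L], row.names = NULL)
  structure(list(coefficients = co, cell = cell, n_frames = sum(frame_mask),
                 regime = attr(frame_mask, "regime") %||% "all"),
            class = "cell_model_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit every cell over all / high-synchrony / low-synchrony frames
#'
#' Computes each cell's NE-synchrony trace (sliding local:global correlation),
#' segments high/low regimes from the cell-average trace, and fits the
#' per-cell GLM on all frames and within each regime. A regime with fewer
#' than 40 frames is reported as missing.
#'
#' @param traceset a `trace_set`
#' @param window_s synchrony window, seconds
#' @return list `fits` (data.frame: one row per cell x regime x term),
#'   `synchrony` (cells x T matrix), `regimes` (from [segment_regimes()])
#' @export
regime_split_fits <- function(traceset, window_s = 30) {
  n <- nrow(traceset$cell_ca)
  tn <- ncol(traceset$cell_ca)
  syn <- matrix(NA_real_, n, tn)
  for (i in seq_len(n)) {
    syn[i, ] <- sliding_correlation(traceset$local_ne[i, ],
                                    traceset$global_ne[i, ],
                                    traceset$frame_hz, window_s)
  }
  reg <- segment_regimes(syn, traceset$frame_hz)
  masks <- list(all = rep(TRUE, tn), high = reg$high, low = reg$low)
  rows <- list()
  for (i in seq_len(n)) {
    for (m in names(masks)) {
      mask <- masks[[m]]
      if (sum(mask) < 40L) {
        message("regime_split_fits: regime `", m, "` too short for cell ",
                i, "; fit marked missing")
        next
      }
      attr(mask, "regime") <- m
      f <- fit_cell_glm(traceset, i, mask)
      rows[[length(rows) + 1L]] <- cbind(cell = i, regime = m,
                                         f$coefficients)
    }
  }
  list(fits = do.call(rbind, rows), synchrony = syn, regimes = reg)
}

#' Local-NE coupling as a function of annulus radius
#'
#' Rebuilds the local annulus (and correspondingly shrunken global field) at
#' each radius, re-extracts the NE traces, refits the per-cell GLM, and
#' summarizes the population mean local-NE coefficient per radius.
#'
#' @param movie a preprocessed `two_channel_movie`
#' @param soma_labels label image of somata
#' @param radii_um increasing vector of outer annulus radii
#' @param frame_mask optional logical frame mask applied to every fit
#' @param kernel_s standardization kernel, seconds
#' @return list `by_radius` (data.frame `radius_um`, `mean_beta_local`,
#'   `se`, `n_cells`), `per_cell` (data.frame with per-cell betas)
#' @export
radius_sweep <- function(movie, soma_labels, radii_um = seq(5, 100, by = 5),
                         frame_mask = NULL, kernel_s = 1) {
  stopifnot(!is.unsorted(radii_um))
  soma_r_px <- sqrt(max(table(soma_labels[soma_labels > 0])) / pi)
  per_cell <- list(); by_radius <- list()
  for (r in radii_um) {
    if (r / movie$px_um <= soma_r_px + 1) {
      message("radius_sweep: radius ", r, " um smaller than the soma; skipped")
      next
    }
    geom <- build_fields(soma_labels, radius_um = r, px_um = movie$px_um)
    ts <- extract_traces(movie, geom, kernel_s)
    betas <- vapply(seq_len(nrow(ts$cell_ca)), function(i) {
      f <- fit_cell_glm(ts, i, frame_mask)
      f$coefficients$beta[f$coefficients$term == "local_ne"]
    }, numeric(1))
    per_cell[[length(per_cell) + 1L]] <-
      data.frame(radius_um = r, cell = seq_along(betas), beta_local = betas)
    by_radius[[length(by_radius) + 1L]] <-
      data.frame(radius_um = r, mean_beta_local = mean(betas),
                 se = stats::sd(betas) / sqrt(length(betas)),
                 n_cells = length(betas))
  }
  list(by_radius = do.call(rbind, by_radius),
       per_cell = do.call(rbind, per_cell))
}

#' Population-level tests on per-cell coefficients
#'
#' One-sample t test of a coefficient's cell-level values against zero, or a
#' pooled two-sample t test across conditions.
#'
#' @param x numeric vector of per-cell coefficients (group 1)
#' @param y optional second group; when given a two-sample pooled-variance
#'   test is run
#' @return list `mean`, `se`, `t`, `df`, `p` (plus `mean_y` for two-sample)
#' @export
population_tests <- function(x, y = NULL) {
  if (length(x) < 3L) stop("population_tests: need >= 3 values per group")
  if (stats::sd(x) < 1e-12 && is.null(y))
    stop("population_tests: zero variance")
  if (is.null(y)) {
    tt <- stats::t.test(x)
    list(mean = mean(x), se = stats::sd(x) / sqrt(length(x)),
         t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  } else {
    if (length(y) < 3L) stop("population_tests: need >= 3 values per group")
    tt <- stats::t.test(x, y, var.equal = TRUE)
    list(mean = mean(x), mean_y = mean(y),
         se = sqrt(stats::var(x) / length(x) + stats::var(y) / length(y)),
         t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  }
}

#' Mixed-effects comparison of correlations between drug conditions
#'
#' Linear mixed model `correlation ~ drug + (drug || mouse) + (drug ||
#' cell_id)` (fixed drug effect; uncorrelated random intercept and slope for
#' mouse and for cell), fitted by REML with Satterthwaite degrees of freedom
#' for the fixed effect. With a single mouse the mouse term is dropped with a
#' warning.
#'
#' @param tab data.frame with columns `correlation`, `drug` (factor, the
#'   non-reference level is the tested effect), `mouse`, `cell_id`
#' @return list `estimate`, `se`, `t`, `df`, `p`, `ranef_variances`, `model`
#' @export
lme_condition_compare <- function(tab) {
  stopifnot(all(c("correlation", "drug", "mouse", "cell_id") %in% names(tab)))
  tab$drug <- as.factor(tab$drug)
  if (nlevels(tab$drug) < 2L)
    stop("lme_condition_compare: need two drug conditions")
  single_mouse <- length(unique(tab$mouse)) < 2L
  form <- if (single_mouse) {
    warning("lme_condition_compare: single mouse; dropping mouse random effect")
    correlation ~ drug + (drug || cell_id)
  } else {
    correlation ~ drug + (drug || mouse) + (drug || cell_id)
  }
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(form, data = tab, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
  sm <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(estimate = sm[2L, "Estimate"], se = sm[2L, "Std. Error"],
       t = sm[2L, "t value"], df = sm[2L, "df"], p = sm[2L, "Pr(>|t|)"],
       ranef_variances = vc[, c("grp", "var1", "vcov")],
       model = fit)
}
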
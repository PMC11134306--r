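# Per-cell GLMs, population tests, mixed-effects drug comparison.

make_traceset <- function(n, tn, fhz = 15, make_y = NULL, seed = 1) {
  set.seed(seed)
  z <- function(m) t(apply(m, 1, function(x) (x - mean(x)) / sd(x)))
  local_ne <- z(matrix(rnorm(n * tn), n))
  global_ne <- z(matrix(rnorm(n * tn), n))
  pop_ca <- z(matrix(rnorm(n * tn), n))
  cell_ca <- if (is.null(make_y)) z(matrix(rnorm(n * tn), n)) else
    z(make_y(local_ne, global_ne, pop_ca))
  structure(list(cell_ca = cell_ca, local_ne = local_ne,
                 global_ne = global_ne, pop_ca = pop_ca, frame_hz = fhz),
            class = "trace_set")
}

test_that("noiseless linear combinations are recovered exactly", {
  ts <- make_traceset(2, 500, make_y = function(l, g, p)
    0.3 * l + 0.1 * g + 0.5 * p)
  f <- fit_cell_glm(ts, 1)
  expect_equal(f$coefficients$beta,
               c(0.3, 0.1, 0.5, 0) / sd(0.3 * ts$local_ne[1, ] +
                                          0.1 * ts$global_ne[1, ] +
                                          0.5 * ts$pop_ca[1, ]),
               tolerance = 1e-10)
  # residual orthogonality to every predictor (noisy response, so the
  # residual is not numerically zero)
  set.seed(12)
  X <- cbind(ts$local_ne[1, ], ts$global_ne[1, ], ts$pop_ca[1, ],
             ts$local_ne[1, ] * ts$global_ne[1, ])
  y <- 0.3 * X[, 1] + rnorm(nrow(X))
  res <- residuals(lm(y ~ X))
  for (j in 1:4) expect_lt(abs(cor(res, X[, j])), 1e-10)
})

test_that("null responses give |beta| < 3 SE nearly always", {
  bad <- 0
  for (s in 1:20) {
    ts <- make_traceset(1, 9000, seed = 100 + s)
    f <- fit_cell_glm(ts, 1)
    bad <- bad + sum(abs(f$coefficients$beta) > 3 * f$coefficients$se)
  }
  expect_lte(bad, 2)  # ~0.3% expected exceedance rate over 80 draws
})

test_that("collinear predictors raise an informative error", {
  ts <- make_traceset(1, 300)
  ts$global_ne <- ts$local_ne
  expect_error(fit_cell_glm(ts, 1), "collinear")
})

test_that("scale invariance: rescaling a raw trace leaves beta unchanged", {
  set.seed(3)
  x <- cumsum(rnorm(600))
  fhz <- 15
  a <- standardize(x, fhz)
  b <- standardize(100 + 7 * x, fhz)
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("population tests match the analytic t expectation", {
  set.seed(8)
  b <- rnorm(326, mean = 0.1, sd = 0.1)
  pt <- population_tests(b)
  expect_equal(pt$df, 325)
  expect_equal(pt$t, 0.1 / (0.1 / sqrt(326)), tolerance = 0.25 * 18)
  expect_gt(pt$t, 10)
  # identical groups: two-sample t ~ 0
  pt2 <- population_tests(b, b)
  expect_equal(pt2$t, 0, tolerance = 1e-10)
  expect_equal(pt2$df, 2 * 326 - 2)
  # zero variance flagged
  expect_error(population_tests(rep(0.2, 10)), "zero variance")
})

test_that("LME recovers a deterministic shift exactly and a planted effect", {
  tab <- simulate_correlation_table(n_mice = 3, cells_per_mouse = 20,
                                    obs_per_cell = 4, drug_effect = 0.1,
                                    mouse_sd = 0, cell_sd = 0, resid_sd = 0,
                                    seed = 2)
  fit <- lme_condition_compare(tab)
  expect_equal(fit$estimate, 0.1, tolerance = 1e-6)

  tab2 <- simulate_correlation_table(n_mice = 3, cells_per_mouse = 110,
                                     obs_per_cell = 13, drug_effect = 0.10,
                                     mouse_sd = 0.05, cell_sd = 0.05,
                                     resid_sd = 0.2, seed = 7)
  expect_gte(nrow(tab2), 8000)
  fit2 <- lme_condition_compare(tab2)
  expect_lt(abs(fit2$estimate - 0.10), 0.03)
  expect_true(all(fit2$ranef_variances$vcov >= 0))
})

test_that("LME null calibration: no effect rarely significant", {
  sig <- 0
  n_rep <- 20
  for (s in seq_len(n_rep)) {
    tab <- simulate_correlation_table(n_mice = 3, cells_per_mouse = 30,
                                      obs_per_cell = 6, drug_effect = 0,
                                      mouse_sd = 0.05, cell_sd = 0.05,
                                      resid_sd = 0.2, seed = 300 + s)
    fit <- lme_condition_compare(tab)
    sig <- sig + (fit$p < 0.05)
  }
  expect_gte(mean(sig <= 0.1 * n_rep), 1)  # at most 2/20 significant
})

test_that("single-mouse tables fall back to cell-only random effects", {
  tab <- simulate_correlation_table(n_mice = 1, cells_per_mouse = 30,
                                    obs_per_cell = 6, drug_effect = 0.1,
                                    seed = 5)
  expect_warning(fit <- lme_condition_compare(tab), "single mouse")
  expect_true(is.finite(fit$estimate))
})
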
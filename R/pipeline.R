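# End-to-end orchestration: simulate (optional) -> preprocess -> spatial ->
# synchrony -> flow -> models, with a reproducibility manifest. The numbered
# scripts under analysis/ are thin drivers over this and the module
# functions.

#' Run the full pipeline on a synthetic or user-supplied movie
#'
#' Executes every stage and writes CSV/JSON outputs plus a manifest (seed,
#' knob values, package version) to `out_dir`. Stages read each other's
#' in-memory results; on failure the pipeline stops naming the stage, keeping
#' the outputs already written.
#'
#' @param config a [sim_config()] for synthetic input, or NULL when `movie`
#'   and `soma_labels` are supplied
#' @param out_dir output directory (created if missing)
#' @param movie optional user `two_channel_movie` (already binned)
#' @param soma_labels optional label image for user data
#' @param radius_um annulus radius for field geometry
#' @param window_s synchrony window
#' @param sigma_px,kernel_s flow preprocessing knobs
#' @param alpha,z_thresh Horn-Schunck smoothness and event z threshold
#' @param run_noise_control number of null datasets (0 = skip)
#' @return invisible list with all stage results
#' @export
run_pipeline <- function(config = NULL, out_dir, movie = NULL,
                         soma_labels = NULL, radius_um = 15, window_s = 30,
                         sigma_px = 12, kernel_s = 5, alpha = 1,
                         z_thresh = 1, run_noise_control = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL
  if (is.null(movie)) {
    if (is.null(config)) stop("run_pipeline: need `config` or `movie`")
    sim <- stage("synth", {
      fld <- simulate_ne_field(config)
      ca <- simulate_cells(fld$movie, fld$truth, config)
      list(two = render_two_channel(fld$movie, ca, fld$truth, config),
           truth = fld$truth)
    })
    movie <- sim$two
    truth <- sim$truth
    soma_labels <- movie$soma_labels
    stage("synth", {
      write_truth_json(truth, file.path(out_dir, "ground_truth.json"))
      write_config_txt(config, file.path(out_dir, "config.txt"))
    })
  }
  if (is.null(soma_labels)) stop("run_pipeline: soma masks missing")

  pre <- stage("preprocess", {
    reg <- register_translation(movie)
    m <- bleedthrough_correct(reg$movie)
    geom <- build_fields(soma_labels, radius_um = radius_um,
                         px_um = movie$px_um)
    ts <- extract_traces(m, geom)
    list(movie = m, geometry = geom, traces = ts, shifts = reg$shifts)
  })
  stage("preprocess", write_traceset_csv(pre$traces,
                                         file.path(out_dir, "traces.csv")))

  green <- new_ne_movie(pre$movie$green, movie$h, movie$w, movie$frame_hz,
                        movie$px_um)
  spatial <- stage("spatial", {
    prof <- grid_autocorrelation(green)
    fit <- fit_double_exponential(prof)
    fc <- field_correlation_distributions(pre$traces)
    utils::write.csv(prof$profile, file.path(out_dir, "autocorr_profile.csv"),
                     row.names = FALSE)
    list(profile = prof, fit = fit, field_cor = fc)
  })

  models <- stage("stats", regime_split_fits(pre$traces, window_s))
  stage("stats", utils::write.csv(models$fits,
                                  file.path(out_dir, "cell_model_fits.csv"),
                                  row.names = FALSE))

  flow <- stage("flow", run_event_pipeline(green, sigma_px = sigma_px,
                                           kernel_s = kernel_s,
                                           alpha = alpha,
                                           z_thresh = z_thresh))
  stage("flow", write_event_csv(flow$events, movie$frame_hz, movie$px_um,
                                file.path(out_dir, "events.csv")))

  noise <- NULL
  if (run_noise_control >= 20) {
    noise <- stage("noise_control", noise_control(
      green, observed = list(spatial_r = flow$maps$spatial_r,
                             temporal_r = flow$maps$temporal_r),
      n = run_noise_control,
      seed = if (!is.null(config)) config$seed + 7L else 7L,
      sigma_px = sigma_px, kernel_s = kernel_s, alpha = alpha,
      z_thresh = z_thresh))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("neflow")),
    seed = if (!is.null(config)) config$seed else NA,
    knobs = list(radius_um = radius_um, window_s = window_s,
                 sigma_px = sigma_px, kernel_s = kernel_s, alpha = alpha,
                 z_thresh = z_thresh),
    n_frames = nrow(movie$green), fov = c(movie$h, movie$w),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(movie = movie, truth = truth, preprocess = pre,
                 spatial = spatial, models = models, flow = flow,
                 noise = noise, manifest = manifest))
}
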
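# File interfaces: TIFF movies and label masks, CSV trace/event tables, JSON
# ground truth and summaries. Float TIFF pages are stored rescaled to [0, 1]
# with the affine calibration kept in a JSON sidecar.

#' Write a two-channel movie as a TIFF stack
#'
#' Pages are interleaved green, red, green, red, ... as 32-bit float, values
#' rescaled to [0, 1]; the range and calibration go to `<path>.json`.
#'
#' @param movie a `two_channel_movie`
#' @param path output TIFF path
#' @export
write_movie_tiff <- function(movie, path) {
  rng <- range(movie$green, movie$red)
  scale <- function(m) (m - rng[1]) / max(rng[2] - rng[1], 1e-12)
  pages <- vector("list", 2L * nrow(movie$green))
  for (t in seq_len(nrow(movie$green))) {
    pages[[2L * t - 1L]] <- matrix(scale(movie$green[t, ]), movie$h, movie$w)
    pages[[2L * t]] <- matrix(scale(movie$red[t, ]), movie$h, movie$w)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(min = rng[1], max = rng[2], h = movie$h, w = movie$w,
         frame_hz = movie$frame_hz, px_um = movie$px_um,
         channels = c("green", "red")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a two-channel movie written by [write_movie_tiff()]
#' @param path TIFF path (expects the `.json` sidecar next to it)
#' @return a `two_channel_movie`
#' @export
read_movie_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  tn <- length(pages) %/% 2L
  scale <- meta$max - meta$min
  g <- matrix(0, tn, meta$h * meta$w)
  r <- matrix(0, tn, meta$h * meta$w)
  for (t in seq_len(tn)) {
    # consume pages as we go to keep the page list from doubling the footprint
    g[t, ] <- as.vector(pages[[2L * t - 1L]]) * scale + meta$min
    r[t, ] <- as.vector(pages[[2L * t]]) * scale + meta$min
    pages[2L * t - 1L] <- list(NULL)
    pages[2L * t] <- list(NULL)
  }
  structure(list(green = g, red = r, h = meta$h, w = meta$w,
                 frame_hz = meta$frame_hz, px_um = meta$px_um,
                 soma_labels = NULL, shifts = NULL),
            class = "two_channel_movie")
}

#' Write / read a 16-bit label mask TIFF
#' @param labels integer h x w matrix
#' @param path TIFF path
#' @export
write_mask_tiff <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write ground truth as JSON
#' @param truth an `ne_truth`
#' @param path output path
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(events = truth$events, cell_centers = truth$cell_centers,
         planted_betas = truth$planted_betas,
         diffusion_sigma_um = truth$diffusion_sigma_um,
         varicosities = truth$varicosities),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read ground truth written by [write_truth_json()]
#' @param path JSON path
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$events <- as.data.frame(x$events)
  x$cell_centers <- as.data.frame(x$cell_centers)
  x$planted_betas <- as.data.frame(x$planted_betas)
  x$varicosities <- as.data.frame(x$varicosities)
  structure(x, class = "ne_truth")
}

#' Write a flat key-value config file
#' @param config a `sim_config`
#' @param path output path
#' @export
write_config_txt <- function(config, path) {
  keep <- !vapply(config, is.null, logical(1)) &
    !vapply(config, is.data.frame, logical(1))
  lines <- vapply(names(config)[keep], function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an event catalog as CSV
#' @param events event data.frame from [classify_and_pair()]
#' @param frame_hz,px_um calibration used to convert frames/px to s/um
#' @param path output CSV path
#' @export
write_event_csv <- function(events, frame_hz, px_um, path) {
  out <- data.frame(kind = events$kind,
                    onset_s = events$onset_frame / frame_hz,
                    offset_s = events$offset_frame / frame_hz,
                    x_um = events$x * px_um,
                    y_um = events$y * px_um)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a trace set as CSV (one column per trace)
#' @param traceset a `trace_set`
#' @param path output CSV path
#' @export
write_traceset_csv <- function(traceset, path) {
  n <- nrow(traceset$cell_ca)
  cols <- list()
  for (i in seq_len(n)) {
    cols[[paste0("cell", i, "_ca")]] <- traceset$cell_ca[i, ]
    cols[[paste0("cell", i, "_local_ne")]] <- traceset$local_ne[i, ]
    cols[[paste0("cell", i, "_global_ne")]] <- traceset$global_ne[i, ]
    cols[[paste0("cell", i, "_pop_ca")]] <- traceset$pop_ca[i, ]
  }
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE)
  invisible(path)
}
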
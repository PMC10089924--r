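#' Write and read a two-column trace CSV
#'
#' The on-disk convention for all traces: column 1 `time_s`, column 2
#' `value`.
#'
#' @param trace numeric trace.
#' @param rate sampling rate in Hz.
#' @param path output file.
#' @export
write_trace_csv <- function(trace, rate, path) {
  df <- data.frame(time_s = (seq_along(trace) - 1) / rate,
                   value = as.numeric(trace))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @return `read_trace_csv`: list with `trace`, `rate` (inferred from
#'   the time column), `times_s`.
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  rate <- if (nrow(df) > 1) 1 / (df$time_s[2] - df$time_s[1]) else NA_real_
  list(trace = df$value, rate = rate, times_s = df$time_s)
}

#' Write a pixel movie as multi-page TIFF
#'
#' Frames are scaled to [0, 1] for 32-bit float TIFF storage; the scale
#' and offset are written to a JSON sidecar (`<path>.json`) so
#' [read_movie_tiff()] can restore the original values.
#'
#' @param movie a [pixel_movie()].
#' @param path output `.tif` path.
#' @export
write_movie_tiff <- function(movie, path) {
  d <- dim(movie$data)
  lo <- min(movie$data)
  hi <- max(movie$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[1]), function(i) {
    (movie$data[i, , ] - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(frame_rate = movie$frame_rate, offset = lo,
                            scale = scale, dim = d),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param frame_rate used if no JSON sidecar is present.
#' @return `read_movie_tiff`: a [pixel_movie()].
#' @export
read_movie_tiff <- function(path, frame_rate = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".json")
  offset <- 0; scale <- 1
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    frame_rate <- meta$frame_rate
    offset <- meta$offset
    scale <- meta$scale
  }
  if (is.null(frame_rate)) stop("`frame_rate` required (no sidecar found)")
  arr <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (i in seq_along(pages)) {
    page <- pages[[i]]
    if (length(dim(page)) == 3L) page <- page[, , 1]
    arr[i, , ] <- page * scale + offset
  }
  pixel_movie(arr, frame_rate)
}

#' Write a session bundle to a directory
#'
#' Traces are written as two-column CSVs, the neuron matrix as a CSV with
#' one row per cell, the astrocyte event table as CSV, the movie (if
#' present) as multi-page TIFF, and the ground truth (if given) as JSON.
#'
#' @param bundle a `session_bundle` from [simulate_session()].
#' @param dir output directory (created if needed).
#' @param truth optional `ground_truth` to store alongside.
#' @export
write_session_bundle <- function(bundle, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- bundle$rates
  write_trace_csv(bundle$pupil, r$pupil, file.path(dir, "pupil.csv"))
  write_trace_csv(bundle$speed, r$speed, file.path(dir, "speed.csv"))
  write_trace_csv(bundle$ne, r$imaging, file.path(dir, "ne.csv"))
  write_trace_csv(bundle$astro_population, r$imaging,
                  file.path(dir, "astro_population.csv"))
  write_trace_csv(bundle$lfp_ipsi$voltage, r$lfp,
                  file.path(dir, "lfp_ipsi.csv"))
  write_trace_csv(bundle$lfp_contra$voltage, r$lfp,
                  file.path(dir, "lfp_contra.csv"))
  write.csv(bundle$astro_events, file.path(dir, "astro_events.csv"),
            row.names = FALSE)
  write.csv(bundle$neuron_matrix, file.path(dir, "neuron_matrix.csv"),
            row.names = FALSE)
  if (!is.null(bundle$photometry)) {
    write_trace_csv(bundle$photometry, r$photometry,
                    file.path(dir, "photometry.csv"))
  }
  if (!is.null(bundle$movie)) {
    write_movie_tiff(bundle$movie, file.path(dir, "movie.tif"))
  }
  jsonlite::write_json(r, file.path(dir, "rates.json"), auto_unbox = TRUE)
  if (!is.null(truth)) {
    tr <- truth
    class(tr) <- NULL
    tr$F_true <- NULL  # matrices stay out of the JSON summary
    tr$noise_trace <- NULL
    jsonlite::write_json(tr, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
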
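#' Fluorescence movie stack
#'
#' Container for an x-y-t two-photon fluorescence time series together with
#' its pixel geometry and frame rate. All downstream spatial quantities
#' (event footprints in um^2, event volumes in um^2*s, frequencies per
#' 100 um^2) derive from `pixel_size` and `frame_rate`.
#'
#' @param data Numeric 3D array, dimensions (x, y, t), arbitrary units.
#' @param pixel_size Pixel side length in micrometers per pixel (> 0).
#' @param frame_rate Acquisition rate in Hz (> 0).
#' @return An object of class `movie_stack` (a list with elements `data`,
#'   `pixel_size`, `frame_rate`).
#' @export
#' @examples
#' m <- movie_stack(array(rnorm(16 * 16 * 10, 100), c(16, 16, 10)),
#'                  pixel_size = 1, frame_rate = 30)
#' m
movie_stack <- function(data, pixel_size, frame_rate) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array with dimensions (x, y, t)", call. = FALSE)
  }
  if (dim(data)[3L] < 2L) stop("a movie needs at least 2 frames", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (um/px)", call. = FALSE)
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("`frame_rate` must be a single positive number (Hz)", call. = FALSE)
  }
  assert_finite(data, "data")
  structure(list(data = data, pixel_size = pixel_size, frame_rate = frame_rate),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("movie_stack: %d x %d px, %d frames @ %g Hz, %g um/px (%.1f s)\n",
              d[1L], d[2L], d[3L], x$frame_rate, x$pixel_size,
              d[3L] / x$frame_rate))
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$data)

#' Read a movie stack from a multi-page TIFF with a JSON sidecar
#'
#' The sidecar (default `<path>.json`) must provide `pixel_size_um` and
#' `frame_rate_hz`; `offset` and `scale` (written by [write_movie()]) map the
#' stored unit-range samples back to the original intensity scale.
#'
#' @param path Path to a multi-page TIFF file.
#' @param sidecar Path to the JSON metadata file.
#' @return A [movie_stack()].
#' @export
read_movie <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("movie file not found: ", path, call. = FALSE)
  if (!file.exists(sidecar)) {
    stop("metadata sidecar not found: ", sidecar,
         " (required keys: pixel_size_um, frame_rate_hz)", call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (key in c("pixel_size_um", "frame_rate_hz")) {
    if (is.null(meta[[key]])) {
      stop("metadata sidecar is missing required key `", key, "`", call. = FALSE)
    }
  }
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  a <- array(unlist(frames, use.names = FALSE),
             dim = c(dim(frames[[1L]])[1:2], length(frames)))
  a <- a * (meta$scale %||% 1) + (meta$offset %||% 0)
  movie_stack(a, pixel_size = meta$pixel_size_um, frame_rate = meta$frame_rate_hz)
}

#' Write a movie stack as a multi-page TIFF plus JSON sidecar
#'
#' Samples are affinely mapped to the unit interval and stored as 32-bit
#' values, so a round trip reproduces intensities to within 32-bit
#' quantization (relative error ~ 2^-32).
#'
#' @param movie A [movie_stack()].
#' @param path Output TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  rng <- range(movie$data)
  offset <- rng[1L]
  scale <- if (diff(rng) > 0) diff(rng) else 1
  d <- dim(movie$data)
  frames <- lapply(seq_len(d[3L]), function(t) {
    (movie$data[, , t] - offset) / scale
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_size_um = movie$pixel_size, frame_rate_hz = movie$frame_rate,
         offset = offset, scale = scale, n_frames = d[3L]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
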
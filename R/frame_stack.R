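#' Time-lapse image stack with physical calibration
#'
#' A `FrameStack` bundles a single-channel fluorescence movie with the
#' acquisition constants the downstream analysis needs: the effective
#' pixel size (65 nm by default, typical of a 100x objective on an sCMOS
#' camera) and the frame interval (1 s by default, continuous streaming).
#'
#' Pixels are stored as a `Y x X x T` array (row = y, col = x, slice =
#' frame), all values non-negative.
#'
#' @param pixels numeric array, either `Y x X x T` or a `Y x X` matrix
#'   (interpreted as a single frame).
#' @param pixel_size_nm physical pixel size in nanometers.
#' @param frame_interval_s time between frames in seconds.
#' @param channel optional channel name (e.g. `"GFP"`).
#' @return An object of class `FrameStack`.
#' @export
frame_stack <- function(pixels, pixel_size_nm = 65, frame_interval_s = 1.0,
                        channel = "ch1") {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  assert_that(length(dim(pixels)) == 3L, "pixels must be a Y x X x T array")
  assert_that(dim(pixels)[3] >= 1L, "stack must have at least one frame")
  assert_that(all(pixels >= 0), "pixel values must be non-negative")
  assert_that(is.numeric(pixel_size_nm) && pixel_size_nm > 0,
              "pixel_size_nm must be positive")
  assert_that(is.numeric(frame_interval_s) && frame_interval_s > 0,
              "frame_interval_s must be positive")
  structure(list(pixels = pixels,
                 pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s,
                 channel = channel),
            class = "FrameStack")
}

#' @export
print.FrameStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("FrameStack [%s]: %d x %d px, %d frames, %.0f nm/px, %.2f s/frame\n",
              x$channel, d[1], d[2], d[3], x$pixel_size_nm, x$frame_interval_s))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a [frame_stack()].
#' @export
n_frames <- function(stack) dim(stack$pixels)[3]

#' Extract one frame as a matrix
#' @param stack a [frame_stack()].
#' @param t frame index (1-based).
#' @export
get_frame <- function(stack, t) {
  assert_that(t >= 1 && t <= n_frames(stack), "frame index out of range")
  stack$pixels[, , t]
}

#' Maximum intensity projection over time
#'
#' Per-pixel maximum across all frames. The MIP of a short movie shows
#' every cortical endocytic event that fired during the acquisition and
#' is the reference image used to tune the cortical band width.
#'
#' @param stack a [frame_stack()].
#' @return numeric matrix (Y x X).
#' @export
max_intensity_projection <- function(stack) {
  apply(stack$pixels, c(1, 2), max)
}

#' Mean intensity projection over time
#' @param stack a [frame_stack()].
#' @return numeric matrix (Y x X).
#' @export
mean_intensity_projection <- function(stack) {
  rowMeans(stack$pixels, dims = 2)
}

#' Read a movie from a multi-page TIFF
#'
#' Accepts 8/16-bit integer or 32-bit float grayscale TIFFs. Calibration
#' is restored from a JSON sidecar (`<path>.json`) written by
#' [write_stack()]; when the sidecar is missing, defaults are applied
#' with a warning.
#'
#' @param path TIFF file path.
#' @param pixel_size_nm,frame_interval_s defaults used when no sidecar
#'   metadata is found.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, pixel_size_nm = 65, frame_interval_s = 1.0) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = FALSE),
                    error = function(e)
                      stop(sprintf("not a readable TIFF: %s (%s)",
                                   path, conditionMessage(e)), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) == 3L, logical(1))))
    stop(sprintf("multi-sample (e.g. RGB) TIFF not supported: %s", path),
         call. = FALSE)
  meta <- list(scale = 65535, pixel_size_nm = pixel_size_nm,
               frame_interval_s = frame_interval_s, channel = "ch1")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    got <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta[names(got)] <- got
  } else {
    warning(sprintf("no calibration sidecar for %s; using defaults (%g nm, %g s)",
                    path, pixel_size_nm, frame_interval_s))
  }
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * meta$scale
  # integer-origin data quantize exactly; round away float fuzz
  if (isTRUE(meta$integer)) arr <- round(arr)
  frame_stack(arr, meta$pixel_size_nm, meta$frame_interval_s, meta$channel)
}

#' Write a movie to a multi-page TIFF with a calibration sidecar
#'
#' Integer-valued stacks within \[0, 65535\] are written as 16-bit pages
#' (bit-exact round trip); anything else is written as 32-bit float with
#' a scale factor recorded in the sidecar.
#'
#' @param stack a [frame_stack()].
#' @param path output TIFF path; a `<path>.json` sidecar is written too.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  px <- stack$pixels
  is_int <- all(px == round(px)) && max(px) <= 65535
  scale <- if (is_int) 65535 else max(px, 1)
  bps <- if (is_int) 16L else 32L
  pages <- lapply(seq_len(n_frames(stack)),
                  function(t) px[, , t] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bps, reduce = FALSE)
  jsonlite::write_json(list(scale = scale,
                            integer = is_int,
                            pixel_size_nm = stack$pixel_size_nm,
                            frame_interval_s = stack$frame_interval_s,
                            channel = stack$channel),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a single-page integer label mask from TIFF
#' @param path TIFF path (as written by [write_mask()] or an external
#'   segmenter exporting integer labels).
#' @return integer matrix, 0 = background.
#' @export
read_mask <- function(path) {
  p <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(p)) == 3L)
    stop("label mask must be single-channel grayscale", call. = FALSE)
  m <- round(p * 65535)
  storage.mode(m) <- "integer"
  m
}

#' Write an integer label mask as a single-page 16-bit TIFF
#' @param mask integer matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  assert_that(max(mask) <= 65535, "more labels than a 16-bit mask can hold")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
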
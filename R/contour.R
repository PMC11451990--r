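#' Extract a sub-pixel cell contour from a label mask
#'
#' The boundary is taken as the 0.5 iso-level of the label's indicator
#' image after light Gaussian smoothing (sub-pixel marching squares;
#' the smoothing removes pixelation so a rasterized disk recovers its
#' analytic circumference to well under 1%). The polygon is oriented
#' counter-clockwise in array coordinates (positive shoelace area over
#' (x, y=row)) and resampled to uniform spacing `step_px`.
#'
#' @param mask integer label matrix.
#' @param label which label to outline.
#' @param step_px sample spacing along the contour, in pixels.
#' @param pixel_size_nm physical calibration used for arclength.
#' @param smooth_sigma_px Gaussian smoothing of the indicator before
#'   iso-contouring (0 disables).
#' @param compartment optional tag (`"mother"`/`"daughter"`).
#' @param cell_id optional cell identifier.
#' @return A `Contour`: data.frame-backed list with `points` (y, x),
#'   `step_px`, `arclength_um` (cumulative, starts at 0), `excluded`
#'   (all `FALSE` initially), `closed = TRUE`, `total_um`, plus
#'   calibration and identity fields.
#' @export
extract_contour <- function(mask, label, step_px = 1, pixel_size_nm = 65,
                            smooth_sigma_px = 1, compartment = NA_character_,
                            cell_id = NA_integer_) {
  bin <- mask == label
  n_px <- sum(bin)
  if (n_px < 9)
    stop(sprintf("label %s has %d pixels; too small for a contour",
                 label, n_px), call. = FALSE)
  z <- bin * 1.0
  if (smooth_sigma_px > 0)
    z <- as.matrix(EBImage::gblur(z, sigma = smooth_sigma_px))
  cl <- grDevices::contourLines(seq_len(nrow(z)), seq_len(ncol(z)), z,
                                levels = 0.5)
  assert_that(length(cl) >= 1L, "no iso-contour found for label")
  # keep the longest polygon (smoothing can shed tiny satellites)
  lens <- vapply(cl, function(p)
    sum(sqrt(diff(p$x)^2 + diff(p$y)^2)), numeric(1))
  p <- cl[[which.max(lens)]]
  y <- p$x   # contourLines' first axis is our row (y)
  x <- p$y
  if (y[1] != y[length(y)] || x[1] != x[length(x)]) {
    y <- c(y, y[1]); x <- c(x, x[1])
  }
  # enforce counter-clockwise orientation (array coordinates)
  area2 <- sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)])
  if (area2 < 0) { y <- rev(y); x <- rev(x) }
  seg <- sqrt(diff(y)^2 + diff(x)^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  n_out <- max(8L, floor(total / step_px))
  s_out <- (seq_len(n_out) - 1) * step_px
  ry <- stats::approx(cum, y, xout = s_out)$y
  rx <- stats::approx(cum, x, xout = s_out)$y
  structure(list(points = data.frame(y = ry, x = rx),
                 step_px = step_px,
                 arclength_um = s_out * pixel_size_nm / 1000,
                 excluded = rep(FALSE, n_out),
                 excluded_intervals = list(),
                 closed = TRUE,
                 total_um = total * pixel_size_nm / 1000,
                 pixel_size_nm = pixel_size_nm,
                 compartment = compartment,
                 cell_id = cell_id),
            class = "Contour")
}

#' @export
print.Contour <- function(x, ...) {
  cat(sprintf(
    "Contour (%s, cell %s): %d samples @ %g px, %.2f um total, %d excluded\n",
    x$compartment, x$cell_id, nrow(x$points), x$step_px, x$total_um,
    sum(x$excluded)))
  invisible(x)
}

#' Retained arclength of a contour in micrometers
#' @param contour a [extract_contour()] result.
#' @export
retained_um <- function(contour) {
  sum(!contour$excluded) * contour$step_px * contour$pixel_size_nm / 1000
}

#' Exclude the bud-neck region from a contour
#'
#' CME sites at the bud neck are too crowded to resolve individually,
#' so contour samples within `margin_px` (Euclidean) of any neck pixel
#' are marked excluded and recorded as index intervals.
#'
#' @param contour a closed [extract_contour()] result.
#' @param neck_pixels n x 2 matrix of (y, x) junction pixels (from
#'   [pair_mother_daughter()]); may be empty.
#' @param margin_px exclusion distance in pixels. The pipeline default
#'   ties this to the band width so the two compartments' kymograph
#'   bands can never overlap.
#' @return the contour with `excluded` and `excluded_intervals` set.
#' @export
exclude_neck <- function(contour, neck_pixels, margin_px) {
  assert_that(isTRUE(contour$closed), "contour must be closed")
  assert_that(margin_px >= 0, "margin_px must be non-negative")
  if (is.null(neck_pixels) || nrow(neck_pixels) == 0) return(contour)
  py <- contour$points$y; px <- contour$points$x
  d2min <- rep(Inf, length(py))
  for (i in seq_len(nrow(neck_pixels))) {
    d2 <- (py - neck_pixels[i, 1])^2 + (px - neck_pixels[i, 2])^2
    d2min <- pmin(d2min, d2)
  }
  excl <- sqrt(d2min) <= margin_px
  if (mean(excl) > 0.5)
    stop("neck exclusion removes more than half the contour; degenerate cell",
         call. = FALSE)
  contour$excluded <- contour$excluded | excl
  contour$excluded_intervals <- runs_to_intervals(contour$excluded)
  contour
}

# contiguous TRUE runs (circular) as list of c(start, end) index pairs
runs_to_intervals <- function(flag) {
  n <- length(flag)
  if (!any(flag)) return(list())
  if (all(flag)) return(list(c(1L, n)))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- Map(c, starts[r$values], ends[r$values])
  # merge a run touching both ends of the circular index space
  if (length(iv) >= 2L && flag[1] && flag[n]) {
    first <- iv[[1]]; last <- iv[[length(iv)]]
    iv <- iv[-c(1L, length(iv))]
    iv <- c(iv, list(c(last[1], first[2])))
  }
  iv
}

#' Choose the cortical band width from a maximum intensity projection
#'
#' Finds the smallest odd band width (pixels, centered on the contour)
#' whose perpendicular extent captures at least `coverage_fraction` of
#' the total above-background cortical MIP signal lying within
#' `3 * psf_sigma_px` of the contour. Mirrors the manual practice of
#' widening the outline until all cortical signal in the MIP falls
#' inside it.
#'
#' @param mip 2D matrix, maximum intensity projection of the movie.
#' @param contour a [extract_contour()] result (neck may already be
#'   excluded; only retained samples are used).
#' @param coverage_fraction fraction of cortical signal to capture,
#'   in (0, 1].
#' @param psf_sigma_px spot scale defining "near the contour".
#' @param default_width_px returned (with a warning) when the MIP shows
#'   no above-background cortical signal.
#' @return odd integer width in pixels.
#' @export
band_width_from_mip <- function(mip, contour, coverage_fraction = 0.95,
                                psf_sigma_px = 1.3, default_width_px = 5) {
  assert_that(coverage_fraction > 0 && coverage_fraction <= 1,
              "coverage_fraction must be in (0, 1]")
  reach <- max(ceiling(3 * psf_sigma_px), 2L)
  prof <- band_profiles(mip, contour, reach)       # rows x offsets
  v <- prof[!contour$excluded, , drop = FALSE]
  bg <- stats::median(v, na.rm = TRUE)
  noise <- mad_scale(v[!is.na(v)] - bg)
  above <- pmax(v - bg, 0)
  total <- sum(above, na.rm = TRUE)
  if (total <= 0 || max(above, na.rm = TRUE) < 3 * noise) {
    warning("no above-background cortical signal in MIP; using default width")
    return(as.integer(default_width_px))
  }
  offsets <- -reach:reach
  for (h in 0:reach) {
    got <- sum(above[, abs(offsets) <= h], na.rm = TRUE)
    if (got >= coverage_fraction * total) return(2L * h + 1L)
  }
  2L * reach + 1L
}

# unit normals of the closed resampled contour via central differences
contour_normals <- function(contour) {
  y <- contour$points$y; x <- contour$points$x
  n <- length(y)
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  ty <- (y[ip] - y[im]) / 2
  tx <- (x[ip] - x[im]) / 2
  len <- sqrt(ty^2 + tx^2)
  len[len == 0] <- 1
  cbind(ny = tx / len, nx = -ty / len)
}

# sample a band of perpendicular offsets around every contour sample;
# returns an (all-samples x offsets) matrix of bilinear values (NA when
# outside the image)
band_profiles <- function(frame, contour, reach) {
  nm <- contour_normals(contour)
  offsets <- -reach:reach
  y0 <- contour$points$y; x0 <- contour$points$x
  ys <- outer(y0, offsets * 1, function(a, o) a) +
    outer(nm[, "ny"], offsets)
  xs <- outer(x0, offsets * 1, function(a, o) a) +
    outer(nm[, "nx"], offsets)
  matrix(bilinear(frame, as.vector(ys), as.vector(xs)),
         nrow = length(y0))
}
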
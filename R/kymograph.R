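#' Sample a cortical band profile from one frame
#'
#' For each retained contour sample, intensities are interpolated
#' (bilinear) at `width_px` points spaced 1 px along the local normal
#' (symmetric about the contour) and reduced with `max` (robust to
#' contour placement error; the default for kymographs) or `mean`
#' (photometric).
#'
#' @param frame 2D intensity matrix.
#' @param contour a [extract_contour()] result (neck exclusion applied
#'   if desired).
#' @param width_px odd band width in pixels.
#' @param reduction `"max"` or `"mean"`.
#' @return numeric vector over retained contour samples; attribute
#'   `flagged` marks rows with more than half their band outside the
#'   image.
#' @export
sample_band <- function(frame, contour, width_px = 5,
                        reduction = c("max", "mean")) {
  reduction <- match.arg(reduction)
  assert_that(width_px >= 1 && width_px %% 2 == 1, "width_px must be odd")
  reach <- (width_px - 1L) / 2L
  prof <- band_profiles(frame, contour, reach)
  prof <- prof[!contour$excluded, , drop = FALSE]
  reduce_band(prof, reduction)
}

reduce_band <- function(prof, reduction) {
  n_na <- rowSums(is.na(prof))
  vals <- if (reduction == "max") {
    suppressWarnings(apply(prof, 1, max, na.rm = TRUE))
  } else {
    rowMeans(prof, na.rm = TRUE)
  }
  vals[!is.finite(vals)] <- NA_real_
  structure(vals, flagged = n_na > ncol(prof) / 2)
}

#' Build a circumferential kymograph along a contour
#'
#' Column `t` of the result is the band profile of frame `t`; rows run
#' along the retained cortex. Row adjacency records which neighboring
#' rows are truly contiguous on the cell surface: the closed-contour
#' seam is adjacent (the kymograph wraps) while rows flanking an
#' excluded bud-neck gap are not.
#'
#' @param stack a [frame_stack()].
#' @param contour a [extract_contour()] result from the same field of
#'   view (with any neck exclusion applied).
#' @param width_px odd band width (see [band_width_from_mip()]).
#' @param reduction band reduction operator, `"max"` or `"mean"`.
#' @return A `Kymograph`: `values` (S x T matrix),
#'   `row_arclength_um`, `adjacent_next` (logical, row i ~ row i+1;
#'   last element is the wrap adjacency), calibration fields,
#'   `cell_id`, `compartment`, `width_px`, `reduction`.
#' @export
build_kymograph <- function(stack, contour, width_px = 5,
                            reduction = c("max", "mean")) {
  reduction <- match.arg(reduction)
  assert_that(width_px >= 1 && width_px %% 2 == 1, "width_px must be odd")
  reach <- (width_px - 1L) / 2L
  nm <- contour_normals(contour)
  keep <- !contour$excluded
  offsets <- -reach:reach
  y0 <- contour$points$y[keep]; x0 <- contour$points$x[keep]
  ys <- outer(y0, offsets, function(a, o) a) + outer(nm[keep, "ny"], offsets)
  xs <- outer(x0, offsets, function(a, o) a) + outer(nm[keep, "nx"], offsets)
  n_t <- n_frames(stack)
  vals <- matrix(NA_real_, length(y0), n_t)
  flagged <- rep(FALSE, length(y0))
  for (t in seq_len(n_t)) {
    prof <- matrix(bilinear(stack$pixels[, , t], as.vector(ys),
                            as.vector(xs)), nrow = length(y0))
    r <- reduce_band(prof, reduction)
    vals[, t] <- r
    flagged <- flagged | attr(r, "flagged")
  }
  idx <- which(keep)
  n_all <- length(contour$excluded)
  nxt <- c(idx[-1], idx[1] + n_all)       # successor in circular index space
  adjacent_next <- (nxt - idx) == 1L | (nxt - idx) == n_all
  structure(list(values = vals,
                 row_arclength_um = contour$arclength_um[keep],
                 adjacent_next = adjacent_next,
                 row_flagged = flagged,
                 pixel_size_nm = contour$pixel_size_nm,
                 frame_interval_s = stack$frame_interval_s,
                 cell_id = contour$cell_id,
                 compartment = contour$compartment,
                 channel = stack$channel,
                 width_px = width_px,
                 reduction = reduction),
            class = "Kymograph")
}

#' @export
print.Kymograph <- function(x, ...) {
  cat(sprintf(
    "Kymograph (%s, cell %s, %s): %d rows x %d frames, band %d px (%s)\n",
    x$compartment, x$cell_id, x$channel, nrow(x$values), ncol(x$values),
    x$width_px, x$reduction))
  invisible(x)
}

#' Pair two kymographs of the same cortex for two-color analysis
#'
#' Both kymographs must have been built from the same contour and band
#' width (identical row maps); mismatched geometry is refused.
#'
#' @param kymoA,kymoB [build_kymograph()] results.
#' @return list of class `KymoPair` with elements `a` and `b`.
#' @export
pair_two_color <- function(kymoA, kymoB) {
  same <- nrow(kymoA$values) == nrow(kymoB$values) &&
    isTRUE(all.equal(kymoA$row_arclength_um, kymoB$row_arclength_um)) &&
    identical(kymoA$adjacent_next, kymoB$adjacent_next)
  if (!same)
    stop("kymographs have different row maps; built from different contours?",
         call. = FALSE)
  structure(list(a = kymoA, b = kymoB), class = "KymoPair")
}

#' Render a kymograph to PNG with a 30-s scale bar
#'
#' Time runs horizontally; a horizontal bar spanning 30 s is drawn in
#' the lower-left corner for visual comparison across movies.
#'
#' @param kymo a [build_kymograph()] result.
#' @param path output PNG path.
#' @param scale_bar_s scale bar length in seconds.
#' @return `path`, invisibly.
#' @export
render_kymograph_png <- function(kymo, path, scale_bar_s = 30) {
  v <- kymo$values
  v[is.na(v)] <- 0
  rng <- range(v)
  g <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  grDevices::png(path, width = ncol(v) * 3, height = nrow(v) * 3)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(t(g)[, rev(seq_len(nrow(g))), drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  useRaster = TRUE)
  bar_frac <- scale_bar_s / (ncol(v) * kymo$frame_interval_s)
  graphics::segments(0.02, 0.03, 0.02 + bar_frac, 0.03,
                     col = "white", lwd = 4)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}

#' Write a kymograph to a float TIFF plus a row-map CSV
#' @param kymo a [build_kymograph()] result.
#' @param path output TIFF path; `<path>.rows.csv` is written alongside.
#' @export
write_kymograph <- function(kymo, path) {
  v <- kymo$values
  v[is.na(v)] <- 0
  sc <- max(v, 1)
  tiff::writeTIFF(v / sc, path, bits.per.sample = 32L)
  utils::write.csv(data.frame(row = seq_len(nrow(v)),
                              arclength_um = kymo$row_arclength_um,
                              adjacent_next = kymo$adjacent_next),
                   paste0(path, ".rows.csv"), row.names = FALSE)
  invisible(path)
}
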
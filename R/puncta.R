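#' Detect cytoplasmic puncta in a cell interior
#'
#' Operationalizes "cells containing at least one visible cytoplasmic
#' spot": a scale-normalized Laplacian-of-Gaussian filter at the spot
#' scale is applied to the projection, and local maxima inside the
#' eroded cell interior exceeding `k_sigma` times the robust response
#' noise are counted as puncta. The cortex margin keeps cortical CME
#' patches from ever counting as cytoplasmic (default margin should be
#' at least the band width plus twice the PSF sigma).
#'
#' @param projection 2D intensity matrix (max-Z or max-time projection).
#' @param cell_mask logical or 0/1 matrix for one cell.
#' @param cortex_margin_px erosion radius removing the cortical rim.
#' @param spot_sigma_px LoG scale, approximately the PSF sigma.
#' @param k_sigma detection threshold in noise units.
#' @param cell_id carried into the result.
#' @return A `PunctaCall` list: `cell_id`, `n_puncta`, `positive`,
#'   `spot_coordinates` (data.frame y, x, response).
#' @export
detect_interior_puncta <- function(projection, cell_mask,
                                   cortex_margin_px = 8,
                                   spot_sigma_px = 1.3, k_sigma = 5,
                                   cell_id = 1L) {
  m <- cell_mask > 0
  brush <- EBImage::makeBrush(2L * as.integer(cortex_margin_px) + 1L, "disc")
  interior <- as.matrix(EBImage::erode(m * 1, brush)) > 0.5
  if (!any(interior))
    stop("cortex margin erases the whole cell interior", call. = FALSE)
  resp <- log_response(projection, spot_sigma_px)
  rin <- resp[interior]
  noise <- mad_scale(rin - stats::median(rin))
  thr <- stats::median(rin) + k_sigma * noise
  mx <- local_maxima(resp) & interior & resp > thr
  idx <- which(mx)
  coords <- data.frame(y = ((idx - 1L) %% nrow(resp)) + 1L,
                       x = ((idx - 1L) %/% nrow(resp)) + 1L,
                       response = resp[idx])
  structure(list(cell_id = cell_id,
                 n_puncta = nrow(coords),
                 positive = nrow(coords) >= 1L,
                 spot_coordinates = coords),
            class = "PunctaCall")
}

# scale-normalized negative LoG: bright spots -> positive peaks
log_response <- function(img, sigma) {
  sm <- as.matrix(EBImage::gblur(img, sigma = sigma))
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  -sigma^2 * as.matrix(EBImage::filter2(sm, lap))
}

# strict 8-neighborhood local maxima (borders excluded)
local_maxima <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  out <- matrix(FALSE, ny, nx)
  ci <- 2:(ny - 1); cj <- 2:(nx - 1)
  c0 <- img[ci, cj]
  ok <- c0 > img[ci - 1, cj] & c0 > img[ci + 1, cj] &
    c0 > img[ci, cj - 1] & c0 > img[ci, cj + 1] &
    c0 > img[ci - 1, cj - 1] & c0 > img[ci - 1, cj + 1] &
    c0 > img[ci + 1, cj - 1] & c0 > img[ci + 1, cj + 1]
  out[ci, cj] <- ok
  out
}

#' Percentage of puncta-positive cells
#'
#' @param calls list of [detect_interior_puncta()] results (or any
#'   objects with a logical `positive` field).
#' @return list with `percent` and `n`.
#' @export
percent_positive <- function(calls) {
  assert_that(length(calls) >= 1, "need at least one cell call")
  pos <- vapply(calls, function(c) isTRUE(c$positive), logical(1))
  list(percent = 100 * sum(pos) / length(pos), n = length(pos))
}

#' Daughter/mother cortical intensity ratio from a projection
#'
#' The mean above-background band intensity along the daughter's
#' retained contour divided by the same quantity for the mother,
#' computed per polarized cell (cohort averages are taken over at
#' least ~10 cells by the calling code).
#'
#' @param mip 2D projection matrix.
#' @param contour_daughter,contour_mother [extract_contour()] results
#'   from one budded cell, neck excluded.
#' @param width_px odd band width.
#' @param background background level(s) subtracted from the band
#'   means: a single number, a vector `c(daughter =, mother =)`, or
#'   `NULL` to estimate it per compartment as the 0.1 quantile of the
#'   per-row mean band profile (rows of cortex untouched by signal).
#' @return list with `ratio`, `daughter_mean`, `mother_mean`,
#'   `background` (named per compartment).
#' @export
cortical_intensity_ratio <- function(mip, contour_daughter, contour_mother,
                                     width_px = 5, background = NULL) {
  reach <- (width_px - 1L) / 2L
  pd <- band_profiles(mip, contour_daughter, reach)
  pd <- rowMeans(pd[!contour_daughter$excluded, , drop = FALSE], na.rm = TRUE)
  pm <- band_profiles(mip, contour_mother, reach)
  pm <- rowMeans(pm[!contour_mother$excluded, , drop = FALSE], na.rm = TRUE)
  if (is.null(background)) {
    background <- c(daughter = unname(stats::quantile(pd, 0.1, na.rm = TRUE)),
                    mother = unname(stats::quantile(pm, 0.1, na.rm = TRUE)))
  } else if (length(background) == 1L) {
    background <- c(daughter = unname(background), mother = unname(background))
  }
  dmean <- mean(pd, na.rm = TRUE) - background[["daughter"]]
  mmean <- mean(pm, na.rm = TRUE) - background[["mother"]]
  if (!is.finite(mmean) || mmean <= 0)
    stop("mother band mean does not exceed background; ratio undefined",
         call. = FALSE)
  list(ratio = dmean / mmean, daughter_mean = dmean, mother_mean = mmean,
       background = background)
}

#' Pearson correlation between two channels over a mask
#'
#' Standard pixel-wise Pearson correlation coefficient, the JACoP-style
#' colocalization score computed over the cell mask of a two-color
#' projection.
#'
#' @param imgA,imgB 2D matrices of identical shape.
#' @param mask logical matrix selecting pixels (default: all). Fewer
#'   than 10 masked pixels triggers a warning (the estimate is
#'   unstable); fewer than 2, or a constant channel, is an error.
#' @return A `ColocResult` list: `pcc`, `n_pixels`, `mask_description`.
#' @export
pearson_cc <- function(imgA, imgB, mask = NULL) {
  assert_that(all(dim(imgA) == dim(imgB)), "images must have equal shape")
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(imgA), ncol(imgA))
    desc <- "whole image"
  } else {
    assert_that(all(dim(mask) == dim(imgA)), "mask shape mismatch")
    mask <- mask > 0
    desc <- sprintf("mask of %d px", sum(mask))
  }
  a <- imgA[mask]; b <- imgB[mask]
  assert_that(length(a) >= 2, "need at least 2 masked pixels")
  if (length(a) < 10)
    warning("fewer than 10 masked pixels; correlation estimate is unstable",
            call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("a channel is constant over the mask; PCC undefined",
         call. = FALSE)
  structure(list(pcc = stats::cor(a, b), n_pixels = length(a),
                 mask_description = desc),
            class = "ColocResult")
}

#' Colocalization score of a simulated two-channel scene
#'
#' Convenience wrapper applying [pearson_cc()] to the maximum intensity
#' projections of a simulated two-channel movie over the cell mask.
#'
#' @param projA,projB 2D projections of the two channels.
#' @param mask cell mask (logical or labels).
#' @return A `ColocResult`.
#' @export
coloc_scene_pcc <- function(projA, projB, mask) {
  pearson_cc(projA, projB, mask = mask > 0)
}
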
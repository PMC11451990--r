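#' Build the budded-cell geometry for a simulation
#'
#' The cell is modeled as two overlapping disks, a larger mother and a
#' smaller daughter (bud), whose circles intersect with the configured
#' neck half-width. Real budded cells are irregular, but the analysis
#' must not depend on shape; disks keep every contour-length oracle
#' analytic. Returns the integer label mask (mother = 1, daughter = 2,
#' overlap assigned to the daughter so each label stays connected) plus
#' the analytic ground-truth cortical arcs with the occluded/neck region
#' already excluded.
#'
#' @param config a [sim_config()].
#' @param neck_margin_px extra cortex excluded on each side of the neck,
#'   in pixels of arclength (mirrors the analysis-side neck exclusion).
#' @param center_distance_px optional override of the lobe center
#'   distance; the default places the circles so their chord half-width
#'   equals `neck_halfwidth_px`. Overrides that separate the lobes are
#'   rejected.
#' @param pad_px background margin around the cell.
#' @return A `CellGeometry` list: `mask` (integer matrix), `ny`, `nx`,
#'   `arcs` (per-compartment analytic arc descriptors), `um_per_px`, and
#'   the generating `config`.
#' @export
make_cell_geometry <- function(config, neck_margin_px = 5,
                               center_distance_px = NULL, pad_px = 10) {
  validate_sim_config(unclass(config))
  rm_ <- config$mother_radius_px
  rd <- config$daughter_radius_px
  a <- config$neck_halfwidth_px
  x1 <- sqrt(rm_^2 - a^2)
  x2 <- sqrt(rd^2 - a^2)
  d <- if (is.null(center_distance_px)) x1 + x2 else center_distance_px
  if (d >= rm_ + rd)
    stop("daughter does not touch mother: lobes are separated", call. = FALSE)
  if (d <= rm_ - rd)
    stop("daughter is engulfed by the mother disk", call. = FALSE)
  if (!is.null(center_distance_px)) {
    # recompute the realized chord half-width for the overridden distance
    x1 <- (d^2 - rd^2 + rm_^2) / (2 * d)
    a <- sqrt(rm_^2 - x1^2)
    x2 <- d - x1
  }
  ny <- round(2 * rm_ + 2 * pad_px)
  nx <- round(rm_ + d + rd + 2 * pad_px)
  cy <- rm_ + pad_px
  cxm <- rm_ + pad_px
  cxd <- cxm + d
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  inm <- (yy - cy)^2 + (xx - cxm)^2 <= rm_^2
  ind <- (yy - cy)^2 + (xx - cxd)^2 <= rd^2
  mask <- matrix(0L, ny, nx)
  mask[inm] <- 1L
  mask[ind] <- 2L
  um <- config$pixel_size_nm / 1000
  alpha_m <- atan2(a, x1)
  alpha_d <- atan2(a, x2)
  arcs <- list(
    mother = make_arc(c(cy, cxm), rm_, phase = 0, alpha_occl = alpha_m,
                      neck_margin_px = neck_margin_px, um_per_px = um),
    daughter = make_arc(c(cy, cxd), rd, phase = pi, alpha_occl = alpha_d,
                        neck_margin_px = neck_margin_px, um_per_px = um))
  structure(list(mask = mask, ny = ny, nx = nx,
                 centers = list(mother = c(cy, cxm), daughter = c(cy, cxd)),
                 radii = c(mother = rm_, daughter = rd),
                 neck_halfwidth_px = a,
                 arcs = arcs, um_per_px = um, config = config),
            class = "CellGeometry")
}

# Analytic retained cortical arc of one lobe: the full circle minus the
# arc occluded by the other lobe (half-angle alpha_occl about the axis
# pointing at it, direction `phase`) minus the neck margin.
make_arc <- function(center, radius, phase, alpha_occl, neck_margin_px,
                     um_per_px) {
  alpha_tot <- alpha_occl + neck_margin_px / radius
  assert_that(alpha_tot < pi, "neck exclusion swallows the whole lobe")
  retained_px <- radius * (2 * pi - 2 * alpha_tot)
  list(center = center, radius = radius, phase = phase,
       alpha_occl = alpha_occl, alpha_tot = alpha_tot,
       retained_um = retained_px * um_per_px,
       retained_px = retained_px,
       um_per_px = um_per_px)
}

#' Map arclength positions on a ground-truth arc to image coordinates
#'
#' Arclength 0 starts at one edge of the neck exclusion and runs
#' counter-clockwise (in array convention) around the retained cortex.
#'
#' @param arc one element of `CellGeometry$arcs`.
#' @param s_um arclength positions in micrometers, in
#'   `[0, arc$retained_um)`.
#' @return data.frame with columns `y`, `x` (sub-pixel) and `angle`.
#' @export
arc_position <- function(arc, s_um) {
  s_px <- s_um / arc$um_per_px
  theta <- arc$phase + arc$alpha_tot + s_px / arc$radius
  data.frame(y = arc$center[1] + arc$radius * sin(theta),
             x = arc$center[2] + arc$radius * cos(theta),
             angle = theta %% (2 * pi))
}

#' Retained ground-truth cortex lengths in micrometers
#' @param geometry a [make_cell_geometry()] result.
#' @return named numeric vector (`mother`, `daughter`).
#' @export
contour_lengths_um <- function(geometry) {
  c(mother = geometry$arcs$mother$retained_um,
    daughter = geometry$arcs$daughter$retained_um)
}

# Rejection-sample interior positions at least margin_px away from
# either lobe's circle (used for cytoplasmic puncta).
sample_interior_positions <- function(geometry, n, margin_px) {
  if (n == 0) return(data.frame(y = numeric(0), x = numeric(0)))
  cm <- geometry$centers$mother; cd <- geometry$centers$daughter
  rm_ <- geometry$radii["mother"]; rd <- geometry$radii["daughter"]
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    y <- stats::runif(4 * n, 1, geometry$ny)
    x <- stats::runif(4 * n, 1, geometry$nx)
    dm <- sqrt((y - cm[1])^2 + (x - cm[2])^2)
    dd <- sqrt((y - cd[1])^2 + (x - cd[2])^2)
    ok <- (rm_ - dm >= margin_px | rd - dd >= margin_px) &
      abs(rm_ - dm) >= margin_px & abs(rd - dd) >= margin_px
    out <- rbind(out, cbind(y[ok], x[ok]))
  }
  data.frame(y = out[seq_len(n), 1], x = out[seq_len(n), 2])
}
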
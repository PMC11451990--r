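#' Per-row baseline and pooled noise scale of a kymograph
#'
#' The baseline of each cortex row is its temporal median (robust to
#' transient events occupying less than half the movie at that row);
#' the noise scale is `1.4826 x MAD` of the residuals, pooled across
#' all rows.
#'
#' @param kymo a [build_kymograph()] result, or a plain S x T matrix.
#' @return list with `baseline` (length-S vector) and `noise` (scalar).
#' @export
estimate_baseline <- function(kymo) {
  v <- if (inherits(kymo, "Kymograph")) kymo$values else kymo
  assert_that(ncol(v) >= 5, "need at least 5 frames to estimate a baseline")
  baseline <- apply(v, 1, stats::median, na.rm = TRUE)
  baseline[is.na(baseline)] <- 0
  resid <- v - baseline
  noise <- mad_scale(resid[!is.na(resid)])
  list(baseline = baseline, noise = noise)
}

#' Detect endocytic event traces on a kymograph
#'
#' The kymograph is lightly smoothed along the cortex axis (within
#' contiguous row runs only; never across an excluded bud-neck gap),
#' thresholded at `baseline + k_sigma * noise`, and above-threshold
#' pixels are grouped into 8-connected components in (row, frame)
#' space. Rows wrap across the closed-contour seam but never across
#' excluded-gap boundaries. Components shorter than `min_len_frames` or
#' spanning fewer than `min_rows` rows are discarded. A trace touching
#' the first or last frame is flagged censored (its true lifetime is
#' underestimated).
#'
#' @param kymo a [build_kymograph()] result.
#' @param k_sigma detection threshold in noise units.
#' @param min_len_frames minimum temporal extent (frames).
#' @param min_rows minimum row extent.
#' @param smooth_row_sigma Gaussian smoothing (rows axis, in rows)
#'   applied before thresholding; 0 disables. Smoothing only along the
#'   cortex axis raises the effective SNR without biasing temporal
#'   extents, which lifetimes are measured from.
#' @return A `TraceSet`: list of traces, each with `rows` (kymograph
#'   row indices), `t_start`, `t_end` (1-based frames, inclusive),
#'   `lifetime_s`, `censored_start`, `censored_end`,
#'   `intensity_profile` (per-frame above-baseline sum over the
#'   component), `peak`, `arclength_um` (intensity-weighted center).
#'   Metadata about the source kymograph is attached as attribute
#'   `meta`.
#' @export
detect_traces <- function(kymo, k_sigma = 4, min_len_frames = 3,
                          min_rows = 1, smooth_row_sigma = 1) {
  v <- kymo$values
  s_count <- nrow(v); n_t <- ncol(v)
  bl0 <- estimate_baseline(kymo)
  vfill <- v
  for (i in seq_len(s_count)) vfill[i, is.na(v[i, ])] <- bl0$baseline[i]
  sm <- smooth_kymo_rows(vfill, kymo$adjacent_next, smooth_row_sigma)
  bl <- estimate_baseline(sm)
  if (bl$noise == 0 && max(sm - bl$baseline) <= 0)
    return(empty_trace_set(kymo))
  mask <- sm > bl$baseline + k_sigma * bl$noise
  comp <- kymo_components(mask, kymo$adjacent_next)
  raw_bl <- estimate_baseline(vfill)
  build_trace_set(comp, kymo, vfill, raw_bl$baseline, min_len_frames,
                  min_rows)
}

# smooth along rows within contiguous runs; circular when the whole
# cortex wraps without gaps
smooth_kymo_rows <- function(v, adjacent_next, sigma) {
  if (sigma <= 0) return(v)
  s_count <- nrow(v)
  breaks <- which(!adjacent_next)          # row i not adjacent to i+1
  if (length(breaks) == 0) {
    return(apply(v, 2, smooth1d, sigma = sigma, circular = TRUE))
  }
  # rotate so a break sits at the end, then split into runs
  out <- v
  ord <- c((breaks[1] + 1):s_count, seq_len(breaks[1]))
  if (breaks[1] == s_count) ord <- seq_len(s_count)
  adj <- adjacent_next[ord]
  run_end <- which(!adj)
  run_start <- c(1L, head(run_end, -1L) + 1L)
  for (r in seq_along(run_end)) {
    rows <- ord[run_start[r]:run_end[r]]
    if (length(rows) >= 2)
      out[rows, ] <- apply(v[rows, , drop = FALSE], 2, smooth1d,
                           sigma = sigma, circular = FALSE)
  }
  out
}

# connected components on a kymograph mask: 8-connectivity in
# (row, frame), with row adjacency given by adjacent_next (wrap across
# the seam, no crossing of excluded gaps)
kymo_components <- function(mask, adjacent_next) {
  s_count <- nrow(mask); n_t <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, s_count, n_t)
  if (length(idx) == 0) return(lab)
  id <- matrix(0L, s_count, n_t)
  id[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  rows <- ((idx - 1L) %% s_count) + 1L
  cols <- ((idx - 1L) %/% s_count) + 1L
  up_of <- function(r) {
    prev <- if (r == 1L) s_count else r - 1L
    if (adjacent_next[prev]) prev else NA_integer_
  }
  ups <- vapply(seq_len(s_count), up_of, integer(1))
  for (j in seq_along(idx)) {
    r <- rows[j]; cc <- cols[j]
    u <- ups[r]
    neigh <- integer(0)
    if (!is.na(u)) {
      neigh <- c(neigh, id[u, cc])
      if (cc > 1L) neigh <- c(neigh, id[u, cc - 1L])
      if (cc < n_t) neigh <- c(neigh, id[u, cc + 1L])
    }
    if (cc > 1L) neigh <- c(neigh, id[r, cc - 1L])
    for (k in neigh[neigh > 0L]) {
      ra <- find(j); rb <- find(k)
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

empty_trace_set <- function(kymo) {
  structure(list(),
            class = "TraceSet",
            meta = list(n_rows = nrow(kymo$values),
                        n_frames = ncol(kymo$values),
                        row_arclength_um = kymo$row_arclength_um,
                        adjacent_next = kymo$adjacent_next,
                        frame_interval_s = kymo$frame_interval_s,
                        pixel_size_nm = kymo$pixel_size_nm,
                        cell_id = kymo$cell_id,
                        compartment = kymo$compartment,
                        channel = kymo$channel))
}

build_trace_set <- function(lab, kymo, vals, baseline, min_len_frames,
                            min_rows) {
  out <- empty_trace_set(kymo)
  n_comp <- max(lab)
  if (n_comp == 0) return(out)
  dt <- kymo$frame_interval_s
  n_t <- ncol(vals)
  traces <- list()
  for (k in seq_len(n_comp)) {
    px <- which(lab == k)
    rows <- ((px - 1L) %% nrow(lab)) + 1L
    cols <- ((px - 1L) %/% nrow(lab)) + 1L
    t0 <- min(cols); t1 <- max(cols)
    urows <- sort(unique(rows))
    if ((t1 - t0 + 1L) < min_len_frames || length(urows) < min_rows) next
    above <- vals[px] - baseline[rows]
    prof <- vapply(t0:t1, function(t) sum(above[cols == t]), numeric(1))
    # intensity-weighted circular mean position along the cortex
    s_um <- kymo$row_arclength_um[rows]
    total_um <- max(kymo$row_arclength_um) +
      kymo$pixel_size_nm / 1000   # approximate circumference
    w <- pmax(above, 0); w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
    ang <- 2 * pi * s_um / total_um
    center_um <- (atan2(sum(w * sin(ang)), sum(w * cos(ang))) %% (2 * pi)) *
      total_um / (2 * pi)
    traces[[length(traces) + 1L]] <- list(
      rows = urows,
      t_start = t0, t_end = t1,
      lifetime_s = (t1 - t0 + 1L) * dt,
      censored_start = t0 == 1L,
      censored_end = t1 == n_t,
      intensity_profile = prof,
      peak = max(vals[px]),
      arclength_um = center_um)
  }
  attributes(traces) <- attributes(out)
  traces
}

#' Single-patch quality filter for detected traces
#'
#' Connected-component grouping merges two endocytic events into one
#' trace when their diffraction-limited footprints touch in (row,
#' frame) space, inflating apparent lifetimes. A human reading a
#' kymograph would not count such a double streak as one event; this
#' filter applies the same judgement algorithmically, discarding
#' candidate traces whose morphology is inconsistent with a single
#' immobile diffraction-limited patch:
#'
#' * `max_row_extent`: a single spot's above-threshold footprint along
#'   the cortex cannot exceed roughly the 99% width of its effective
#'   profile (about `5 * sigma_eff` rows, where `sigma_eff` combines
#'   the PSF and any row smoothing). Wider components are side-by-side
#'   merges.
#' * `min_row_extent`: conversely, a genuine patch spans at least the
#'   FWHM of the effective profile (about `2.4 * sigma_eff` rows).
#'   Narrower components are partial tails, typically of events
#'   centered inside an excluded cortex region (spatially censored).
#' * `profile_range = c(lo, hi)`: for plateau-like events, the
#'   per-frame summed intensity of a single patch fluctuates around a
#'   flat level. Frames where a second patch is co-resident push the
#'   profile above `hi` times its median (a double-intensity spike);
#'   a weak bridge joining two patches through a barely-detected
#'   intermediary drops it below `lo` times the median. Not meaningful
#'   for ramp-shaped events; pass `NULL` to disable.
#'
#' Censoring flags and all other trace fields are untouched; the
#' filter only drops whole traces.
#'
#' @param traces a [detect_traces()] `TraceSet`.
#' @param max_row_extent maximum number of distinct rows a trace may
#'   span (`NULL` to disable).
#' @param min_row_extent minimum number of distinct rows (`NULL` to
#'   disable).
#' @param profile_range length-2 numeric `c(lo, hi)` bounds on the
#'   per-frame intensity profile relative to its median (`NULL` to
#'   disable).
#' @return the filtered `TraceSet` (same metadata).
#' @export
filter_traces <- function(traces, max_row_extent = NULL,
                          min_row_extent = NULL,
                          profile_range = NULL) {
  assert_that(inherits(traces, "TraceSet"), "traces must be a TraceSet")
  if (!is.null(profile_range))
    assert_that(length(profile_range) == 2 &&
                  profile_range[1] < profile_range[2],
                "profile_range must be c(lo, hi) with lo < hi")
  keep <- vapply(traces, function(t) {
    if (!is.null(max_row_extent) && length(t$rows) > max_row_extent)
      return(FALSE)
    if (!is.null(min_row_extent) && length(t$rows) < min_row_extent)
      return(FALSE)
    if (!is.null(profile_range)) {
      med <- stats::median(t$intensity_profile)
      if (med > 0 &&
          (max(t$intensity_profile) > profile_range[2] * med ||
             min(t$intensity_profile) < profile_range[1] * med))
        return(FALSE)
    }
    TRUE
  }, logical(1))
  at <- attributes(traces)
  out <- traces[keep]
  attributes(out) <- at
  out
}

#' Flatten a TraceSet into a data.frame
#'
#' @param traces a [detect_traces()] result.
#' @return data.frame with one row per trace.
#' @export
traces_table <- function(traces) {
  meta <- attr(traces, "meta")
  if (length(traces) == 0)
    return(data.frame(cell_id = integer(0), compartment = character(0),
                      channel = character(0), row_min = integer(0),
                      row_max = integer(0), arclength_um = numeric(0),
                      t_start = integer(0), t_end = integer(0),
                      lifetime_s = numeric(0), peak = numeric(0),
                      censored_start = logical(0),
                      censored_end = logical(0), censored = logical(0)))
  data.frame(
    cell_id = if (is.null(meta$cell_id)) NA_integer_ else meta$cell_id,
    compartment = if (is.null(meta$compartment)) NA_character_ else meta$compartment,
    channel = if (is.null(meta$channel)) NA_character_ else meta$channel,
    row_min = vapply(traces, function(t) min(t$rows), integer(1)),
    row_max = vapply(traces, function(t) max(t$rows), integer(1)),
    arclength_um = vapply(traces, function(t) t$arclength_um, numeric(1)),
    t_start = vapply(traces, function(t) t$t_start, integer(1)),
    t_end = vapply(traces, function(t) t$t_end, integer(1)),
    lifetime_s = vapply(traces, function(t) t$lifetime_s, numeric(1)),
    peak = vapply(traces, function(t) t$peak, numeric(1)),
    censored_start = vapply(traces, function(t) t$censored_start, logical(1)),
    censored_end = vapply(traces, function(t) t$censored_end, logical(1)),
    censored = vapply(traces, function(t)
      t$censored_start || t$censored_end, logical(1)))
}
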
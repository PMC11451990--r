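#' Render ground-truth events into a noisy fluorescence movie
#'
#' Each event is an immobile isotropic Gaussian spot (standard deviation
#' `psf_sigma_px`) at its cortical or interior position, with the
#' configured temporal profile while alive. Background composes
#' additively: every pixel receives `background_out` (out-of-focus /
#' camera offset level) and pixels inside the cell receive
#' `background` cytoplasmic photons on top, so the expected interior
#' level is `background_out + background`. Spot photons add to that,
#' the whole frame is attenuated by global exponential
#' photobleaching, then Poisson-sampled, and Gaussian read noise is
#' added (camera gain fixed at 1 count/photon). Negative read-out values
#' are clipped at zero.
#'
#' @param events event table (rows for one channel; see
#'   [sample_events()]).
#' @param geometry a [make_cell_geometry()] result.
#' @param config the generating [sim_config()].
#' @param channel_name label stored on the output stack.
#' @param noise set `FALSE` to return the noiseless expected-photon
#'   movie (useful for photometric oracles).
#' @return A [frame_stack()].
#' @export
render_movie <- function(events, geometry, config, channel_name = "ch1",
                         noise = TRUE) {
  dt <- config$frame_interval_s
  n_t <- n_frames_for(config)
  ny <- geometry$ny; nx <- geometry$nx
  sigma <- config$psf_sigma_px
  inside <- geometry$mask > 0
  base <- matrix(config$background_out, ny, nx)
  base[inside] <- base[inside] + config$background
  peak_snr <- min(events$amplitude, Inf) /
    sqrt(max(config$background + config$background_out, 1))
  if (nrow(events) > 0 && peak_snr < 1)
    warning("expected peak SNR < 1; events will be near-invisible")

  # immobile spots: precompute each event's stamp once
  w <- ceiling(4 * sigma)
  stamps <- lapply(seq_len(nrow(events)), function(i) {
    yc <- events$y_px[i]; xc <- events$x_px[i]
    ys <- max(1L, floor(yc) - w):min(ny, ceiling(yc) + w)
    xs <- max(1L, floor(xc) - w):min(nx, ceiling(xc) + w)
    ky <- exp(-(ys - yc)^2 / (2 * sigma^2))
    kx <- exp(-(xs - xc)^2 / (2 * sigma^2))
    list(ys = ys, xs = xs, k = outer(ky, kx))
  })

  arr <- array(0, c(ny, nx, n_t))
  for (t in seq_len(n_t)) {
    tt <- (t - 1) * dt
    lam <- base
    alive <- which(events$t_birth_s <= tt & events$t_death_s > tt)
    for (i in alive) {
      a <- event_amplitude_at(events[i, ], tt, config)
      st <- stamps[[i]]
      lam[st$ys, st$xs] <- lam[st$ys, st$xs] + a * st$k
    }
    lam <- lam * exp(-config$bleach_rate_per_s * tt)
    if (noise) {
      fr <- stats::rpois(length(lam), lam)
      if (config$read_noise_sd > 0)
        fr <- fr + stats::rnorm(length(fr), 0, config$read_noise_sd)
      lam <- matrix(pmax(fr, 0), ny, nx)
    }
    arr[, , t] <- lam
  }
  frame_stack(arr, config$pixel_size_nm, dt, channel_name)
}

# expected amplitude of one event at absolute time tt
event_amplitude_at <- function(ev, tt, config) {
  a <- ev$amplitude
  if (ev$compartment %in% c("interior", "eisosome")) return(a)
  if (!is.null(config$two_stage)) {
    if (tt - ev$t_birth_s < config$two_stage[2]) a <- a * config$two_stage[1]
    return(a)
  }
  if (config$profile == "ramp") {
    u <- (tt - ev$t_birth_s) / (ev$t_death_s - ev$t_birth_s)
    a <- a * (1 - abs(2 * u - 1))
  }
  a
}

#' Simulate a complete budded-cell movie with ground truth
#'
#' Seeds the RNG from `config$seed`, builds the geometry, samples
#' events, and renders one stack per channel (a second channel is
#' rendered when `channel_offset_s` is configured). Identical seed and
#' config give a bit-identical ground-truth table and movie.
#'
#' @param config a [sim_config()].
#' @param neck_margin_px forwarded to [make_cell_geometry()].
#' @param noise forwarded to [render_movie()].
#' @return A `SimulatedMovie` list: `stacks` (named list of
#'   [frame_stack()]), `events` (ground-truth table), `geometry`,
#'   `mask`, `config`.
#' @export
simulate_movie <- function(config, neck_margin_px = 5, noise = TRUE) {
  set.seed(config$seed)
  geometry <- make_cell_geometry(config, neck_margin_px = neck_margin_px)
  events <- sample_events(config, geometry)
  if (!is.null(config$channel_offset_s))
    events <- add_offset_channel(events, config)
  stacks <- list(ch1 = render_movie(events[events$channel == 1L, ,
                                           drop = FALSE],
                                    geometry, config, "ch1", noise = noise))
  if (!is.null(config$channel_offset_s))
    stacks$ch2 <- render_movie(events[events$channel == 2L, , drop = FALSE],
                               geometry, config, "ch2", noise = noise)
  structure(list(stacks = stacks, events = events, geometry = geometry,
                 mask = geometry$mask, config = config),
            class = "SimulatedMovie")
}

#' Write a simulated movie, mask, ground truth and config to disk
#'
#' Emits one multi-page TIFF per channel (with calibration sidecars),
#' the label mask as a single-page TIFF, the ground-truth event table as
#' CSV, and a JSON echo of the configuration.
#'
#' @param sim a [simulate_movie()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in names(sim$stacks))
    write_stack(sim$stacks[[ch]], file.path(dir, paste0("movie_", ch, ".tif")))
  write_mask(sim$mask, file.path(dir, "mask.tif"))
  utils::write.csv(sim$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  cfg <- unclass(sim$config)
  cfg$two_stage <- if (is.null(cfg$two_stage)) NULL else as.numeric(cfg$two_stage)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
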
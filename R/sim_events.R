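#' Sample ground-truth endocytic events for a simulated movie
#'
#' Event births follow a homogeneous Poisson process along each
#' compartment's retained cortex: the expected number of initiations
#' inside the movie is `rate x retained_length_um x duration_min`.
#' Births are also drawn over a pre-movie extension window so that
#' events already in progress at frame 1 appear (and are flagged
#' censored), matching what a microscopist sees when the shutter opens.
#' Lifetimes come from the configured family, truncated at two frame
#' intervals (shorter events cannot produce a measurable streak).
#'
#' Uses the current RNG state; [simulate_movie()] seeds it from
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param geometry a [make_cell_geometry()] result for the same config.
#' @return data.frame of `EventRecord` rows: `event_id`, `cell_id`,
#'   `compartment`, `arclength_um`, `y_px`, `x_px`, `t_birth_s`,
#'   `t_death_s`, `channel`, `amplitude`, `censored_start_truth`,
#'   `censored_end_truth`, `censored_truth`. Events visible in no frame
#'   are dropped; the empty data.frame is a valid result.
#' @export
sample_events <- function(config, geometry) {
  dt <- config$frame_interval_s
  n_frames <- n_frames_for(config)
  t_last <- (n_frames - 1) * dt
  lengths_um <- contour_lengths_um(geometry)
  rows <- list()
  for (comp in c("mother", "daughter")) {
    rate <- config$rate[[comp]]                  # events / um / min
    if (rate <= 0) next
    mean_s <- config$lifetime_mean_s[[comp]]
    cv <- config$lifetime_cv[[comp]]
    family <- config$lifetime_family[[comp]]
    ext_s <- mean_s * (1 + 5 * cv)               # pre-movie window
    window_min <- (config$duration_s + ext_s) / 60
    n <- stats::rpois(1, rate * lengths_um[[comp]] * window_min)
    if (n == 0) next
    birth <- stats::runif(n, -ext_s, config$duration_s)
    life <- draw_lifetimes(n, mean_s, cv, family, min_s = 2 * dt)
    death <- birth + life
    s_um <- stats::runif(n, 0, lengths_um[[comp]])
    amp <- if (comp == "daughter") config$amplitude_daughter
           else config$amplitude
    pos <- arc_position(geometry$arcs[[comp]], s_um)
    rows[[comp]] <- data.frame(
      compartment = comp, arclength_um = s_um,
      y_px = pos$y, x_px = pos$x,
      t_birth_s = birth, t_death_s = death,
      amplitude = amp)
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev)) {
    ev <- data.frame(compartment = character(0), arclength_um = numeric(0),
                     y_px = numeric(0), x_px = numeric(0),
                     t_birth_s = numeric(0), t_death_s = numeric(0),
                     amplitude = numeric(0))
  }
  # immobile confounders: cytoplasmic puncta and eisosome-like cortical
  # structures span the whole movie
  if (config$n_interior_puncta > 0) {
    margin <- max(config$interior_margin_px, ceiling(2 * config$psf_sigma_px))
    p <- sample_interior_positions(geometry, config$n_interior_puncta, margin)
    ev <- rbind(ev, data.frame(
      compartment = "interior", arclength_um = NA_real_,
      y_px = p$y, x_px = p$x, t_birth_s = -Inf, t_death_s = Inf,
      amplitude = config$puncta_amplitude))
  }
  if (config$n_eisosomes > 0) {
    s <- stats::runif(config$n_eisosomes, 0,
                      contour_lengths_um(geometry)[["mother"]])
    pos <- arc_position(geometry$arcs$mother, s)
    ev <- rbind(ev, data.frame(
      compartment = "eisosome", arclength_um = s,
      y_px = pos$y, x_px = pos$x, t_birth_s = -Inf, t_death_s = Inf,
      amplitude = config$puncta_amplitude))
  }
  # keep events visible in at least one sampled frame
  visible <- ev$t_death_s > 0 & ev$t_birth_s <= t_last
  ev <- ev[visible, , drop = FALSE]
  ev$channel <- rep(1L, nrow(ev))
  ev$cell_id <- rep(1L, nrow(ev))
  if (nrow(ev) > 0) {
    o <- order(ev$t_birth_s)
    ev <- ev[o, , drop = FALSE]
  }
  ev$event_id <- seq_len(nrow(ev))
  ev$censored_start_truth <- ev$t_birth_s <= 0
  ev$censored_end_truth <- ev$t_death_s > t_last
  ev$censored_truth <- ev$censored_start_truth | ev$censored_end_truth
  rownames(ev) <- NULL
  ev[, c("event_id", "cell_id", "compartment", "arclength_um", "y_px",
         "x_px", "t_birth_s", "t_death_s", "channel", "amplitude",
         "censored_start_truth", "censored_end_truth", "censored_truth")]
}

# number of frames implied by duration and frame interval
n_frames_for <- function(config) {
  as.integer(round(config$duration_s / config$frame_interval_s))
}

draw_lifetimes <- function(n, mean_s, cv, family, min_s) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- 2L * (n - length(out)) + 10L
    x <- if (family == "gaussian") {
      stats::rnorm(m, mean_s, cv * mean_s)
    } else {
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(m, log(mean_s) - sdlog^2 / 2, sdlog)
    }
    out <- c(out, x[x >= min_s])
  }
  out[seq_len(n)]
}

#' Duplicate cortical events into a second channel with timing offsets
#'
#' Models a second fluorescently tagged protein recruited to the same
#' endocytic sites with shifted arrival/departure times (e.g. an
#' early-arriving protein followed by a later module).
#'
#' @param events event table from [sample_events()].
#' @param config a [sim_config()] with non-`NULL` `channel_offset_s`.
#' @param n_frames movie length in frames.
#' @return the combined two-channel event table.
#' @export
add_offset_channel <- function(events, config, n_frames = n_frames_for(config)) {
  assert_that(!is.null(config$channel_offset_s),
              "config$channel_offset_s is not set")
  off <- config$channel_offset_s
  dt <- config$frame_interval_s
  t_last <- (n_frames - 1) * dt
  cort <- events[events$compartment %in% c("mother", "daughter"), ,
                 drop = FALSE]
  ch2 <- cort
  ch2$t_birth_s <- cort$t_birth_s + off[1]
  ch2$t_death_s <- cort$t_death_s + off[2]
  ch2 <- ch2[ch2$t_death_s > ch2$t_birth_s &
               ch2$t_death_s > 0 & ch2$t_birth_s <= t_last, , drop = FALSE]
  ch2$channel <- 2L
  ch2$censored_start_truth <- ch2$t_birth_s <= 0
  ch2$censored_end_truth <- ch2$t_death_s > t_last
  ch2$censored_truth <- ch2$censored_start_truth | ch2$censored_end_truth
  out <- rbind(events, ch2)
  rownames(out) <- NULL
  out
}
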
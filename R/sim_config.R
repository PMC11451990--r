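#' Configuration for the synthetic budded-cell movie generator
#'
#' Defines a single budded yeast cell (two overlapping disks joined at a
#' neck) with cortical endocytic events initiating as a Poisson process
#' per unit retained cortex length, at a higher rate on the daughter
#' (bud) than on the mother, mirroring the strong mother/daughter
#' asymmetry of CME site initiation in polarized cells.
#'
#' Default rates give of order ten daughter events per 3-minute movie on
#' a medium bud, the sparse regime in which individual kymograph traces
#' remain resolvable (crowded cortex regions, like the bud neck, defeat
#' trace-level analysis, which is why the neck is excluded upstream).
#'
#' @param mother_radius_px,daughter_radius_px lobe radii in pixels;
#'   daughter must not exceed mother.
#' @param neck_halfwidth_px half-width of the mother/daughter junction
#'   in pixels (must be smaller than the daughter radius).
#' @param rate_mother,rate_daughter event initiation rates in
#'   events per micrometer of cortex per minute.
#' @param lifetime_mean_s,lifetime_cv mean lifetime (s) and coefficient
#'   of variation per compartment, as length-1 values (shared) or named
#'   vectors `c(mother = , daughter = )`.
#' @param lifetime_family `"gaussian"` (truncated at two frame
#'   intervals; regular, daughter-like dynamics) or `"lognormal"`
#'   (heavy-tailed; irregular, mother-like dynamics). Length-1 or named
#'   per compartment.
#' @param amplitude peak photons of one event above background.
#' @param amplitude_daughter optional daughter-specific amplitude
#'   (defaults to `amplitude`).
#' @param profile temporal intensity profile: `"plateau"` (constant
#'   while alive) or `"ramp"` (triangular rise and fall).
#' @param two_stage optional `c(low_fraction, low_duration_s)` giving a
#'   low-intensity stage of that relative amplitude and duration at the
#'   start of every event (Pan1-like dynamics).
#' @param channel_offset_s optional `c(birth, death)` offsets in seconds
#'   applied to a second channel's copy of every cortical event.
#' @param psf_sigma_px point-spread-function standard deviation in
#'   pixels (1.3 px at 65 nm/px approximates a high-NA widefield PSF).
#' @param background photons per pixel per frame inside the cell.
#' @param background_out photons per pixel per frame outside cells
#'   (camera floor / stray light).
#' @param read_noise_sd Gaussian read noise standard deviation (counts).
#' @param bleach_rate_per_s global exponential photobleaching constant.
#' @param n_interior_puncta immobile cytoplasmic puncta per cell.
#' @param interior_margin_px minimum distance of interior puncta from
#'   either lobe's cortex (keeps cytoplasmic spots unambiguously
#'   non-cortical).
#' @param n_eisosomes immobile cortical puncta on the mother cortex.
#' @param puncta_amplitude peak photons of interior/eisosome puncta.
#' @param pixel_size_nm,frame_interval_s,duration_s acquisition
#'   calibration and movie length.
#' @param seed RNG seed controlling every random draw of the simulation.
#' @return A validated `SimulationConfig` (list).
#' @export
sim_config <- function(mother_radius_px = 32,
                       daughter_radius_px = 22,
                       neck_halfwidth_px = 7,
                       rate_mother = 0.09,
                       rate_daughter = 0.45,
                       lifetime_mean_s = c(mother = 30, daughter = 30),
                       lifetime_cv = c(mother = 0.2, daughter = 0.2),
                       lifetime_family = c(mother = "gaussian",
                                           daughter = "gaussian"),
                       amplitude = 50,
                       amplitude_daughter = NULL,
                       profile = c("plateau", "ramp"),
                       two_stage = NULL,
                       channel_offset_s = NULL,
                       psf_sigma_px = 1.3,
                       background = 10,
                       background_out = 2,
                       read_noise_sd = 1.5,
                       bleach_rate_per_s = 0.001,
                       n_interior_puncta = 0,
                       interior_margin_px = 10,
                       n_eisosomes = 0,
                       puncta_amplitude = 60,
                       pixel_size_nm = 65,
                       frame_interval_s = 1.0,
                       duration_s = 180,
                       seed = 1L) {
  profile <- match.arg(profile)
  per_comp <- function(v, what) {
    if (length(v) == 1L && is.null(names(v)))
      v <- c(mother = unname(v), daughter = unname(v))
    assert_that(all(c("mother", "daughter") %in% names(v)),
                sprintf("%s must be shared or named per compartment", what))
    v[c("mother", "daughter")]
  }
  cfg <- list(
    mother_radius_px = mother_radius_px,
    daughter_radius_px = daughter_radius_px,
    neck_halfwidth_px = neck_halfwidth_px,
    rate = c(mother = rate_mother, daughter = rate_daughter),
    lifetime_mean_s = per_comp(lifetime_mean_s, "lifetime_mean_s"),
    lifetime_cv = per_comp(lifetime_cv, "lifetime_cv"),
    lifetime_family = per_comp(lifetime_family, "lifetime_family"),
    amplitude = amplitude,
    amplitude_daughter = if (is.null(amplitude_daughter)) amplitude
                         else amplitude_daughter,
    profile = profile,
    two_stage = two_stage,
    channel_offset_s = channel_offset_s,
    psf_sigma_px = psf_sigma_px,
    background = background,
    background_out = background_out,
    read_noise_sd = read_noise_sd,
    bleach_rate_per_s = bleach_rate_per_s,
    n_interior_puncta = n_interior_puncta,
    interior_margin_px = interior_margin_px,
    n_eisosomes = n_eisosomes,
    puncta_amplitude = puncta_amplitude,
    pixel_size_nm = pixel_size_nm,
    frame_interval_s = frame_interval_s,
    duration_s = duration_s,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$mother_radius_px > 0 && cfg$daughter_radius_px > 0,
              "radii must be positive")
  assert_that(cfg$daughter_radius_px <= cfg$mother_radius_px,
              "daughter radius must not exceed mother radius")
  assert_that(cfg$neck_halfwidth_px > 0 &&
                cfg$neck_halfwidth_px < cfg$daughter_radius_px,
              "neck half-width must be positive and smaller than the daughter radius")
  assert_that(all(cfg$rate >= 0), "rates must be non-negative")
  assert_that(all(cfg$lifetime_mean_s > 0), "lifetime means must be positive")
  assert_that(all(cfg$lifetime_cv > 0 & cfg$lifetime_cv < 1),
              "lifetime CV must lie in (0, 1)")
  assert_that(all(cfg$lifetime_family %in% c("gaussian", "lognormal")),
              "lifetime_family must be 'gaussian' or 'lognormal'")
  assert_that(cfg$psf_sigma_px > 0, "psf_sigma_px must be positive")
  assert_that(cfg$pixel_size_nm > 0 && cfg$frame_interval_s > 0 &&
                cfg$duration_s > 0, "calibration values must be positive")
  assert_that(cfg$background >= 0 && cfg$background_out >= 0 &&
                cfg$read_noise_sd >= 0 && cfg$bleach_rate_per_s >= 0,
              "noise parameters must be non-negative")
  if (!is.null(cfg$two_stage))
    assert_that(length(cfg$two_stage) == 2L && cfg$two_stage[1] > 0 &&
                  cfg$two_stage[1] < 1 && cfg$two_stage[2] > 0,
                "two_stage must be c(low_fraction in (0,1), low_duration_s > 0)")
  if (!is.null(cfg$channel_offset_s))
    assert_that(length(cfg$channel_offset_s) == 2L,
                "channel_offset_s must be c(birth_offset, death_offset)")
  invisible(cfg)
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat(sprintf(paste0("SimulationConfig: mother r=%g px, daughter r=%g px, ",
                     "neck %g px\n  rates %.3g/%.3g ev/um/min (M/D), ",
                     "lifetimes %g/%g s, %g s movie @ %g s/frame, seed %d\n"),
              x$mother_radius_px, x$daughter_radius_px, x$neck_halfwidth_px,
              x$rate["mother"], x$rate["daughter"],
              x$lifetime_mean_s["mother"], x$lifetime_mean_s["daughter"],
              x$duration_s, x$frame_interval_s, x$seed))
  invisible(x)
}
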
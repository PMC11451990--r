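#' Analyze one movie: contours, kymographs, traces, summaries
#'
#' End-to-end single-movie analysis: segment (or accept an external
#' label mask), pair mother/daughter lobes, extract neck-excluded
#' cortical contours, build one circumferential kymograph per
#' compartment and channel, detect traces, and summarize lifetimes and
#' initiation frequencies.
#'
#' @param stacks a [frame_stack()] or named list of them (channels).
#' @param mask optional integer label mask; when `NULL` the built-in
#'   Otsu/watershed segmenter runs on the blurred mean projection.
#' @param step_px contour sample spacing.
#' @param band_width_px odd cortical band width; `NULL` chooses it from
#'   the MIP via [band_width_from_mip()].
#' @param neck_margin_px extra cortex excluded around the neck; `NULL`
#'   defaults to the band width so the two compartments' bands cannot
#'   overlap.
#' @param reduction band reduction for kymographs.
#' @param k_sigma,min_len_frames,min_rows,smooth_row_sigma trace
#'   detection parameters (see [detect_traces()]).
#' @param censor_policy lifetime summary policy (see
#'   [summarize_lifetimes()]).
#' @param median_radius_px,erosion_radius_px blur parameters for the
#'   built-in segmenter.
#' @return A `CMEAnalysis` list: `mask`, `cells`, `contours`
#'   (per cell/compartment), `band_width_px`, `kymographs`, `traces`,
#'   `report` (stacked `LifetimeSummary` rows), `params`.
#' @export
analyze_movie <- function(stacks, mask = NULL, step_px = 1,
                          band_width_px = NULL, neck_margin_px = NULL,
                          reduction = "max", k_sigma = 4,
                          min_len_frames = 3, min_rows = 1,
                          smooth_row_sigma = 1,
                          censor_policy = "exclude",
                          median_radius_px = 2, erosion_radius_px = 1) {
  if (inherits(stacks, "FrameStack")) stacks <- list(ch1 = stacks)
  s1 <- stacks[[1]]
  mip <- max_intensity_projection(s1)
  if (is.null(mask)) {
    blurred <- blur_frame(mean_intensity_projection(s1),
                          median_radius_px, erosion_radius_px)
    mask <- segment_cells(blurred)
  } else {
    mask <- validate_label_mask(mask)
  }
  pairing <- pair_mother_daughter(mask)
  assert_that(length(pairing$cells) >= 1, "no budded cell found in mask")
  duration_min <- n_frames(s1) * s1$frame_interval_s / 60
  contours <- list(); kymos <- list(); traces <- list()
  report <- NULL
  for (cell in pairing$cells) {
    comp_labels <- c(mother = cell$mother_label,
                     daughter = cell$daughter_label)
    raw <- lapply(names(comp_labels), function(comp)
      extract_contour(mask, comp_labels[[comp]], step_px = step_px,
                      pixel_size_nm = s1$pixel_size_nm,
                      compartment = comp, cell_id = cell$cell_id))
    names(raw) <- names(comp_labels)
    width <- if (is.null(band_width_px))
      band_width_from_mip(mip, raw$mother) else band_width_px
    margin <- if (is.null(neck_margin_px)) width else neck_margin_px
    cc <- lapply(raw, exclude_neck, neck_pixels = cell$neck_pixels,
                 margin_px = margin)
    contours[[paste0("cell", cell$cell_id)]] <- cc
    for (comp in names(cc)) {
      for (ch in names(stacks)) {
        key <- paste("cell", cell$cell_id, comp, ch, sep = "_")
        km <- build_kymograph(stacks[[ch]], cc[[comp]], width_px = width,
                              reduction = reduction)
        tr <- detect_traces(km, k_sigma = k_sigma,
                            min_len_frames = min_len_frames,
                            min_rows = min_rows,
                            smooth_row_sigma = smooth_row_sigma)
        kymos[[key]] <- km
        traces[[key]] <- tr
        report <- rbind(report,
                        summarize_lifetimes(tr, retained_um(cc[[comp]]),
                                            duration_min,
                                            censor_policy = censor_policy,
                                            label = ch))
      }
    }
  }
  structure(list(mask = mask, cells = pairing$cells,
                 singletons = pairing$singletons,
                 contours = contours, band_width_px = width,
                 kymographs = kymos, traces = traces, report = report,
                 params = list(step_px = step_px,
                               band_width_px = band_width_px,
                               neck_margin_px = neck_margin_px,
                               reduction = reduction, k_sigma = k_sigma,
                               min_len_frames = min_len_frames,
                               min_rows = min_rows,
                               smooth_row_sigma = smooth_row_sigma,
                               censor_policy = censor_policy)),
            class = "CMEAnalysis")
}

#' @export
print.CMEAnalysis <- function(x, ...) {
  cat(sprintf("CMEAnalysis: %d budded cell(s), band %d px\n",
              length(x$cells), x$band_width_px))
  print(x$report)
  invisible(x)
}

REPORT_SCHEMA_VERSION <- "1.0"

#' Build a run configuration
#'
#' A flat parameter list with dotted keys (`module.parameter`) covering
#' every stage. Values given here override defaults; command-line flags
#' override both (precedence: flags > config file > defaults).
#'
#' @param ... dotted-key overrides, e.g. `trace.k_sigma = 5`.
#' @return named list of class `RunConfig`.
#' @export
run_config <- function(...) {
  defaults <- list(
    input.movie = NA_character_, input.movie2 = NA_character_,
    input.mask = NA_character_,
    calib.pixel_size_nm = 65, calib.frame_interval_s = 1.0,
    segment.median_radius_px = 2, segment.erosion_radius_px = 1,
    contour.step_px = 1, contour.neck_margin_px = NA_real_,
    kymo.band_width_px = NA_real_, kymo.reduction = "max",
    trace.k_sigma = 4, trace.min_len_frames = 3, trace.min_rows = 1,
    trace.smooth_row_sigma = 1, trace.censor_policy = "exclude",
    out.dir = ".", seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  assert_that(length(unknown) == 0,
              sprintf("unknown config keys: %s",
                      paste(unknown, collapse = ", ")))
  defaults[names(over)] <- over
  assert_that(defaults$calib.pixel_size_nm > 0 &&
                defaults$calib.frame_interval_s > 0,
              "physical calibrations must be positive")
  structure(defaults, class = "RunConfig")
}

#' Read a run configuration from a flat `key = value` text file
#' @param path config file; lines like `trace.k_sigma = 5`, `#` comments.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2L
  assert_that(!any(bad), "config lines must be 'key = value'")
  vals <- lapply(kv, function(p) {
    v <- utils::type.convert(p[2], as.is = TRUE)
    v
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  do.call(run_config, vals)
}

#' Run the full movie-to-report pipeline from a configuration
#'
#' Reads the movie (and mask, if given), runs [analyze_movie()], and
#' writes traces, summaries, and a machine-readable parameter log to
#' the output directory. Deterministic given the same inputs and seed.
#'
#' @param config a [run_config()].
#' @param stacks optional in-memory stacks (bypasses `input.movie`).
#' @param mask optional in-memory mask (bypasses `input.mask`).
#' @return the [analyze_movie()] result, invisibly.
#' @export
run_pipeline <- function(config, stacks = NULL, mask = NULL) {
  assert_that(inherits(config, "RunConfig"), "config must be a RunConfig")
  set.seed(as.integer(config$seed))
  if (is.null(stacks)) {
    assert_that(!is.na(config$input.movie), "no input movie configured")
    stacks <- list(ch1 = read_stack(config$input.movie,
                                    config$calib.pixel_size_nm,
                                    config$calib.frame_interval_s))
    if (!is.na(config$input.movie2))
      stacks$ch2 <- read_stack(config$input.movie2,
                               config$calib.pixel_size_nm,
                               config$calib.frame_interval_s)
  }
  if (is.null(mask) && !is.na(config$input.mask))
    mask <- read_mask(config$input.mask)
  na_null <- function(v) if (is.na(v)) NULL else v
  res <- analyze_movie(
    stacks, mask = mask,
    step_px = config$contour.step_px,
    band_width_px = na_null(config$kymo.band_width_px),
    neck_margin_px = na_null(config$contour.neck_margin_px),
    reduction = config$kymo.reduction,
    k_sigma = config$trace.k_sigma,
    min_len_frames = config$trace.min_len_frames,
    min_rows = config$trace.min_rows,
    smooth_row_sigma = config$trace.smooth_row_sigma,
    censor_policy = config$trace.censor_policy,
    median_radius_px = config$segment.median_radius_px,
    erosion_radius_px = config$segment.erosion_radius_px)
  dir.create(config$out.dir, recursive = TRUE, showWarnings = FALSE)
  tr_all <- do.call(rbind, lapply(names(res$traces), function(k) {
    tab <- traces_table(res$traces[[k]])
    if (nrow(tab) > 0) tab$source <- k
    tab
  }))
  write_versioned_csv(tr_all, file.path(config$out.dir, "traces.csv"))
  write_versioned_csv(res$report, file.path(config$out.dir, "report.csv"))
  jsonlite::write_json(
    c(unclass(config), list(schema_version = REPORT_SCHEMA_VERSION,
                            band_width_px_used = res$band_width_px)),
    file.path(config$out.dir, "params.json"), auto_unbox = TRUE,
    digits = NA, null = "null")
  invisible(res)
}

#' Write a CSV with a schema-version column
#' @keywords internal
#' @noRd
write_versioned_csv <- function(df, path) {
  if (is.null(df)) df <- data.frame()
  if (nrow(df) > 0) df$schema_version <- REPORT_SCHEMA_VERSION
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a versioned report CSV, rejecting unknown major versions
#' @param path CSV written by [run_pipeline()].
#' @export
read_report_csv <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df) > 0 && "schema_version" %in% names(df)) {
    major <- sub("\\..*$", "", df$schema_version[1])
    ours <- sub("\\..*$", "", REPORT_SCHEMA_VERSION)
    assert_that(identical(major, ours),
                sprintf("unsupported report schema version %s",
                        df$schema_version[1]))
  }
  df
}
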
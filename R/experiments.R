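# Self-contained validation experiments: each simulates movies with
# known ground truth, runs the analysis pipeline on them, and reports
# how well the pipeline recovers the truth. Used by the test suite and
# by scripts/acceptance.R.

#' Precompute the analysis context shared by replicate simulations
#'
#' Replicates of one configuration share the same cell geometry, so the
#' label mask, mother/daughter pairing, and neck-excluded contours are
#' computed once and reused. The ground-truth mask enters the analysis
#' as an external segmentation, the pipeline's first-class input path.
#'
#' @param config a [sim_config()].
#' @param band_width_px odd kymograph band width.
#' @param neck_margin_px neck exclusion margin (defaults to the band
#'   width).
#' @param step_px contour sampling step.
#' @return list with `geometry`, `contours` (mother/daughter, neck
#'   excluded), `retained_um`, `width`.
#' @export
sim_context <- function(config, band_width_px = 5, neck_margin_px = NULL,
                        step_px = 1) {
  if (is.null(neck_margin_px)) neck_margin_px <- band_width_px
  geometry <- make_cell_geometry(config, neck_margin_px = neck_margin_px)
  pairing <- pair_mother_daughter(geometry$mask)
  cell <- pairing$cells[[1]]
  labs <- c(mother = cell$mother_label, daughter = cell$daughter_label)
  contours <- lapply(names(labs), function(comp)
    exclude_neck(
      extract_contour(geometry$mask, labs[[comp]], step_px = step_px,
                      pixel_size_nm = config$pixel_size_nm,
                      compartment = comp, cell_id = 1L),
      cell$neck_pixels, neck_margin_px))
  names(contours) <- names(labs)
  list(geometry = geometry, contours = contours,
       retained_um = vapply(contours, retained_um, numeric(1)),
       width = band_width_px)
}

# detect traces on one compartment of one simulated stack
detect_on <- function(stack, ctx, comp, k_sigma = 4, min_len_frames = 3,
                      smooth_row_sigma = 1) {
  km <- build_kymograph(stack, ctx$contours[[comp]], width_px = ctx$width)
  detect_traces(km, k_sigma = k_sigma, min_len_frames = min_len_frames,
                smooth_row_sigma = smooth_row_sigma)
}

# kymograph row index (retained space) nearest an image position
truth_row <- function(contour, y, x) {
  keep <- which(!contour$excluded)
  d2 <- (contour$points$y[keep] - y)^2 + (contour$points$x[keep] - x)^2
  which.min(d2)
}

# visible frame range (1-based) of a ground-truth event
truth_frames <- function(ev, dt, n_t) {
  k0 <- max(0, ceiling(ev$t_birth_s / dt))
  if (ev$t_birth_s <= 0) k0 <- 0
  k1 <- min(n_t - 1, ceiling(ev$t_death_s / dt) - 1)
  c(k0 + 1L, k1 + 1L)
}

#' Lifetime recovery on simulated daughter-cortex events
#'
#' Simulates replicate single-budded-cell movies until the pooled
#' number of detected daughter events reaches `target_events`, then
#' compares the recovered uncensored lifetime mean and CV to the
#' generating distribution. Events are pooled across replicates
#' because the number requested far exceeds what one 3-minute movie of
#' one bud can hold while traces stay individually resolvable (the
#' same crowding argument that excludes the bud neck from analysis).
#'
#' The default rate puts the daughter cortex in the sparse regime
#' where individual traces stay resolvable; traces that connected-
#' component grouping nevertheless merges (or partial tails of events
#' centered in the excluded neck margin) are removed with the
#' single-patch filter ([filter_traces()]), with bounds derived from
#' the effective spot width `sigma_eff = sqrt(psf^2 + smoothing^2)`
#' and from the flatness of a single plateau-profile event.
#'
#' @param seed integer seed for the whole experiment.
#' @param target_events minimum pooled daughter event count.
#' @param lifetime_mean_s,lifetime_cv generating lifetime distribution.
#' @param rate_daughter daughter initiation rate (events/um/min).
#' @param k_sigma detection threshold.
#' @param profile_range single-patch profile bounds (see
#'   [filter_traces()]).
#' @return list with recovered `mean_s`, `sd_s`, `cv_percent`,
#'   `n_events`, the generating `truth_mean_s`, `truth_cv_percent`,
#'   and `n_replicates`.
#' @export
lifetime_recovery_experiment <- function(seed = 1,
                                         target_events = 150,
                                         lifetime_mean_s = 30,
                                         lifetime_cv = 0.2,
                                         rate_daughter = 0.2,
                                         k_sigma = 4,
                                         profile_range = c(0.4, 1.6)) {
  cfg0 <- sim_config(rate_daughter = rate_daughter, rate_mother = 0.09,
                     lifetime_mean_s = lifetime_mean_s,
                     lifetime_cv = lifetime_cv, seed = 1L)
  ctx <- sim_context(cfg0)
  expected <- rate_daughter *
    contour_lengths_um(ctx$geometry)[["daughter"]] * cfg0$duration_s / 60
  n_rep <- ceiling(target_events / expected)
  life <- numeric(0)
  i <- 0
  while ((length(life) < target_events || i < n_rep) && i < 4 * n_rep) {
    i <- i + 1
    cfg <- cfg0
    cfg$seed <- derive_seed(seed, sprintf("lifetime%d", i))
    sim <- simulate_movie(cfg)
    tr <- detect_on(sim$stacks$ch1, ctx, "daughter", k_sigma = k_sigma)
    sigma_eff <- sqrt(cfg0$psf_sigma_px^2 + 1)   # detection smooths rows
    tr <- filter_traces(tr, max_row_extent = floor(5 * sigma_eff),
                        min_row_extent = floor(2.4 * sigma_eff),
                        profile_range = profile_range)
    tab <- traces_table(tr)
    life <- c(life, tab$lifetime_s[!tab$censored])
  }
  list(mean_s = mean(life), sd_s = stats::sd(life),
       cv_percent = 100 * stats::sd(life) / mean(life),
       n_events = length(life),
       truth_mean_s = lifetime_mean_s,
       truth_cv_percent = 100 * lifetime_cv,
       n_replicates = i)
}

#' Recovery of the daughter:mother initiation-rate ratio
#'
#' Simulates replicates at a configured rate ratio and recovers it as
#' the ratio of detected event frequencies, each normalized per
#' retained micrometer of cortex per minute. Short lifetimes are used
#' so that traces stay well separated at the daughter's higher density;
#' frequency does not depend on the lifetime distribution. Replicates
#' accumulate until the mother (the sparser compartment, which limits
#' the counting precision) reaches `target_mother_events`.
#'
#' @param ratio configured daughter:mother rate ratio.
#' @param seed experiment seed.
#' @param rate_daughter daughter rate (events/um/min).
#' @param target_mother_events pooled mother event floor.
#' @param max_rep replicate cap.
#' @return list with `ratio_recovered`, `ratio_truth`, per-compartment
#'   frequencies and counts, and `n_replicates`.
#' @export
frequency_ratio_experiment <- function(ratio, seed = 1,
                                       rate_daughter = 0.6,
                                       target_mother_events = 200,
                                       max_rep = 100) {
  cfg0 <- sim_config(rate_daughter = rate_daughter,
                     rate_mother = rate_daughter / ratio,
                     lifetime_mean_s = 12, lifetime_cv = 0.2, seed = 1L)
  ctx <- sim_context(cfg0)
  counts <- c(mother = 0, daughter = 0)
  i <- 0
  while (counts[["mother"]] < target_mother_events && i < max_rep) {
    i <- i + 1
    cfg <- cfg0
    cfg$seed <- derive_seed(seed, sprintf("freq%g_%d", ratio, i))
    sim <- simulate_movie(cfg)
    for (comp in c("mother", "daughter")) {
      tr <- detect_on(sim$stacks$ch1, ctx, comp)
      counts[[comp]] <- counts[[comp]] + length(tr)
    }
  }
  duration_min <- i * cfg0$duration_s / 60
  freq <- counts / (ctx$retained_um[c("mother", "daughter")] * duration_min)
  list(ratio_recovered = unname(freq[["daughter"]] / freq[["mother"]]),
       ratio_truth = ratio,
       frequency_mother = unname(freq[["mother"]]),
       frequency_daughter = unname(freq[["daughter"]]),
       n_mother = unname(counts[["mother"]]),
       n_daughter = unname(counts[["daughter"]]),
       n_replicates = i)
}

#' Censoring-flag correctness against ground truth
#'
#' Over seeded replicates, ground-truth events are matched one-to-one
#' to detected traces (nearest cortex row, overlapping time) and the
#' censored flags of resolvable matches - those whose detected
#' temporal extent agrees with the truth within `extent_tol_frames` -
#' are scored. Events overlapping the movie boundary must be flagged;
#' interior events must not be.
#'
#' @param seed experiment seed.
#' @param n_rep replicate count.
#' @param row_tol,extent_tol_frames matching tolerances.
#' @return list with `boundary_total`, `boundary_flagged`,
#'   `interior_total`, `interior_false_flags`, `n_unresolved`.
#' @export
censoring_experiment <- function(seed = 1, n_rep = 20, row_tol = 4,
                                 extent_tol_frames = 3) {
  cfg0 <- sim_config(rate_daughter = 0.25, rate_mother = 0.15,
                     lifetime_mean_s = 35, lifetime_cv = 0.3, seed = 1L)
  ctx <- sim_context(cfg0)
  dt <- cfg0$frame_interval_s
  n_t <- n_frames_for(cfg0)
  tot <- c(boundary_total = 0, boundary_flagged = 0,
           interior_total = 0, interior_false_flags = 0, n_unresolved = 0)
  for (r in seq_len(n_rep)) {
    cfg <- cfg0
    cfg$seed <- derive_seed(seed, sprintf("censor%d", r))
    sim <- simulate_movie(cfg)
    for (comp in c("mother", "daughter")) {
      tr <- detect_on(sim$stacks$ch1, ctx, comp)
      ev <- sim$events[sim$events$compartment == comp, , drop = FALSE]
      if (nrow(ev) == 0 || length(tr) == 0) next
      m <- match_truth_to_traces(ev, tr, ctx$contours[[comp]], dt, n_t,
                                 row_tol)
      for (k in seq_len(nrow(ev))) {
        j <- m[k]
        if (is.na(j)) { tot["n_unresolved"] <- tot["n_unresolved"] + 1; next }
        tf <- truth_frames(ev[k, ], dt, n_t)
        trk <- tr[[j]]
        if (abs(trk$t_start - tf[1]) > extent_tol_frames ||
            abs(trk$t_end - tf[2]) > extent_tol_frames) {
          tot["n_unresolved"] <- tot["n_unresolved"] + 1
          next
        }
        if (ev$censored_truth[k]) {
          tot["boundary_total"] <- tot["boundary_total"] + 1
          if (trk$censored_start || trk$censored_end)
            tot["boundary_flagged"] <- tot["boundary_flagged"] + 1
        } else {
          tot["interior_total"] <- tot["interior_total"] + 1
          if (trk$censored_start || trk$censored_end)
            tot["interior_false_flags"] <- tot["interior_false_flags"] + 1
        }
      }
    }
  }
  as.list(tot)
}

# greedy one-to-one truth-event -> trace matching by temporal overlap,
# gated on circular row distance; returns trace index per event (NA if
# unmatched or ambiguous)
match_truth_to_traces <- function(ev, traces, contour, dt, n_t, row_tol) {
  s_count <- sum(!contour$excluded)
  rows_ev <- vapply(seq_len(nrow(ev)), function(k)
    truth_row(contour, ev$y_px[k], ev$x_px[k]), integer(1))
  cand <- list()
  for (k in seq_len(nrow(ev))) {
    tf <- truth_frames(ev[k, ], dt, n_t)
    for (j in seq_along(traces)) {
      dr <- abs(traces[[j]]$rows - rows_ev[k])
      dr <- pmin(dr, s_count - dr)
      if (min(dr) > row_tol) next
      ov <- min(tf[2], traces[[j]]$t_end) - max(tf[1], traces[[j]]$t_start)
      if (ov < 0) next
      cand[[length(cand) + 1L]] <- c(k, j, ov + 1)
    }
  }
  out <- rep(NA_integer_, nrow(ev))
  if (length(cand) == 0) return(out)
  cm <- do.call(rbind, cand)
  cm <- cm[order(-cm[, 3]), , drop = FALSE]
  used <- logical(length(traces))
  for (r in seq_len(nrow(cm))) {
    k <- cm[r, 1]; j <- cm[r, 2]
    if (is.na(out[k]) && !used[j]) { out[k] <- j; used[j] <- TRUE }
  }
  out
}

#' Two-channel trace alignment with known timing offsets
#'
#' Simulates movies whose second channel repeats every cortical event
#' shifted by `offset_s`, detects traces in both channels on the same
#' contour, and reports the matched fraction of (uncensored) channel-1
#' traces. With `independent = TRUE` the second channel comes from an
#' independently seeded simulation instead, giving the chance-level
#' matched fraction. Chance matching scales with trace density and
#' lifetime (fraction of the movie each trace occupies), so the
#' experiment uses sparse rates and short lifetimes to keep the
#' independent-channel baseline well below the offset-pair fraction.
#'
#' @param seed experiment seed.
#' @param offset_s `c(birth, death)` channel-2 offsets in seconds.
#' @param independent use an unrelated movie as channel 2.
#' @param n_rep replicates pooled.
#' @param row_tol,frame_tol [align_traces()] tolerances.
#' @return list with `matched_fraction`, `n_traces`, `n_replicates`.
#' @export
alignment_experiment <- function(seed = 1, offset_s = c(5, 5),
                                 independent = FALSE, n_rep = 6,
                                 row_tol = 2, frame_tol = 5) {
  cfg0 <- sim_config(rate_daughter = 0.15, rate_mother = 0.1,
                     lifetime_mean_s = 15, lifetime_cv = 0.2,
                     channel_offset_s = offset_s, seed = 1L)
  ctx <- sim_context(cfg0)
  matched <- 0; total <- 0
  for (r in seq_len(n_rep)) {
    cfg <- cfg0
    cfg$seed <- derive_seed(seed, sprintf("align%d", r))
    sim <- simulate_movie(cfg)
    stack2 <- if (independent) {
      cfg2 <- cfg0
      cfg2$seed <- derive_seed(seed, sprintf("align-indep%d", r))
      simulate_movie(cfg2)$stacks$ch1
    } else sim$stacks$ch2
    for (comp in c("mother", "daughter")) {
      trA <- detect_on(sim$stacks$ch1, ctx, comp)
      trB <- detect_on(stack2, ctx, comp)
      keep <- which(!vapply(trA, function(t)
        t$censored_start || t$censored_end, logical(1)))
      if (length(keep) == 0) next
      trA_u <- trA[keep]
      attributes(trA_u) <- attributes(trA)[c("class", "meta")]
      al <- align_traces(trA_u, trB, row_tol = row_tol,
                         frame_tol = frame_tol)
      matched <- matched + sum(al$matched)
      total <- total + length(trA_u)
    }
  }
  list(matched_fraction = matched / total, n_traces = total,
       n_replicates = n_rep)
}

#' Sensitivity and specificity of the cytoplasmic puncta classifier
#'
#' Simulates short movies of cells with or without interior puncta
#' (all cells keep normal cortical CME traffic), classifies each cell
#' from its maximum intensity projection, and reports classifier
#' sensitivity and specificity.
#'
#' @param seed experiment seed.
#' @param n_cells total simulated cells (half positive).
#' @param max_puncta positive cells carry 1..max_puncta puncta.
#' @param k_sigma puncta detection threshold.
#' @param cortex_margin_px interior erosion margin.
#' @return list with `sensitivity`, `specificity`, `n_positive`,
#'   `n_negative`.
#' @export
puncta_classifier_experiment <- function(seed = 1, n_cells = 100,
                                         max_puncta = 3, k_sigma = 5,
                                         cortex_margin_px = 8) {
  set.seed(derive_seed(seed, "puncta-n"))
  truth_pos <- rep(c(TRUE, FALSE), length.out = n_cells)
  n_p <- ifelse(truth_pos, sample(seq_len(max_puncta), n_cells,
                                  replace = TRUE), 0L)
  called <- logical(n_cells)
  for (i in seq_len(n_cells)) {
    cfg <- sim_config(n_interior_puncta = n_p[i], duration_s = 5,
                      seed = derive_seed(seed, sprintf("puncta%d", i)))
    sim <- simulate_movie(cfg)
    mip <- max_intensity_projection(sim$stacks$ch1)
    call <- detect_interior_puncta(mip, sim$mask > 0,
                                   cortex_margin_px = cortex_margin_px,
                                   spot_sigma_px = cfg$psf_sigma_px,
                                   k_sigma = k_sigma, cell_id = i)
    called[i] <- call$positive
  }
  list(sensitivity = mean(called[truth_pos]),
       specificity = mean(!called[!truth_pos]),
       n_positive = sum(truth_pos), n_negative = sum(!truth_pos))
}

#' Recovery of a daughter/mother cortical amplitude ratio
#'
#' Simulates polarized cells whose daughter-cortex events are
#' `amp_ratio` times brighter than mother events (equal initiation
#' rates), measures the per-cell daughter/mother cortical intensity
#' ratio on the MIP, and returns the cohort mean.
#'
#' @param seed experiment seed.
#' @param n_cells cohort size.
#' @param amp_ratio ground-truth amplitude ratio.
#' @param rate shared initiation rate (events/um/min) providing dense
#'   cortical coverage.
#' @param noise render with (TRUE) or without (FALSE) camera noise.
#' @return list with `ratio_mean`, `ratio_truth`, `per_cell`.
#' @export
intensity_ratio_experiment <- function(seed = 1, n_cells = 10,
                                       amp_ratio = 2, rate = 1.2,
                                       noise = TRUE) {
  ratios <- numeric(n_cells)
  ctx <- NULL
  for (i in seq_len(n_cells)) {
    cfg <- sim_config(rate_daughter = rate, rate_mother = rate,
                      amplitude = 50, amplitude_daughter = 50 * amp_ratio,
                      lifetime_mean_s = 30, lifetime_cv = 0.2,
                      seed = derive_seed(seed, sprintf("ratio%d", i)))
    if (is.null(ctx)) ctx <- sim_context(cfg)
    sim <- simulate_movie(cfg, noise = noise)
    mip <- max_intensity_projection(sim$stacks$ch1)
    ratios[i] <- cortical_intensity_ratio(mip, ctx$contours$daughter,
                                          ctx$contours$mother,
                                          width_px = ctx$width)$ratio
  }
  list(ratio_mean = mean(ratios), ratio_truth = amp_ratio,
       per_cell = ratios)
}

#' PCC of colocalized versus independent two-channel puncta scenes
#'
#' Renders two-channel scenes in which channel-2 puncta either sit at
#' the channel-1 positions (colocalized) or are placed independently,
#' and returns the Pearson correlation over the cell mask.
#'
#' @param seed experiment seed.
#' @param colocalized share positions between channels.
#' @param n_puncta interior puncta per channel.
#' @param amplitude puncta peak photons.
#' @return A `ColocResult` (see [pearson_cc()]).
#' @export
coloc_scene_experiment <- function(seed = 1, colocalized = TRUE,
                                   n_puncta = 8, amplitude = 80) {
  cfg <- sim_config(rate_daughter = 0, rate_mother = 0, duration_s = 5,
                    puncta_amplitude = amplitude,
                    n_interior_puncta = n_puncta,
                    seed = derive_seed(seed, "coloc1"))
  sim1 <- simulate_movie(cfg)
  cfg2 <- cfg
  cfg2$seed <- derive_seed(seed, "coloc2")
  if (colocalized) {
    ev2 <- sim1$events
    set.seed(cfg2$seed)
    stack2 <- render_movie(ev2, sim1$geometry, cfg, "ch2")
  } else {
    sim2 <- simulate_movie(cfg2)
    stack2 <- sim2$stacks$ch1
  }
  coloc_scene_pcc(max_intensity_projection(sim1$stacks$ch1),
                  max_intensity_projection(stack2),
                  sim1$mask)
}
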
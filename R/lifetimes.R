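#' Summarize trace lifetimes and initiation frequency
#'
#' Lifetime moments use the sample SD (n-1) and are reported with the
#' coefficient of variation in percent. Boundary-censored traces have
#' underestimated lifetimes, so the default policy excludes them from
#' the mean/SD/CV while still counting them in `n_censored` and in the
#' initiation frequency; `"include-flagged"` keeps them in the moments
#' (the choice is reported in the summary). Frequency is normalized per
#' retained micrometer of cortex per minute, correcting for differences
#' in the surface distance sampled between compartments; the raw count
#' is also returned.
#'
#' @param traces a [detect_traces()] result, or a numeric vector of
#'   lifetimes in seconds (then censoring is ignored).
#' @param retained_length_um retained cortex arclength sampled (um).
#' @param duration_min movie duration in minutes.
#' @param censor_policy `"exclude"` or `"include-flagged"`.
#' @param label optional protein/channel label carried through.
#' @return A `LifetimeSummary` data.frame row: `label`, `compartment`,
#'   `n_events`, `n_censored`, `mean_s`, `sd_s`, `cv_percent`,
#'   `frequency_per_um_min`, `retained_length_um`, `duration_min`,
#'   `censor_policy`.
#' @export
summarize_lifetimes <- function(traces, retained_length_um, duration_min,
                                censor_policy = c("exclude",
                                                  "include-flagged"),
                                label = NA_character_) {
  censor_policy <- match.arg(censor_policy)
  assert_that(duration_min > 0, "duration_min must be positive")
  assert_that(retained_length_um > 0, "retained_length_um must be positive")
  if (inherits(traces, "TraceSet")) {
    tab <- traces_table(traces)
    life <- tab$lifetime_s
    cens <- tab$censored
    compartment <- attr(traces, "meta")$compartment
  } else {
    life <- as.numeric(traces)
    cens <- rep(FALSE, length(life))
    compartment <- NA_character_
  }
  keep <- if (censor_policy == "exclude") !cens else rep(TRUE, length(life))
  x <- life[keep]
  m <- if (length(x) > 0) mean(x) else NaN
  s <- if (length(x) > 1) stats::sd(x) else NaN
  data.frame(label = label,
             compartment = if (is.null(compartment)) NA_character_ else compartment,
             n_events = length(life),
             n_censored = sum(cens),
             mean_s = m,
             sd_s = s,
             cv_percent = 100 * s / m,
             frequency_per_um_min = length(life) /
               (retained_length_um * duration_min),
             retained_length_um = retained_length_um,
             duration_min = duration_min,
             censor_policy = censor_policy)
}

#' Mann-Whitney comparison of two lifetime samples
#'
#' Two-sided Mann-Whitney U test: exact by null-distribution
#' enumeration when the combined sample is small (`n1 + n2 <= 12`) and
#' untied, otherwise the normal approximation with the tie-corrected
#' variance (no continuity correction). Returns the U statistic of the
#' first sample.
#'
#' @param x,y numeric lifetime vectors (or `TraceSet`s, in which case
#'   uncensored lifetimes are compared).
#' @return list with `U`, `p_value`, `n1`, `n2`, `method`.
#' @export
compare_lifetimes <- function(x, y) {
  pick <- function(v) {
    if (inherits(v, "TraceSet")) {
      tab <- traces_table(v)
      tab$lifetime_s[!tab$censored]
    } else as.numeric(v)
  }
  x <- pick(x); y <- pick(y)
  assert_that(length(x) > 0 && length(y) > 0,
              "both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  has_ties <- anyDuplicated(c(x, y)) > 0
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (!has_ties && n1 + n2 <= 12) {
    wt <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    return(list(U = unname(wt$statistic), p_value = wt$p.value,
                n1 = n1, n2 = n2, method = "exact"))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(c(x, y))
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                              (n * (n - 1)))
  if (sigma2 <= 0) {
    p <- if (u == mu) 1 else 0
  } else {
    z <- (u - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = u, p_value = p, n1 = n1, n2 = n2, method = "normal-ties")
}

#' Split a trace intensity profile into low and high stages
#'
#' Some endocytic proteins (Pan1-like dynamics) show a low-abundance
#' stage followed by a high-abundance stage. The change point is the
#' interior split minimizing the two-segment piecewise-constant
#' residual sum of squares; the step is called significant when the
#' high/low mean difference exceeds twice the noise scale.
#'
#' @param trace a trace from [detect_traces()], or a numeric intensity
#'   profile (one value per frame).
#' @param frame_interval_s seconds per frame.
#' @param noise_scale intensity noise; when `NULL`, estimated robustly
#'   from first differences of the profile.
#' @return A `TwoStageSplit` list: `change_frame` (last frame of the
#'   low stage, 1-based within the trace), `low_duration_s`,
#'   `high_duration_s`, `low_mean`, `high_mean`, `step_significant`.
#' @export
split_two_stage <- function(trace, frame_interval_s = 1, noise_scale = NULL) {
  prof <- if (is.list(trace)) trace$intensity_profile else as.numeric(trace)
  n <- length(prof)
  if (n < 6)
    stop("trace too short to split (need at least 6 frames)", call. = FALSE)
  cs <- cumsum(prof)
  cs2 <- cumsum(prof^2)
  c_idx <- 1:(n - 1)
  rss_low <- cs2[c_idx] - cs[c_idx]^2 / c_idx
  rss_high <- (cs2[n] - cs2[c_idx]) - (cs[n] - cs[c_idx])^2 / (n - c_idx)
  rss <- rss_low + rss_high
  cf <- c_idx[which.min(rss)]
  low_mean <- cs[cf] / cf
  high_mean <- (cs[n] - cs[cf]) / (n - cf)
  if (is.null(noise_scale))
    noise_scale <- mad_scale(diff(prof)) / sqrt(2)
  list(change_frame = cf,
       low_duration_s = cf * frame_interval_s,
       high_duration_s = (n - cf) * frame_interval_s,
       low_mean = low_mean,
       high_mean = high_mean,
       step_significant = (high_mean - low_mean) > 2 * noise_scale)
}

#' Match traces across two channels of the same cortex
#'
#' Trace `a` matches trace `b` when their row intervals overlap within
#' `row_tol` rows and their time intervals overlap within `frame_tol`
#' frames; assignment is greedy one-to-one by overlap area. Used to ask
#' what fraction of one protein's events also recruit a second protein.
#'
#' @param tracesA,tracesB [detect_traces()] results built on kymographs
#'   sharing a row map.
#' @param row_tol,frame_tol matching tolerances.
#' @return list with `matched` (logical per A trace), `matched_fraction`,
#'   `pairs` (data.frame of matched indices).
#' @export
align_traces <- function(tracesA, tracesB, row_tol = 3, frame_tol = 10) {
  ma <- attr(tracesA, "meta"); mb <- attr(tracesB, "meta")
  if (ma$n_rows != mb$n_rows ||
      !isTRUE(all.equal(ma$row_arclength_um, mb$row_arclength_um)))
    stop("trace sets come from kymographs with different row maps",
         call. = FALSE)
  assert_that(length(tracesA) > 0, "channel A has no traces")
  s_count <- ma$n_rows
  if (length(tracesB) == 0)
    return(list(matched = rep(FALSE, length(tracesA)),
                matched_fraction = 0,
                pairs = data.frame(a = integer(0), b = integer(0))))
  expand_rows <- function(rows, tol) {
    unique(as.vector(outer(rows, -tol:tol, "+") - 1L) %% s_count + 1L)
  }
  rows_a <- lapply(tracesA, function(t) expand_rows(t$rows, row_tol))
  rows_b <- lapply(tracesB, function(t) t$rows)
  cand <- list()
  for (i in seq_along(tracesA)) {
    for (j in seq_along(tracesB)) {
      nr <- length(intersect(rows_a[[i]], rows_b[[j]]))
      if (nr == 0) next
      t0 <- max(tracesA[[i]]$t_start - frame_tol, tracesB[[j]]$t_start)
      t1 <- min(tracesA[[i]]$t_end + frame_tol, tracesB[[j]]$t_end)
      if (t1 < t0) next
      cand[[length(cand) + 1L]] <- c(i, j, nr * (t1 - t0 + 1))
    }
  }
  matched <- rep(FALSE, length(tracesA))
  pairs <- data.frame(a = integer(0), b = integer(0))
  if (length(cand) > 0) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, 3]), , drop = FALSE]
    used_b <- logical(length(tracesB))
    for (k in seq_len(nrow(cm))) {
      i <- cm[k, 1]; j <- cm[k, 2]
      if (!matched[i] && !used_b[j]) {
        matched[i] <- TRUE
        used_b[j] <- TRUE
        pairs <- rbind(pairs, data.frame(a = i, b = j))
      }
    }
  }
  list(matched = matched,
       matched_fraction = mean(matched),
       pairs = pairs)
}
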
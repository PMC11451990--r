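test_that("baseline is the row median and noise the pooled MAD", {
  v <- matrix(5, 4, 20)
  km <- make_test_kymo(v)
  bl <- estimate_baseline(km)
  expect_equal(bl$baseline, rep(5, 4))
  expect_equal(bl$noise, 0)
  # one 6-frame event in 20 frames does not move the median
  v2 <- v; v2[2, 8:13] <- 50
  bl2 <- estimate_baseline(make_test_kymo(v2))
  expect_equal(bl2$baseline[2], 5)
  # MAD recovers a known Gaussian sigma
  set.seed(1)
  v3 <- matrix(rnorm(200 * 100, 10, 2), 200, 100)
  bl3 <- estimate_baseline(make_test_kymo(v3))
  expect_equal(bl3$noise, 2, tolerance = 0.1)
  expect_error(estimate_baseline(make_test_kymo(matrix(0, 3, 3))),
               "at least 5 frames")
})

test_that("lifetime follows the (t_end - t_start + 1) * dt convention", {
  v <- matrix(0, 6, 12)
  v[3, 4:8] <- 50               # 5 frames
  km <- make_test_kymo(v, frame_interval_s = 2)
  tr <- detect_traces(km, min_len_frames = 1, smooth_row_sigma = 0)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$t_start, 4L)
  expect_equal(tr[[1]]$t_end, 8L)
  expect_equal(tr[[1]]$lifetime_s, 5 * 2)
  # a 1-frame event has lifetime dt but falls below the default
  # min_len_frames = 3 and is filtered
  v1 <- matrix(0, 6, 12); v1[3, 5] <- 50
  km1 <- make_test_kymo(v1)
  expect_length(detect_traces(km1, smooth_row_sigma = 0), 0)
  got <- detect_traces(km1, min_len_frames = 1, smooth_row_sigma = 0)
  expect_equal(got[[1]]$lifetime_s, 1)
})

test_that("traces touching the first or last frame are censored", {
  v <- matrix(0, 6, 15)
  v[2, 1:6] <- 40               # starts at frame 1
  v[5, 10:15] <- 40             # ends at last frame
  tr <- detect_traces(make_test_kymo(v), smooth_row_sigma = 0)
  tab <- traces_table(tr)
  tab <- tab[order(tab$t_start), ]
  expect_true(tab$censored_start[1]); expect_false(tab$censored_end[1])
  expect_false(tab$censored_start[2]); expect_true(tab$censored_end[2])
  # a whole-movie component is censored at both ends (it drifts across
  # rows so each row's median baseline stays at background)
  v2 <- matrix(0, 6, 30)
  v2[2, 1:10] <- 40; v2[3, 10:21] <- 40; v2[4, 21:30] <- 40
  tr2 <- detect_traces(make_test_kymo(v2), smooth_row_sigma = 0)
  expect_length(tr2, 1)
  expect_true(tr2[[1]]$censored_start && tr2[[1]]$censored_end)
})

test_that("an event straddling the seam is one trace, not two", {
  v <- matrix(0, 10, 15)
  v[c(9, 10, 1, 2), 5:9] <- 50
  tr <- detect_traces(make_test_kymo(v), smooth_row_sigma = 0)
  expect_length(tr, 1)
  expect_setequal(tr[[1]]$rows, c(1, 2, 9, 10))
  # with the wrap adjacency broken (an excluded gap at the seam) the
  # same pattern splits in two
  adj <- rep(TRUE, 10); adj[10] <- FALSE
  tr2 <- detect_traces(make_test_kymo(v, adjacent_next = adj),
                       smooth_row_sigma = 0)
  expect_length(tr2, 2)
})

test_that("detect_traces equals the flood-fill oracle on small kymographs", {
  set.seed(99)
  for (rep in 1:12) {
    s_count <- sample(6:50, 1)
    n_t <- sample(6:50, 1)
    v <- matrix(0, s_count, n_t)
    n_on <- rbinom(1, s_count * n_t, 0.12)
    v[sample(s_count * n_t, n_on)] <- 50
    adj <- rep(TRUE, s_count)
    if (rep %% 3 == 0) adj[sample(s_count, 2)] <- FALSE
    km <- make_test_kymo(v, adjacent_next = adj)
    tr <- detect_traces(km, min_len_frames = 1, min_rows = 1,
                        smooth_row_sigma = 0)
    # oracle: flood fill on the same thresholded map
    lab <- flood_fill_oracle(v > 0, adj)
    want <- component_signature(lab)
    # compare component structure: row sets and time extents
    sig_tr <- sort(vapply(tr, function(t)
      paste(paste(t$rows, collapse = ","), t$t_start, t$t_end),
      character(1)))
    sig_or <- sort(vapply(seq_along(want), function(k) {
      px <- as.integer(strsplit(want[k], ",")[[1]])
      rows <- sort(unique(((px - 1) %% s_count) + 1))
      cols <- ((px - 1) %/% s_count) + 1
      paste(paste(rows, collapse = ","), min(cols), max(cols))
    }, character(1)))
    expect_identical(sig_tr, sig_or)
  }
})

test_that("row smoothing raises SNR without changing temporal extents", {
  set.seed(7)
  v <- matrix(rnorm(40 * 60, 10, 2), 40, 60)
  v[18:22, 20:35] <- v[18:22, 20:35] + 30
  km <- make_test_kymo(v)
  tr <- detect_traces(km, k_sigma = 4, smooth_row_sigma = 1)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$t_start, 20L)
  expect_equal(tr[[1]]$t_end, 35L)
})

test_that("filter_traces drops merged and fragmentary components", {
  # events stay temporally sparse (occupy < half of each row) so the
  # per-row median baseline remains at background
  v <- matrix(0, 30, 80)
  v[5:10, 5:20] <- 50            # single-patch-like (6 rows)
  v[15:28, 10:30] <- 50          # too wide (14 rows): side-by-side merge
  v[2, 33:38] <- 50              # 1-row fragment
  tr <- detect_traces(make_test_kymo(v), smooth_row_sigma = 0)
  expect_length(tr, 3)
  kept <- filter_traces(tr, max_row_extent = 8, min_row_extent = 3)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$rows, 5:10)
  # double-intensity plateau (temporal overlap of two patches)
  v2 <- matrix(0, 30, 80)
  v2[5:10, 5:30] <- 50
  v2[5:10, 15:20] <- 100         # co-resident second patch
  tr2 <- detect_traces(make_test_kymo(v2), smooth_row_sigma = 0)
  expect_length(tr2, 1)
  expect_length(filter_traces(tr2, profile_range = c(0.4, 1.6)), 0)
  # flat single patches pass the same profile bounds
  expect_length(filter_traces(tr, profile_range = c(0.4, 1.6)), 3)
  expect_error(filter_traces(tr, profile_range = c(2, 1)), "lo < hi")
  expect_error(filter_traces(list()), "TraceSet")
})

test_that("simulated events are each recovered within a frame", {
  cfg <- sim_config(rate_mother = 0, rate_daughter = 0.2,
                    lifetime_mean_s = 25, lifetime_cv = 0.2, seed = 14)
  ctx <- sim_context(cfg)
  sim <- simulate_movie(cfg)
  tr <- cortexkymo:::detect_on(sim$stacks$ch1, ctx, "daughter")
  ev <- sim$events[sim$events$compartment == "daughter", , drop = FALSE]
  n_t <- ncol(attr(tr, "meta")$adjacent_next)
  m <- cortexkymo:::match_truth_to_traces(
    ev, tr, ctx$contours$daughter, cfg$frame_interval_s,
    cortexkymo:::n_frames_for(cfg), row_tol = 4)
  matched <- !is.na(m)
  expect_gt(mean(matched), 0.8)
  for (k in which(matched)) {
    tf <- cortexkymo:::truth_frames(ev[k, ], cfg$frame_interval_s,
                                    cortexkymo:::n_frames_for(cfg))
    expect_lte(abs(tr[[m[k]]]$t_start - tf[1]), 1)
    expect_lte(abs(tr[[m[k]]]$t_end - tf[2]), 1)
  }
})

test_that("traces_table flattens a TraceSet faithfully", {
  v <- matrix(0, 8, 12); v[3:4, 4:9] <- 50
  tr <- detect_traces(make_test_kymo(v), smooth_row_sigma = 0)
  tab <- traces_table(tr)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$row_min, 3L); expect_equal(tab$row_max, 4L)
  expect_equal(tab$lifetime_s, 6)
  expect_false(tab$censored)
  expect_equal(nrow(traces_table(cortexkymo:::empty_trace_set(
    make_test_kymo(v)))), 0)
})
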
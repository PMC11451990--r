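test_that("lifetime moments and frequency follow their definitions", {
  s <- summarize_lifetimes(c(28, 30, 32), retained_length_um = 15,
                           duration_min = 3)
  expect_equal(s$mean_s, 30)
  expect_equal(s$sd_s, 2)
  expect_equal(s$cv_percent, 100 * 2 / 30, tolerance = 1e-10)
  expect_equal(s$n_events, 3)
  s2 <- summarize_lifetimes(rep(10, 12), retained_length_um = 15,
                            duration_min = 3)
  expect_equal(s2$frequency_per_um_min, 12 / (15 * 3), tolerance = 1e-10)
  expect_error(summarize_lifetimes(1:3, 0, 3), "positive")
  expect_error(summarize_lifetimes(1:3, 15, -1), "positive")
})

test_that("censor policy controls which traces enter the moments", {
  v <- matrix(0, 6, 20)
  v[2, 1:5] <- 40          # start-censored, apparent lifetime 5 s
  v[4, 8:12] <- 40         # complete, 5 s
  v[6, 14:18] <- 40        # complete, 5 s
  tr <- detect_traces(make_test_kymo(v), smooth_row_sigma = 0)
  s_ex <- summarize_lifetimes(tr, 10, 20 / 60)
  expect_equal(s_ex$n_events, 3)
  expect_equal(s_ex$n_censored, 1)
  expect_equal(s_ex$mean_s, 5)
  s_in <- summarize_lifetimes(tr, 10, 20 / 60,
                              censor_policy = "include-flagged")
  expect_equal(s_in$mean_s, 5)
  # frequency counts all traces under both policies
  expect_equal(s_ex$frequency_per_um_min, s_in$frequency_per_um_min)
  # every trace censored: moments are NaN under the exclude policy.
  # (A streak occupying a whole row would raise that row's median
  # baseline and hide itself, so the both-ends-censored component here
  # drifts across rows, each row staying mostly background.)
  v2 <- matrix(0, 6, 30)
  v2[3, 1:10] <- 40; v2[4, 10:21] <- 40; v2[5, 21:30] <- 40
  tr2 <- detect_traces(make_test_kymo(v2), smooth_row_sigma = 0)
  expect_length(tr2, 1)
  s3 <- summarize_lifetimes(tr2, 10, 30 / 60)
  expect_true(is.nan(s3$mean_s))
  expect_equal(s3$n_censored, 1)
})

test_that("exact Mann-Whitney p-values match full enumeration", {
  r <- compare_lifetimes(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$U, 0)
  expect_equal(r$method, "exact")
  set.seed(11)
  for (i in 1:10) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    v <- sample(100, n1 + n2)          # untied by construction
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    got <- compare_lifetimes(x, y)
    want <- mw_enumeration_oracle(x, y)
    expect_equal(got$p_value, want, tolerance = 1e-12)
  }
})

test_that("large or tied samples use the tie-corrected normal method", {
  x <- c(rep(10, 5), 12, 13, 14)
  y <- c(rep(10, 3), 15, 16, 17, 18, 19)
  r <- compare_lifetimes(x, y)
  expect_equal(r$method, "normal-ties")
  expect_true(r$p_value > 0 && r$p_value < 1)
  # cross-check against R's own tie-corrected approximation
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = FALSE))
  expect_equal(r$p_value, wt$p.value, tolerance = 1e-10)
  # identical constant samples: no evidence of a difference
  expect_equal(compare_lifetimes(rep(5, 8), rep(5, 8))$p_value, 1)
  # clearly separated large samples give a tiny p
  set.seed(2)
  expect_lt(compare_lifetimes(rnorm(40, 10), rnorm(40, 20))$p_value, 1e-6)
  expect_error(compare_lifetimes(numeric(0), 1:3), "non-empty")
})

test_that("two-stage split matches the brute-force RSS oracle", {
  # noiseless step: exact change point
  prof <- c(rep(10, 35), rep(40, 25))
  sp <- split_two_stage(prof, frame_interval_s = 1)
  expect_equal(sp$change_frame, 35)
  expect_equal(sp$low_duration_s, 35)
  expect_equal(sp$high_duration_s, 25)
  expect_equal(sp$low_mean, 10)
  expect_equal(sp$high_mean, 40)
  expect_true(sp$step_significant)
  # random profiles: same minimizer as an O(n^2) direct search
  set.seed(4)
  for (i in 1:10) {
    p <- rnorm(sample(6:40, 1), sd = 3) + c(0, 5)[1 + (i %% 2)]
    expect_equal(split_two_stage(p)$change_frame, split_bruteforce_oracle(p))
  }
})

test_that("step significance distinguishes flat noise from real steps", {
  set.seed(9)
  flat <- rnorm(50, 20, 1)
  expect_false(split_two_stage(flat)$step_significant)
  step <- c(rnorm(30, 10, 0.2), rnorm(20, 30, 0.2))
  sp <- split_two_stage(step, frame_interval_s = 2)
  expect_true(sp$step_significant)
  expect_lte(abs(sp$change_frame - 30), 1)
  expect_equal(sp$low_duration_s + sp$high_duration_s, 100)
  # a symmetric ramp splits at an interior point; the two-segment RSS
  # optimum of a triangle is an off-apex pair symmetric about the
  # midpoint, and exact symmetry makes the argmin tie-dependent
  ramp <- c(seq(0, 50, length.out = 40), seq(50, 0, length.out = 40))
  cf <- split_two_stage(ramp)$change_frame
  expect_gte(cf, 10); expect_lte(cf, 70)
  expect_error(split_two_stage(1:4), "at least 6")
})

test_that("align_traces matches same-position traces one-to-one", {
  v <- matrix(0, 20, 40)
  v[4:6, 5:15] <- 50
  v[12:14, 20:32] <- 50
  trA <- detect_traces(make_test_kymo(v), smooth_row_sigma = 0)
  # channel B: the same traces shifted 5 frames later
  vb <- matrix(0, 20, 40)
  vb[4:6, 10:20] <- 50
  vb[12:14, 25:37] <- 50
  trB <- detect_traces(make_test_kymo(vb), smooth_row_sigma = 0)
  al <- align_traces(trA, trB, row_tol = 2, frame_tol = 6)
  expect_equal(al$matched_fraction, 1)
  expect_equal(nrow(al$pairs), 2)
  expect_equal(anyDuplicated(al$pairs$b), 0)
  # self-alignment is perfect; empty partner gives zero
  expect_equal(align_traces(trA, trA)$matched_fraction, 1)
  empty <- cortexkymo:::empty_trace_set(make_test_kymo(v))
  expect_equal(align_traces(trA, empty)$matched_fraction, 0)
  # distant traces do not match under tight tolerances
  vc <- matrix(0, 20, 40); vc[18:19, 2:8] <- 50
  trC <- detect_traces(make_test_kymo(vc), smooth_row_sigma = 0)
  expect_equal(align_traces(trC, trB, row_tol = 1,
                            frame_tol = 2)$matched_fraction, 0)
  # mismatched row maps are an error
  v2 <- v[1:10, ]
  tr2 <- detect_traces(make_test_kymo(v2), smooth_row_sigma = 0)
  expect_error(align_traces(trA, tr2), "row maps")
})
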
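test_that("a rasterized disk recovers its analytic circumference", {
  m <- matrix(0L, 60, 60)
  yy <- row(m); xx <- col(m)
  m[(yy - 30)^2 + (xx - 30)^2 <= 20^2] <- 1L
  ct <- extract_contour(m, 1L, step_px = 1, pixel_size_nm = 1000)
  expect_equal(ct$total_um, 2 * pi * 20, tolerance = 0.03)
  # orientation is counter-clockwise in array coordinates
  y <- ct$points$y; x <- ct$points$x
  n <- length(y)
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  expect_gt(area2, 0)
})

test_that("a filled square recovers its perimeter within 10%", {
  m <- matrix(0L, 30, 30)
  m[10:19, 10:19] <- 1L
  ct <- extract_contour(m, 1L, pixel_size_nm = 1000)
  expect_equal(ct$total_um, 40, tolerance = 0.10)
})

test_that("tiny labels are rejected", {
  m <- matrix(0L, 10, 10); m[5, 5:6] <- 1L
  expect_error(extract_contour(m, 1L), "too small")
})

test_that("neck exclusion marks samples near neck pixels", {
  m <- matrix(0L, 60, 60)
  yy <- row(m); xx <- col(m)
  m[(yy - 30)^2 + (xx - 30)^2 <= 20^2] <- 1L
  ct <- extract_contour(m, 1L)
  # pick a contour point as the fake neck and exclude around it
  neck <- as.matrix(ct$points[1, c("y", "x")])
  ct2 <- exclude_neck(ct, neck, margin_px = 5)
  expect_gt(sum(ct2$excluded), 0)
  expect_lt(mean(ct2$excluded), 0.5)
  expect_length(ct2$excluded_intervals, 1)
  # retained + excluded arclength equals the closed total (to step_px)
  total <- retained_um(ct2) +
    sum(ct2$excluded) * ct2$step_px * ct2$pixel_size_nm / 1000
  expect_equal(total, length(ct2$excluded) * ct2$step_px * 65 / 1000)
  # empty neck set leaves the contour unchanged
  expect_identical(exclude_neck(ct, matrix(numeric(0), 0, 2), 5)$excluded,
                   ct$excluded)
  # a margin spanning the whole contour is degenerate
  expect_error(exclude_neck(ct, neck, margin_px = 100), "degenerate")
})

test_that("circular exclusion runs merge across the index seam", {
  flag <- c(TRUE, TRUE, rep(FALSE, 6), TRUE, TRUE)
  iv <- cortexkymo:::runs_to_intervals(flag)
  expect_length(iv, 1)
  expect_equal(iv[[1]], c(9L, 2L))
})

test_that("band width selection follows the cortical signal spread", {
  m <- matrix(0L, 60, 60)
  yy <- row(m); xx <- col(m)
  m[(yy - 30)^2 + (xx - 30)^2 <= 20^2] <- 1L
  ct <- extract_contour(m, 1L)
  # realistic regime: sparse cortical spots over background (a
  # uniformly bright ring defeats the robust background estimate and
  # falls back to the default width with a warning, tested below)
  spot_mip <- function(spot_sigma) {
    mip <- matrix(0, 60, 60)
    idx <- seq(1, nrow(ct$points), length.out = 13)[-13]
    for (i in round(idx)) {
      cy <- ct$points$y[i]; cx <- ct$points$x[i]
      mip <- mip + 100 * exp(-((yy - cy)^2 + (xx - cx)^2) /
                               (2 * spot_sigma^2))
    }
    mip
  }
  w_narrow <- band_width_from_mip(spot_mip(1.0), ct, psf_sigma_px = 1)
  w_wide <- band_width_from_mip(spot_mip(2.5), ct, psf_sigma_px = 2.5)
  # wider cross-sections need wider bands; widths are odd
  expect_gt(w_wide, w_narrow)
  expect_equal(w_wide %% 2, 1)
  expect_equal(w_narrow %% 2, 1)
  # lower coverage never widens the band
  expect_lte(band_width_from_mip(spot_mip(2.5), ct,
                                 coverage_fraction = 0.6,
                                 psf_sigma_px = 2.5), w_wide)
  # blank MIP falls back to the default with a warning
  expect_warning(w0 <- band_width_from_mip(matrix(0, 60, 60), ct),
                 "default")
  expect_equal(w0, 5L)
})

test_that("band sampling reads a rendered spot along the normal", {
  cfg <- sim_config(rate_mother = 0, rate_daughter = 0.3, background = 0,
                    background_out = 0, read_noise_sd = 0, seed = 13)
  sim <- simulate_movie(cfg, noise = FALSE)
  ev <- sim$events[!sim$events$censored_truth &
                     sim$events$compartment == "daughter", ][1, ]
  fr <- get_frame(sim$stacks$ch1, round(ev$t_birth_s) + 3)
  ct <- extract_contour(sim$mask, 2L, pixel_size_nm = cfg$pixel_size_nm)
  prof1 <- sample_band(fr, ct, width_px = 1)
  d2 <- (ct$points$y - ev$y_px)^2 + (ct$points$x - ev$x_px)^2
  # the profile is bright at the event's cortex position (other events
  # of the same movie may be brighter elsewhere)
  expect_gt(prof1[which.min(d2)], 0.5 * max(prof1))
  # constant image: every row equals the constant for both reductions
  const <- matrix(4.2, nrow(sim$mask), ncol(sim$mask))
  expect_true(all(abs(sample_band(const, ct, 5, "max") - 4.2) < 1e-9))
  expect_true(all(abs(sample_band(const, ct, 5, "mean") - 4.2) < 1e-9))
  # max reduction with width 5 is robust to contour placement error
  prof5 <- sample_band(fr, ct, width_px = 5, reduction = "max")
  expect_gt(max(prof5), 0.9 * max(prof1))
  expect_error(sample_band(fr, ct, width_px = 4), "odd")
})
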
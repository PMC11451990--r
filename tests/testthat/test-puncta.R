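make_disk_mask <- function(n = 80, r = 30) {
  yy <- row(matrix(0, n, n)); xx <- col(matrix(0, n, n))
  (yy - n / 2)^2 + (xx - n / 2)^2 <= r^2
}

add_spot <- function(img, y, x, amp, sigma = 1.3) {
  yy <- row(img); xx <- col(img)
  img + amp * exp(-((yy - y)^2 + (xx - x)^2) / (2 * sigma^2))
}

test_that("interior puncta of known count and position are detected", {
  set.seed(3)
  mask <- make_disk_mask()
  img <- matrix(rnorm(80 * 80, 10, 1), 80, 80)
  truth <- rbind(c(30, 30), c(45, 55), c(55, 35))
  for (k in 1:3) img <- add_spot(img, truth[k, 1], truth[k, 2], amp = 8)
  call <- detect_interior_puncta(img, mask, cortex_margin_px = 8)
  expect_true(call$positive)
  expect_equal(call$n_puncta, 3)
  for (k in 1:3) {
    d <- sqrt((call$spot_coordinates$y - truth[k, 1])^2 +
                (call$spot_coordinates$x - truth[k, 2])^2)
    expect_lt(min(d), 2)
  }
})

test_that("cortical-only signal never counts as cytoplasmic", {
  set.seed(5)
  mask <- make_disk_mask()
  img <- matrix(rnorm(80 * 80, 10, 1), 80, 80)
  # bright patches exactly on the cortex rim (radius 30 around center 40)
  for (a in seq(0, 2 * pi, length.out = 9)[-9])
    img <- add_spot(img, 40 + 30 * sin(a), 40 + 30 * cos(a), amp = 30)
  call <- detect_interior_puncta(img, mask, cortex_margin_px = 8)
  expect_false(call$positive)
  expect_equal(call$n_puncta, 0)
})

test_that("blank cells are negative and tiny masks error", {
  set.seed(6)
  mask <- make_disk_mask()
  img <- matrix(rnorm(80 * 80, 10, 1), 80, 80)
  expect_false(detect_interior_puncta(img, mask)$positive)
  small <- matrix(FALSE, 80, 80); small[40:42, 40:42] <- TRUE
  expect_error(detect_interior_puncta(img, small, cortex_margin_px = 8),
               "interior")
})

test_that("percent_positive counts calls and enforces bounds", {
  mk <- function(p) list(positive = p)
  r <- percent_positive(c(replicate(3, mk(TRUE), simplify = FALSE),
                          replicate(97, mk(FALSE), simplify = FALSE)))
  expect_equal(r$percent, 3)
  expect_equal(r$n, 100)
  expect_equal(percent_positive(replicate(50, mk(FALSE),
                                          simplify = FALSE))$percent, 0)
  all_pos <- replicate(145, mk(TRUE), simplify = FALSE)
  expect_equal(percent_positive(all_pos)$percent, 100)
  expect_error(percent_positive(list()), "at least one")
})

test_that("cortical intensity ratio recovers a simulated amplitude ratio", {
  # dense cortical coverage so the band means are well averaged, and
  # near-equal lobe radii so contour curvature affects both
  # compartments almost identically (exactly equal radii would make
  # the area-based mother/daughter pairing a coin flip; the realistic
  # unequal-radius geometry is exercised by intensity_ratio_experiment)
  cfg <- sim_config(mother_radius_px = 28, daughter_radius_px = 26,
                    neck_halfwidth_px = 6,
                    rate_mother = 2.4, rate_daughter = 2.4,
                    amplitude = 40, amplitude_daughter = 80,
                    lifetime_mean_s = 30, duration_s = 60,
                    background = 10, seed = 8)
  sim <- simulate_movie(cfg, noise = FALSE)
  mip <- max_intensity_projection(sim$stacks$ch1)
  ctx <- sim_context(cfg)
  # default background: estimated per compartment from the band itself
  # (the band straddles the membrane, so the in-cell background level
  # would over-subtract)
  r <- cortical_intensity_ratio(mip, ctx$contours$daughter,
                                ctx$contours$mother)
  expect_equal(r$ratio, 2, tolerance = 0.25)
  expect_gt(r$daughter_mean, r$mother_mean)
  # equal amplitudes give a ratio near one
  cfg2 <- sim_config(mother_radius_px = 28, daughter_radius_px = 26,
                     neck_halfwidth_px = 6,
                     rate_mother = 2.4, rate_daughter = 2.4,
                     amplitude = 60, lifetime_mean_s = 30,
                     duration_s = 60, background = 10, seed = 9)
  sim2 <- simulate_movie(cfg2, noise = FALSE)
  ctx2 <- sim_context(cfg2)
  r2 <- cortical_intensity_ratio(max_intensity_projection(sim2$stacks$ch1),
                                 ctx2$contours$daughter,
                                 ctx2$contours$mother)
  expect_equal(r2$ratio, 1, tolerance = 0.25)
  # zero signal above background on the mother is undefined
  blank <- matrix(10, nrow(sim$mask), ncol(sim$mask))
  expect_error(cortical_intensity_ratio(blank, ctx$contours$daughter,
                                        ctx$contours$mother,
                                        background = 10),
               "undefined")
})

test_that("pearson_cc equals the direct formula to 1e-12", {
  set.seed(12)
  a <- matrix(rnorm(100 * 100), 100, 100)
  b <- 0.6 * a + matrix(rnorm(100 * 100, sd = 0.5), 100, 100)
  mask <- matrix(runif(100 * 100) < 0.7, 100, 100)
  got <- pearson_cc(a, b, mask)
  expect_equal(got$pcc, pcc_direct_oracle(a[mask], b[mask]),
               tolerance = 1e-12)
  expect_equal(got$n_pixels, sum(mask))
  # identity and affine behavior
  expect_equal(pearson_cc(a, a)$pcc, 1, tolerance = 1e-12)
  expect_equal(pearson_cc(a, -2 * a + 7)$pcc, -1, tolerance = 1e-12)
  expect_equal(pearson_cc(a, 3 * b + 100, mask)$pcc, got$pcc,
               tolerance = 1e-12)
})

test_that("pearson_cc reproduces the 4-pixel worked example and errors", {
  a <- matrix(c(1, 2, 3, 4, rep(0, 12)), 4, 4)
  b <- matrix(c(1, 3, 2, 4, rep(0, 12)), 4, 4)
  m4 <- matrix(FALSE, 4, 4); m4[1:4] <- TRUE
  expect_warning(r4 <- pearson_cc(a, b, m4), "unstable")
  expect_equal(r4$pcc, 0.8, tolerance = 1e-12)
  expect_error(pearson_cc(a, b, matrix(FALSE, 4, 4)), "at least 2")
  expect_error(pearson_cc(matrix(1, 5, 5), matrix(1:25, 5, 5)), "constant")
  expect_error(pearson_cc(matrix(1, 2, 3), matrix(1, 3, 2)), "equal shape")
})

test_that("coloc_scene_pcc separates shared from independent scenes", {
  same <- coloc_scene_experiment(seed = 7, colocalized = TRUE)
  diff <- coloc_scene_experiment(seed = 7, colocalized = FALSE)
  expect_gt(same$pcc, 0.5)
  expect_lt(diff$pcc, 0.3)
  expect_gt(same$pcc, diff$pcc + 0.3)
})
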
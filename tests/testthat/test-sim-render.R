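test_that("background renders at the configured photon level", {
  cfg <- sim_config(rate_mother = 0, rate_daughter = 0, background = 10,
                    background_out = 2, read_noise_sd = 0,
                    bleach_rate_per_s = 0, duration_s = 20, seed = 1)
  sim <- simulate_movie(cfg)
  # background composes additively: interior = background_out +
  # background; score the deep interior and far exterior
  deep <- as.matrix(EBImage::distmap(sim$mask > 0)) > 6
  far <- as.matrix(EBImage::distmap(sim$mask == 0)) > 6
  m <- mean(apply(sim$stacks$ch1$pixels, 3, function(fr) mean(fr[deep])))
  expect_lt(abs(m - (10 + 2)), 0.5)
  expect_lt(abs(mean(sim$stacks$ch1$pixels[, , 1][far]) - 2), 0.5)
})

test_that("a noiseless plateau event peaks near amplitude + background", {
  cfg <- sim_config(rate_mother = 0, rate_daughter = 0.3, amplitude = 50,
                    background = 10, bleach_rate_per_s = 0, seed = 21)
  sim <- simulate_movie(cfg, noise = FALSE)
  all_ev <- sim$events
  ev <- all_ev[all_ev$compartment == "daughter" & !all_ev$censored_truth, ,
               drop = FALSE]
  # pick an event spatially isolated from every other event, so its
  # peak is not inflated by a neighbor
  isolated <- vapply(seq_len(nrow(ev)), function(k) {
    d <- sqrt((all_ev$y_px - ev$y_px[k])^2 + (all_ev$x_px - ev$x_px[k])^2)
    sum(d < 10) == 1
  }, logical(1))
  expect_gt(sum(isolated), 0)
  e <- ev[which(isolated)[1], ]
  t_mid <- round((e$t_birth_s + e$t_death_s) / 2)
  fr <- get_frame(sim$stacks$ch1, t_mid + 1)
  yc <- round(e$y_px); xc <- round(e$x_px)
  peak <- max(fr[(yc - 1):(yc + 1), (xc - 1):(xc + 1)])
  # interior background is background_out + background = 12; the pixel
  # grid sits at most half a pixel off the true center
  expect_gt(peak, 0.8 * 50 + 12 - 2)
  expect_lt(peak, 50 + 12 + 2)
  # frames after its death show only background there, provided no
  # other event ever visits the neighborhood
  later <- all_ev$t_birth_s > e$t_death_s + 2
  if (e$t_death_s < cfg$duration_s - 2 && !any(later & sqrt(
    (all_ev$y_px - e$y_px)^2 + (all_ev$x_px - e$x_px)^2) < 10)) {
    fr2 <- get_frame(sim$stacks$ch1, cortexkymo:::n_frames_for(cfg))
    expect_lt(max(fr2[(yc - 1):(yc + 1), (xc - 1):(xc + 1)]), 12 + 5)
  }
})

test_that("photobleaching decays the frame mean exponentially", {
  cfg <- sim_config(rate_mother = 0, rate_daughter = 0, background = 40,
                    background_out = 0, read_noise_sd = 0,
                    bleach_rate_per_s = 0.01, duration_s = 120, seed = 2)
  sim <- simulate_movie(cfg, noise = FALSE)
  inside <- sim$mask > 0
  means <- vapply(seq_len(n_frames(sim$stacks$ch1)), function(t)
    mean(sim$stacks$ch1$pixels[, , t][inside]), numeric(1))
  tt <- (seq_along(means) - 1) * cfg$frame_interval_s
  fit <- stats::lm(log(means) ~ tt)
  expect_equal(unname(stats::coef(fit)[2]), -0.01, tolerance = 1e-6)
})

test_that("ramp profile rises and falls; two-stage shows a low phase", {
  base <- list(rate_mother = 0, rate_daughter = 0.3, background = 0,
               background_out = 0, read_noise_sd = 0,
               bleach_rate_per_s = 0, seed = 31)
  cfg_r <- do.call(sim_config, c(base, list(profile = "ramp")))
  sim <- simulate_movie(cfg_r, noise = FALSE)
  ev <- sim$events[!sim$events$censored_truth, ][1, ]
  yc <- round(ev$y_px); xc <- round(ev$x_px)
  tr <- sim$stacks$ch1$pixels[yc, xc, ]
  live <- which(tr > 0)
  peak_at <- which.max(tr)
  expect_gt(peak_at, min(live))
  expect_lt(peak_at, max(live))
  cfg_t <- do.call(sim_config, c(base, list(two_stage = c(0.3, 10),
                                            lifetime_mean_s = 40)))
  sim2 <- simulate_movie(cfg_t, noise = FALSE)
  ev2 <- sim2$events[!sim2$events$censored_truth, ]
  ev2 <- ev2[ev2$t_death_s - ev2$t_birth_s > 20, ][1, ]
  tr2 <- sim2$stacks$ch1$pixels[round(ev2$y_px), round(ev2$x_px), ]
  k0 <- ceiling(ev2$t_birth_s) + 1
  expect_lt(tr2[k0 + 2], 0.6 * max(tr2))   # low stage
  expect_gt(max(tr2), 2 * tr2[k0 + 2])     # high stage follows
})

test_that("rendered stacks carry the configured calibration", {
  cfg <- sim_config(pixel_size_nm = 80, frame_interval_s = 0.5,
                    duration_s = 5, rate_mother = 0, rate_daughter = 0,
                    seed = 1)
  sim <- simulate_movie(cfg)
  expect_equal(sim$stacks$ch1$pixel_size_nm, 80)
  expect_equal(sim$stacks$ch1$frame_interval_s, 0.5)
  expect_equal(n_frames(sim$stacks$ch1), 10)
})

test_that("write_simulation emits movie, mask, events and config", {
  dir <- withr::local_tempdir()
  cfg <- small_sim_config(duration_s = 8, seed = 3)
  sim <- simulate_movie(cfg)
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "movie_ch1.tif")))
  expect_true(file.exists(file.path(dir, "mask.tif")))
  ev <- utils::read.csv(file.path(dir, "events.csv"))
  expect_equal(nrow(ev), nrow(sim$events))
  cfg_back <- jsonlite::read_json(file.path(dir, "config.json"),
                                  simplifyVector = TRUE)
  expect_equal(cfg_back$duration_s, 8)
  expect_identical(read_mask(file.path(dir, "mask.tif")), sim$mask)
})
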
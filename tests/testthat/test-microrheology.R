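eta_water <- 1.002e-3

test_that("Stokes-Einstein arithmetic matches the hand value", {
  bead <- bead_spec()   # 0.51 um radius, 293.15 K
  D <- diffusion_coefficient(bead, eta_water)
  expect_equal(D, 1.380649e-23 * 293.15 / (6 * pi * eta_water * 0.51e-6))
  expect_equal(D, 4.20e-13, tolerance = 0.002)
  expect_error(diffusion_coefficient(bead, 0), "positive")
  expect_error(bead_spec(radius = 0), "positive")
})

test_that("trajectory simulation is seeded and near-frozen at high viscosity", {
  bead <- bead_spec()
  t1 <- simulate_trajectories(5, 50, bead, eta_water, seed = 3)
  t2 <- simulate_trajectories(5, 50, bead, eta_water, seed = 3)
  expect_identical(t1$tracks, t2$tracks)
  t3 <- simulate_trajectories(5, 50, bead, eta_water, seed = 4)
  expect_false(identical(t1$tracks, t3$tracks))
  # eta -> infinity: particles effectively stationary
  frozen <- simulate_trajectories(3, 50, bead_spec(localization_noise_sd = 0),
                                  viscosity = 1e6, seed = 1)
  expect_lt(max(abs(frozen$tracks$x_m), abs(frozen$tracks$y_m)), 1e-10)
})

test_that("MSD estimator is exact on constructed tracks", {
  dt <- 0.02
  v <- 2e-6
  tr <- data.frame(track_id = 1, frame = 1:100,
                   x_m = v * (1:100) * dt, y_m = 0)
  ts <- structure(list(tracks = tr, frame_interval = dt, bead = NULL,
                       seed = NULL, true_viscosity = NULL),
                  class = "trajectory_set")
  mc <- msd(ts, 10)$curve
  expect_equal(mc$msd_m2, (v * mc$tau_s)^2)       # ballistic: v^2 tau^2
  expect_true(all(diff(mc$n_pairs) < 0))          # pairs decrease with lag

  # single two-point track: one lag, msd = squared step
  tr2 <- data.frame(track_id = 1, frame = 1:2,
                    x_m = c(0, 3e-7), y_m = c(0, 4e-7))
  ts2 <- structure(list(tracks = tr2, frame_interval = dt, bead = NULL,
                        seed = NULL, true_viscosity = NULL),
                   class = "trajectory_set")
  mc2 <- msd(ts2, 10)$curve
  expect_equal(nrow(mc2), 1L)
  expect_equal(mc2$msd_m2, (3e-7)^2 + (4e-7)^2)
})

test_that("Brownian MSD tracks 4 D tau within its standard errors", {
  bead <- bead_spec(localization_noise_sd = 0)
  ts <- simulate_trajectories(100, 2000, bead, eta_water, seed = 5)
  mc <- msd(ts, 25)$curve
  D <- diffusion_coefficient(bead, eta_water)
  z <- abs(mc$msd_m2 - 4 * D * mc$tau_s) / mc$se
  # 25 correlated lags: every value within 3 SE and the bulk within 2 SE
  expect_true(all(z <= 3))
  expect_gte(mean(z <= 2), 0.8)
})

test_that("fit_viscosity inverts an exact Newtonian curve", {
  bead <- bead_spec()
  D <- diffusion_coefficient(bead, eta_water)
  tau <- (1:20) * 0.02
  curve <- structure(list(curve = data.frame(
    tau_s = tau, msd_m2 = 4 * D * tau, n_pairs = 1000, se = 1e-18)),
    class = "msd_curve")
  fit <- suppressWarnings(fit_viscosity(curve, bead))  # exact-fit lm warning
  expect_equal(fit$viscosity, eta_water, tolerance = 1e-10)
  expect_equal(fit$offset_m2, 0, tolerance = 1e-20)
  expect_equal(fit$powerlaw_exponent, 1, tolerance = 1e-8)
  expect_true(fit$newtonian)
  # non-positive slope is physically invalid
  bad <- structure(list(curve = data.frame(
    tau_s = tau, msd_m2 = rev(4 * D * tau), n_pairs = 1000, se = 1e-18)),
    class = "msd_curve")
  expect_error(fit_viscosity(bad, bead), "physically-invalid")
})

test_that("the offset term absorbs localization noise and eta stays unbiased", {
  noisy <- bead_spec(localization_noise_sd = 50e-9)
  ts <- simulate_trajectories(100, 2000, noisy, eta_water, seed = 6)
  fit <- fit_viscosity(msd(ts, 25), noisy)
  expect_lt(abs(fit$viscosity - eta_water) / eta_water, 0.02)
  # fitted offset close to 4 sigma^2
  expect_equal(fit$offset_m2, 4 * (50e-9)^2, tolerance = 0.25)
})

test_that("a subdiffusive walk is detected as non-Newtonian", {
  bead <- bead_spec(localization_noise_sd = 0)
  ts <- simulate_trajectories(60, 1500, bead, eta_water, seed = 7,
                              alpha = 0.7)
  fit <- fit_viscosity(msd(ts, 25), bead)
  expect_equal(fit$powerlaw_exponent, 0.7, tolerance = 0.05)
  expect_false(fit$newtonian)
})

test_that("localization finds symmetric spots to sub-millipixel accuracy", {
  # one spot exactly on the center pixel's center: pixel (21, 21) of a
  # 41 x 41 frame has its center at 20.5 px = 5.125 um
  ctr <- 20.5 * 0.25e-6
  ts <- structure(list(tracks = data.frame(
    track_id = 1, frame = 1, x_m = ctr, y_m = ctr),
    frame_interval = 0.02, bead = NULL, seed = NULL,
    true_viscosity = NULL), class = "trajectory_set")
  frames <- render_frames(ts, image_size = 41, psf_sd = 2,
                          pixel_size = 0.25e-6)
  img <- frames[[1]]
  brightest <- which(img == max(img), arr.ind = TRUE)
  expect_equal(unname(brightest[1, ]), c(21, 21))
  pos <- localize(frames, threshold = 10)[[1]]
  expect_equal(pos$x_m, ctr, tolerance = 1e-3 * 0.25e-6)
  expect_equal(pos$y_m, ctr, tolerance = 1e-3 * 0.25e-6)
  # a uniform image below threshold yields no detections
  expect_identical(nrow(localize(list(matrix(1, 16, 16)), 10)[[1]]), 0L)
})

test_that("two separated spots give two detections; SNR-20 constellation
           is recovered within 0.1 px", {
  set.seed(8)
  xy <- cbind(x = c(5e-6, 15e-6, 9e-6), y = c(5e-6, 12e-6, 16e-6))
  ts <- structure(list(tracks = data.frame(
    track_id = 1:3, frame = 1, x_m = xy[, 1], y_m = xy[, 2]),
    frame_interval = 0.02, bead = NULL, seed = NULL,
    true_viscosity = NULL), class = "trajectory_set")
  frames <- render_frames(ts, image_size = 80, psf_sd = 2,
                          pixel_size = 0.25e-6, intensity = 1000)
  noisy <- list(frames[[1]] + matrix(stats::rnorm(80 * 80, sd = 50), 80, 80))
  attr(noisy, "pixel_size") <- 0.25e-6
  pos <- localize(noisy, threshold = 200)[[1]]
  expect_identical(nrow(pos), 3L)
  for (k in 1:3) {
    d <- sqrt((pos$x_m - xy[k, 1])^2 + (pos$y_m - xy[k, 2])^2)
    expect_lt(min(d), 0.1 * 0.25e-6)
  }
})

test_that("rendered-then-localized positions round-trip at zero noise", {
  bead <- bead_spec(localization_noise_sd = 0)
  starts <- as.matrix(expand.grid(x = c(8e-6, 16e-6), y = c(8e-6, 16e-6)))
  ts <- simulate_trajectories(4, 20, bead, eta_water, seed = 9,
                              start_positions = starts)
  frames <- render_frames(ts, image_size = 96, psf_sd = 2,
                          pixel_size = 0.25e-6)
  pos <- localize(frames, threshold = 30)
  for (f in seq_along(pos)) {
    truth <- ts$tracks[ts$tracks$frame == f, ]
    expect_identical(nrow(pos[[f]]), nrow(truth))
    for (k in seq_len(nrow(truth))) {
      d <- sqrt((pos[[f]]$x_m - truth$x_m[k])^2 +
                  (pos[[f]]$y_m - truth$y_m[k])^2)
      expect_lt(min(d), 0.05 * 0.25e-6)
    }
  }
})

test_that("linking follows single and well-separated particles", {
  # one particle, small steps
  pos1 <- lapply(1:10, function(f)
    data.frame(x_m = f * 1e-7, y_m = 0))
  ts <- link_tracks(pos1, max_step = 5e-7)
  expect_identical(length(unique(ts$tracks$track_id)), 1L)
  expect_identical(nrow(ts$tracks), 10L)
  # two particles always farther apart than the gate: two tracks, no swap
  pos2 <- lapply(1:10, function(f)
    data.frame(x_m = c(f * 1e-7, 5e-6 + f * 1e-7), y_m = c(0, 0)))
  ts2 <- link_tracks(pos2, max_step = 5e-7)
  expect_identical(length(unique(ts2$tracks$track_id)), 2L)
  expect_true(all(table(ts2$tracks$track_id) == 10))
})

test_that("a crossing pair within the gate terminates both tracks", {
  # frame 3 is ambiguous: detection at 2.0 is in the gate of both track
  # ends (1.0 and 3.0), and the end at 3.0 also sees 2.6
  pos <- list(
    data.frame(x_m = c(0, 4), y_m = c(0, 0)),
    data.frame(x_m = c(1, 3), y_m = c(0, 0)),
    data.frame(x_m = c(2.0, 2.6), y_m = c(0, 0)),
    data.frame(x_m = c(1.0, 4.0), y_m = c(0, 0))  # diverge again
  )
  ts <- link_tracks(pos, max_step = 1.5)
  lens <- table(ts$tracks$track_id)
  expect_identical(length(lens), 4L)            # 2 originals + 2 restarts
  ends <- tapply(ts$tracks$frame, ts$tracks$track_id, max)
  expect_identical(sort(unname(ends)), c(2L, 2L, 4L, 4L))
})

test_that("density is weight over volume with the working-regime note", {
  expect_equal(as.numeric(density_from_weight_volume(1e-8, 1e-11)), 1000)
  d <- density_from_weight_volume(4e-9, 4e-12)   # 4 nL: in regime
  expect_true(attr(d, "in_regime"))
  expect_message(d2 <- density_from_weight_volume(1e-7, 1e-10),
                 "outside the 4-80 nL")
  expect_false(attr(d2, "in_regime"))
  expect_error(density_from_weight_volume(1e-8, 0), "positive")
})
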
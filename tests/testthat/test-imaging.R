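test_that("render + fit round trip recovers the geometry to sub-pixel", {
  st <- droplet_pair_state(50, 50, 30)
  fr <- render_droplet_image(st, pixel_size = 1, image_shape = c(256, 256))
  fit <- fit_droplet_pair(fr)
  expect_lt(abs(fit$R1 - 50), 0.5)
  expect_lt(abs(fit$R2 - 50), 0.5)
  expect_lt(abs(fit$rc - 30), 1)
  expect_lt(abs(fit$d - 80), 1)
})

test_that("fit is invariant to pixel size in physical units", {
  st <- droplet_pair_state(25, 25, 15)
  f1 <- fit_droplet_pair(render_droplet_image(st, 1, c(128, 128)))
  f2 <- fit_droplet_pair(render_droplet_image(st, 0.5, c(256, 256)))
  expect_equal(f1$R1, f2$R1, tolerance = 0.02)   # um unchanged
  expect_equal(f2$R1 / 0.5, 2 * (f1$R1 / 1), tolerance = 0.02)  # px doubled
})

test_that("fit is invariant under rotation and intensity scaling", {
  st <- droplet_pair_state(40, 30, 20)
  fr <- render_droplet_image(st, 1, c(192, 192))
  fit <- fit_droplet_pair(fr)
  rot <- image_frame(t(fr$intensity)[ncol(fr$intensity):1, ],
                     fr$pixel_size)
  fit_r <- fit_droplet_pair(rot)
  expect_equal(sort(c(fit$R1, fit$R2)), sort(c(fit_r$R1, fit_r$R2)),
               tolerance = 1e-6)
  expect_equal(fit$rc, fit_r$rc, tolerance = 1e-6)
  scaled <- image_frame(fr$intensity * 37.5, fr$pixel_size)
  fit_s <- fit_droplet_pair(scaled)
  expect_equal(c(fit$R1, fit$R2, fit$rc), c(fit_s$R1, fit_s$R2, fit_s$rc))
})

test_that("fit is equivariant under image translation", {
  st <- droplet_pair_state(30, 30, 18)
  fr <- render_droplet_image(st, 1, c(160, 160))
  base <- fit_droplet_pair(fr)
  shifted <- matrix(0, 180, 180)
  shifted[11:170, 16:175] <- fr$intensity  # +10 rows (y), +15 cols (x)
  fit_t <- fit_droplet_pair(image_frame(shifted, 1))
  expect_equal(fit_t$R1, base$R1, tolerance = 1e-6)
  expect_equal(fit_t$rc, base$rc, tolerance = 1e-6)
  expect_equal(attr(fit_t, "fit")$centers[1, ] -
                 attr(base, "fit")$centers[1, ],
               c(15, 10), tolerance = 1e-6)
})

test_that("degenerate frames raise detection errors", {
  expect_error(fit_droplet_pair(image_frame(matrix(0, 64, 64), 1)),
               "0 candidate")
  expect_error(droplet_pair_state(0, 50, 0))  # zero-radius droplet
  st <- droplet_pair_state(50, 50, 30)
  expect_error(render_droplet_image(st, 1, c(64, 64)), "fit inside")
})

test_that("a single disk is rejected as one candidate circle", {
  # one circle only: both sub-fits collapse onto the same centre
  x <- (1:128) - 1
  img <- outer(x, x, function(yy, xx)
    pmin(pmax((30 - sqrt((xx - 64)^2 + (yy - 64)^2)) + 0.5, 0), 1))
  expect_error(fit_droplet_pair(image_frame(img, 1)), "1 candidate")
})

test_that("track_trajectory recovers a simulated shrinkage series", {
  cfg <- control_dib_config(true_Pf = 500, duration = 30,
                            sample_interval = 10)
  traj <- simulate_dib_trajectory(cfg)
  frames <- lapply(seq_len(nrow(traj)), function(i)
    render_droplet_image(droplet_pair_state(traj$R1_um[i], traj$R2_um[i],
                                            traj$rc_um[i]),
                         pixel_size = 1, image_shape = c(224, 224),
                         timestamp = traj$time_s[i]))
  rec <- track_trajectory(frames)
  expect_equal(rec$time_s, traj$time_s)
  expect_lt(max(abs(rec$R1_um - traj$R1_um)), 0.5)
  expect_lt(max(abs(rec$R2_um - traj$R2_um)), 0.5)
  expect_lt(max(abs(rec$rc_um - traj$rc_um)), 1)
})

test_that("tracking preconditions and constant-frame behaviour", {
  st <- droplet_pair_state(40, 40, 20)
  fr <- function(t) render_droplet_image(st, 1, c(160, 160), timestamp = t)
  rec <- track_trajectory(list(fr(0), fr(1), fr(2)))
  expect_equal(rec$R1_um, rep(rec$R1_um[1], 3))
  expect_error(track_trajectory(list(fr(0))), "at least 2")
  expect_error(track_trajectory(list(fr(1), fr(0))), "increasing")
})
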
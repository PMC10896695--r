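test_that("noiseless kinematics are exact and frame spacing follows the rate", {
  cfg <- sim_track_config(
    n_tracks = 1, seed = 3, localization_sd = 0, pause_entry_rate = 0,
    direction_mix = c(retrograde = 1, anterograde = 0, stationary = 0),
    speed_mean = 2, speed_sd = 0, label_onset = TRUE,
    visible_length_mean = 1e6, movie_duration = 300, frame_rate = 2
  )
  s <- simulate_tracks(cfg)
  expect_equal(unique(diff(s$spots$t)), 0.5)
  expect_equal(unique(round(diff(s$spots$x), 12)), -1.0)
  expect_equal(s$truth$direction, "retrograde")
})

test_that("same seed reproduces output bit-identically, different seeds differ", {
  cfg1 <- sim_track_config(n_tracks = 20, seed = 11)
  cfg2 <- sim_track_config(n_tracks = 20, seed = 12)
  a <- simulate_tracks(cfg1)
  b <- simulate_tracks(cfg1)
  c <- simulate_tracks(cfg2)
  expect_identical(a$spots, b$spots)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$spots, c$spots))
})

test_that("emitted positions stay inside the imaging window", {
  s <- simulate_tracks(sim_track_config(n_tracks = 100, seed = 5))
  geom <- axon_geometry()
  expect_true(all(s$spots$x >= geom$window_start))
  expect_true(all(s$spots$x <= geom$window_end))
})

test_that("per-track speed draws recover the configured mean at 3 SE", {
  s <- simulate_tracks(sim_track_config(
    n_tracks = 1000, seed = 42, speed_mean = 1.76, speed_sd = 0.5,
    direction_mix = c(retrograde = 0.8, anterograde = 0.2, stationary = 0)
  ))
  v <- s$truth$speed
  expect_lt(abs(mean(v) - 1.76), 3 * sd(v) / sqrt(length(v)))
})

test_that("invalid track configurations are rejected", {
  expect_error(sim_track_config(frame_rate = 0), "positive")
  expect_error(
    sim_track_config(direction_mix = c(retrograde = 0.5, anterograde = 0.5, stationary = 0.5)),
    "sum to 1"
  )
  expect_error(axon_geometry(window_start = 200, window_end = 100), "window")
  expect_error(
    axon_geometry(groove_length = 100, window_end = 150), "window"
  )
})

test_that("dual-channel generator honours the colocalized fraction exactly", {
  base <- function(n, seed) {
    sim_track_config(
      n_tracks = n, seed = seed, movie_duration = 120, localization_sd = 0
    )
  }
  # fraction 0: no B track shares a trajectory with any A track
  d0 <- simulate_dual_channel(base(20, 1), base(20, 2), 0, seed = 9)
  expect_equal(nrow(d0$pairs), 0)
  joint <- dplyr::inner_join(
    d0$spots_a, d0$spots_b,
    by = "frame", suffix = c("_a", "_b"), relationship = "many-to-many"
  )
  expect_gt(min(abs(joint$x_a - joint$x_b) + abs(joint$t_a - joint$t_b)), 0)

  # fraction 1 with zero noise: every emitted A track has an identical B twin
  d1 <- simulate_dual_channel(base(15, 3), base(0, 4), 1, seed = 10)
  expect_equal(nrow(d1$pairs), dplyr::n_distinct(d1$spots_a$track_id))
  for (r in seq_len(nrow(d1$pairs))) {
    a <- dplyr::filter(d1$spots_a, track_id == d1$pairs$track_id_a[r])
    b <- dplyr::filter(d1$spots_b, track_id == d1$pairs$track_id_b[r])
    expect_equal(a$x, b$x)
    expect_equal(a$frame, b$frame)
  }

  # fraction 0.10 of 500 generated tracks: exactly 50 ground-truth pairs
  d2 <- simulate_dual_channel(
    sim_track_config(n_tracks = 500, seed = 5, movie_duration = 120),
    sim_track_config(n_tracks = 50, seed = 6, movie_duration = 120),
    0.10,
    seed = 11
  )
  expect_equal(nrow(d2$pairs), 50)
  expect_error(
    simulate_dual_channel(base(5, 1), base(5, 2), 1.2, seed = 1), "0, 1"
  )
})

test_that("kymograph rendering maps static and moving spots to lines", {
  geom <- axon_geometry()
  static <- tibble::tibble(frame = 0:9, x = 50, intensity = 1)
  img <- render_kymograph(static, geom, psf_sd = 0.3)
  peaks <- apply(img, 1, which.max)
  expect_equal(length(unique(peaks)), 1)

  moving <- tibble::tibble(frame = 0:9, x = 20 + 2 * (0:9), intensity = 1)
  img2 <- render_kymograph(moving, geom, psf_sd = 0.3, bin_width = 0.2)
  pos <- attr(img2, "positions")
  slope <- diff(pos[apply(img2, 1, which.max)])
  expect_true(all(abs(slope - 2) < 0.2 + 1e-9))

  empty <- render_kymograph(
    static[0, ], geom, psf_sd = 0.3, n_frames = 5
  )
  expect_true(all(empty == 0))
  expect_error(render_kymograph(static, geom, psf_sd = 0), "positive")
})
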
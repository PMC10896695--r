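test_that("instantaneous velocity is exact on noiseless constant motion", {
  tr <- make_track(1L, list(c(30, -2)))
  v <- instantaneous_velocity(tr)
  expect_true(all(abs(v$velocity + 2) < 1e-10))
  # at 2 Hz the default 3-frame window spans a 1.0 s baseline
  expect_equal(tr$t[3] - tr$t[1], 1.0)
  expect_error(
    instantaneous_velocity(tr[1:2, ], kinetics_config(velocity_window = 5)),
    "window"
  )
})

test_that("a stationary noisy particle sits below the pause threshold", {
  s <- simulate_tracks(sim_track_config(
    n_tracks = 1000, seed = 3, movie_duration = 60,
    direction_mix = c(retrograde = 0, anterograde = 0, stationary = 1)
  ))
  sp <- s$spots |>
    dplyr::group_by(track_id) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::ungroup()
  v <- instantaneous_velocity(sp)
  expect_gte(mean(abs(v$velocity) < 0.1), 0.95)
})

test_that("pause detection honours the threshold and duration semantics", {
  # constant 1 um/s: no pauses
  expect_equal(nrow(detect_pauses(make_track(1L, list(c(30, 1))))), 0)
  # 10 s creeping at 0.05 um/s between two runs: one pause of ~10 s
  tr <- make_track(1L, list(c(15, 2), c(10, 0.05), c(15, -2)))
  p <- detect_pauses(tr)
  expect_equal(nrow(p), 1)
  expect_lt(abs(p$duration - 10), 0.5 + 1e-9)
})

test_that("per-track summaries reproduce the arithmetic of the speed definition", {
  # 100 -> 40 um in 30 s: retrograde, 2 um/s, run length 60
  tr <- make_track(1L, list(c(30, -2)), x0 = 100)
  s <- track_summaries(tr)
  expect_equal(s$mean_speed, 2)
  expect_equal(s$run_length, 60)
  expect_equal(s$direction, "retrograde")
  expect_true(s$passed_motile_filter)

  # net displacement 8 um: fails the 10 um motile filter
  s8 <- track_summaries(make_track(2L, list(c(16, 0.5))))
  expect_false(s8$passed_motile_filter)
  expect_equal(s8$direction, "stationary")

  # 40 um in 20 s then a 10 s pause: net speed 1.333, ~33% pausing
  tr3 <- make_track(3L, list(c(20, 2), c(10, 0)), x0 = 10)
  s3 <- track_summaries(tr3)
  expect_equal(s3$mean_speed, 40 / 30, tolerance = 1e-9)
  expect_equal(s3$percent_pausing, 100 / 3, tolerance = 0.07)
  expect_equal(s3$n_pauses, 1)
  expect_error(track_summaries(tr3[rep(1, 3), ]), "Zero-duration")
})

test_that("net speed never exceeds path speed", {
  s <- simulate_tracks(sim_track_config(n_tracks = 100, seed = 17))
  ts <- track_summaries(s$spots)
  expect_true(all(ts$mean_speed_net <= ts$mean_speed_path + 1e-12))
})

test_that("flipping the axis swaps directions but preserves all magnitudes", {
  s <- simulate_tracks(sim_track_config(n_tracks = 50, seed = 23))
  a <- track_summaries(s$spots)
  flipped <- dplyr::mutate(s$spots, x = -x)
  b <- track_summaries(flipped)
  swap <- c(
    retrograde = "anterograde", anterograde = "retrograde",
    stationary = "stationary"
  )
  expect_equal(unname(swap[a$direction]), b$direction)
  expect_equal(a$mean_speed, b$mean_speed)
  expect_equal(a$run_length, b$run_length)
  expect_equal(a$percent_pausing, b$percent_pausing)
})

test_that("population summaries aggregate over tracks and report fractions", {
  tracks <- dplyr::bind_rows(
    make_track(1L, list(c(30, -1)), x0 = 100),
    make_track(2L, list(c(30, -2)), x0 = 100),
    make_track(3L, list(c(30, -3)), x0 = 100)
  )
  pop <- population_summary(tracks)
  retro <- dplyr::filter(tidy(pop), direction == "retrograde")
  expect_equal(retro$mean_speed, 2)
  expect_equal(retro$sem_speed, sd(1:3) / sqrt(3), tolerance = 1e-9)

  mixed <- dplyr::bind_rows(
    purrr::map(1:8, \(i) make_track(i, list(c(30, -2)), x0 = 100)),
    purrr::map(9:10, \(i) make_track(i, list(c(30, 2)), x0 = 10))
  )
  fr <- population_summary(mixed)$direction_fractions
  expect_equal(
    fr$fraction[match(c("retrograde", "anterograde"), fr$direction)],
    c(0.8, 0.2)
  )

  none <- population_summary(make_track(1L, list(c(16, 0.1))))
  expect_equal(none$status, "empty")
})

test_that("event frequency counts qualifying tracks per movie", {
  six <- dplyr::bind_rows(
    purrr::map(1:6, \(i) make_track(i, list(c(30, -2)), x0 = 100))
  )
  ef <- event_frequency(six, movie_duration = 120)
  expect_equal(ef$events_per_min, 3.0)
  ef0 <- event_frequency(six, 120, direction = "anterograde")
  expect_equal(ef0$events_per_min, 0)
  expect_error(event_frequency(six, 0), "positive")
})

test_that("event frequency recovers a configured Poisson flux within 3 SE", {
  s <- simulate_tracks(sim_track_config(
    n_tracks = 15, n_movies = 20, poisson_n = TRUE, seed = 31,
    movie_duration = 240, pause_entry_rate = 0,
    direction_mix = c(retrograde = 1, anterograde = 0, stationary = 0)
  ))
  est <- event_frequency(s$spots, 240, n_movies = 20)
  truth_rate <- s$truth |>
    dplyr::mutate(qualifies = !is.na(net_speed_true) &
      net_speed_true * span >= 10) |>
    dplyr::summarise(rate = sum(qualifies) / (20 * 4)) |>
    dplyr::pull(rate)
  se <- sd(est$events_per_min) / sqrt(nrow(est))
  expect_lt(abs(mean(est$events_per_min) - truth_rate), 3 * se + 1e-9)
})

test_that("first arrival reports the earliest qualifying track per movie", {
  tr <- make_track(1L, list(c(60, -1.5)), x0 = 109, t0 = 180)
  fa <- first_arrival_time(tr)
  expect_true(fa$observed)
  expect_equal(fa$arrival_min, 3.0)

  none <- first_arrival_time(tibble::tibble(
    track_id = integer(), frame = integer(), t = numeric(), x = numeric()
  ))
  expect_false(none$observed)
  expect_true(is.na(none$arrival_min))
})

test_that("a stable-binding simulation arrives in under five minutes", {
  s <- simulate_tracks(sim_track_config(
    n_tracks = 20, seed = 19, label_onset = TRUE, pause_entry_rate = 0,
    speed_mean = 1.76, speed_sd = 0, movie_duration = 600,
    visible_length_mean = 1e6,
    direction_mix = c(retrograde = 1, anterograde = 0, stationary = 0)
  ))
  fa <- first_arrival_time(s$spots)
  expect_true(fa$observed)
  expect_lt(fa$arrival_min, 5)
})
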
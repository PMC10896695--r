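two_parallel_sets <- function(n, spacing = 10, frames = 20, speed = -1) {
  dplyr::bind_rows(purrr::map(
    seq_len(n),
    \(i) make_track(i, list(c(frames / 2, speed)), x0 = 10 + i * spacing / 2)
  ))
}

test_that("identical channels match completely at zero separation", {
  a <- two_parallel_sets(5, frames = 20)
  m <- match_tracks(a, a)
  expect_equal(nrow(m), 5)
  expect_true(all(m$mean_separation == 0))
  expect_true(all(m$overlap_fraction == 1))
})

test_that("temporally disjoint or spatially distant channels never match", {
  a <- two_parallel_sets(4)
  b <- dplyr::mutate(a, t = t + 1000, frame = frame + 2000L)
  expect_equal(nrow(match_tracks(a, b)), 0)
  shifted <- dplyr::mutate(a, x = x + 2.5)
  expect_equal(nrow(match_tracks(a, shifted)), 0)
})

test_that("channel swap mirrors percentages and keeps the matched set", {
  d <- simulate_dual_channel(
    sim_track_config(n_tracks = 60, seed = 1, movie_duration = 120),
    sim_track_config(n_tracks = 40, seed = 2, movie_duration = 120),
    0.2,
    seed = 3
  )
  m_ab <- match_tracks(d$spots_a, d$spots_b)
  m_ba <- match_tracks(d$spots_b, d$spots_a)
  expect_equal(
    dplyr::arrange(m_ab, track_id_a)$track_id_a,
    dplyr::arrange(m_ba, track_id_b)$track_id_b
  )
  s_ab <- summarize_colocalization(m_ab, d$spots_a, d$spots_b)
  s_ba <- summarize_colocalization(m_ba, d$spots_b, d$spots_a)
  expect_equal(s_ab$percent_of_a, s_ba$percent_of_b)
  expect_equal(s_ab$percent_of_b, s_ba$percent_of_a)
  # percent(A) * n_A = percent(B) * n_B = 100 * n_matched
  expect_equal(s_ab$percent_of_a * s_ab$n_a, 100 * s_ab$n_matched)
  expect_equal(s_ab$percent_of_b * s_ab$n_b, 100 * s_ab$n_matched)
})

test_that("published-scale track counts yield the printed percentages", {
  pct <- function(n_matched, n) 100 * n_matched / n
  a <- two_parallel_sets(413, spacing = 0.5)
  b <- dplyr::mutate(two_parallel_sets(732, spacing = 0.5), x = x + 3000)
  matches <- tibble::tibble(
    track_id_a = 1:57, track_id_b = 1:57,
    overlap_frames = 20L, overlap_fraction = 1,
    mean_separation = 0.1, close_fraction = 1
  )
  s <- summarize_colocalization(matches, a, b)
  expect_equal(round(s$percent_of_a, 1), 13.8)
  expect_equal(round(s$percent_of_b, 1), 7.8)
  expect_equal(pct(57, 413), s$percent_of_a)
  zero <- summarize_colocalization(matches[0, ], a, b)
  expect_equal(zero$percent_of_a, 0)
  expect_equal(zero$percent_of_b, 0)
})

test_that("a configured matched fraction is recovered from noisy channels", {
  d <- simulate_dual_channel(
    sim_track_config(n_tracks = 300, seed = 5, movie_duration = 240),
    sim_track_config(n_tracks = 80, seed = 6, movie_duration = 240),
    0.10,
    seed = 7
  )
  expect_equal(nrow(d$pairs), 30)
  m <- match_tracks(d$spots_a, d$spots_b)
  ci_half <- 1.96 * sqrt(300 * 0.1 * 0.9)
  expect_lt(abs(nrow(m) - 30), ci_half)
  truth_keys <- paste(d$pairs$track_id_a, d$pairs$track_id_b)
  found <- paste(m$track_id_a, m$track_id_b) %in% truth_keys
  # nearly all ground-truth pairs are found
  expect_gte(sum(found), 0.9 * nrow(d$pairs))
})

test_that("matched particles inherit the faster channel's speed", {
  fast <- sim_track_config(
    n_tracks = 60, seed = 11, movie_duration = 120, speed_mean = 3.5,
    direction_mix = c(retrograde = 0, anterograde = 1, stationary = 0)
  )
  slow <- sim_track_config(
    n_tracks = 60, seed = 12, movie_duration = 120, speed_mean = 1.7,
    direction_mix = c(retrograde = 0, anterograde = 1, stationary = 0)
  )
  d <- simulate_dual_channel(fast, slow, 0.3, seed = 13)
  m <- match_tracks(d$spots_a, d$spots_b)
  s <- summarize_colocalization(m, d$spots_a, d$spots_b, kinetics_config())
  sp <- s$speeds
  expect_gt(
    sp$mean_speed[sp$group == "matched"],
    sp$mean_speed[sp$group == "B_only"]
  )
})

test_that("mismatched frame clocks are rejected", {
  a <- make_track(1L, list(c(10, -1)), frame_rate = 2)
  b <- make_track(1L, list(c(10, -1)), frame_rate = 4)
  expect_error(match_tracks(a, b), "frame rate")
})
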
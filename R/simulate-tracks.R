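# Run speed drawn from a normal truncated to [lo, hi] by rejection.
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0) {
    return(rep(min(max(mean, lo), hi), n))
  }
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Alternating run/pause segments for one particle, starting in a run.
# Returns a data.frame of segment start time (relative), duration, velocity,
# paused flag. Run lengths are censored at `visible_length` of moving path.
build_motion_segments <- function(speed_signed, pause_entry_rate,
                                  pause_mean_duration, visible_length,
                                  max_time) {
  t_rel <- 0
  moved <- 0
  segs <- list()
  running <- TRUE
  speed <- abs(speed_signed)
  while (t_rel < max_time && moved < visible_length) {
    if (running) {
      dur <- if (pause_entry_rate > 0) rexp(1, pause_entry_rate) else Inf
      # censor the run when the visible path length is exhausted
      dur <- min(dur, (visible_length - moved) / max(speed, 1e-12), max_time - t_rel)
      segs[[length(segs) + 1L]] <- c(t_rel, dur, speed_signed, 0)
      moved <- moved + speed * dur
    } else {
      dur <- min(rexp(1, 1 / pause_mean_duration), max_time - t_rel)
      segs[[length(segs) + 1L]] <- c(t_rel, dur, 0, 1)
    }
    t_rel <- t_rel + dur
    running <- !running
  }
  m <- do.call(rbind, segs)
  colnames(m) <- c("start", "duration", "velocity", "paused")
  m
}

# Position and pause state at relative times `tq` for a segment table.
eval_motion <- function(segs, x0, tq) {
  starts <- segs[, "start"]
  ends <- starts + segs[, "duration"]
  # displacement accumulated at each segment start
  disp0 <- c(0, cumsum(segs[, "velocity"] * segs[, "duration"]))
  idx <- findInterval(tq, starts)
  idx[idx < 1L] <- 1L
  x <- unname(x0 + disp0[idx] + segs[idx, "velocity"] * (tq - starts[idx]))
  list(x = x, paused = unname(segs[idx, "paused"] == 1),
       total_end = unname(ends[nrow(segs)]))
}

# Exact time spent paused inside [a, b] according to the segment table.
paused_time_in <- function(segs, a, b) {
  starts <- segs[, "start"]
  ends <- starts + segs[, "duration"]
  ov <- pmax(0, pmin(ends, b) - pmax(starts, a))
  sum(ov[segs[, "paused"] == 1])
}

#' Simulate single-particle tracks in a microfluidic groove
#'
#' Generates seeded synthetic tracks with the statistical structure the
#' downstream kinetics analysis assumes: per-track run speed from a
#' truncated normal, alternating exponential runs and pauses (two-state
#' Markov motion), Gaussian localization noise, exponential visible run
#' length (censoring by defocus), and an imaging window that clips what is
#' observed. With `label_onset = TRUE` every motile particle departs the
#' axon tip (`x = groove_length`) at `t = 0`, emulating dye application at
#' the tip when imaging starts.
#'
#' @param config A [sim_track_config()].
#' @return A list of class `sim_tracks` with elements
#'   * `spots`: tibble of observed points (`track_id`, `movie`, `frame`,
#'     `t`, `x`, `y`, `intensity`, `channel`, `replicate`);
#'   * `truth`: one row per generated track: direction, run speed, net
#'     speed over the observed span, censoring flag, and two paused-time
#'     fractions — `percent_pausing_true` (continuous-time fraction of the
#'     observed span spent in the paused state) and `percent_pausing_obs`
#'     (the thresholded-velocity pause observable, default
#'     [kinetics_config()] settings, evaluated on the noise-free
#'     trajectory — the recovery target for [detect_pauses()]);
#'   * `config`: the configuration used.
#' @examples
#' sim <- simulate_tracks(sim_track_config(n_tracks = 5, seed = 1))
#' dplyr::count(sim$spots, track_id)
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_track_config"))
  with_seed(config$seed, simulate_tracks_impl(config))
}

simulate_tracks_impl <- function(config) {
  geom <- config$geometry
  dt <- 1 / config$frame_rate
  n_frames_movie <- floor(config$movie_duration * config$frame_rate)
  frame_times <- (0:n_frames_movie) * dt

  spots <- list()
  truth <- list()
  id <- 0L
  for (m in seq_len(config$n_movies)) {
    n_m <- if (config$poisson_n) rpois(1, config$n_tracks) else config$n_tracks
    if (n_m == 0) next
    dirs <- sample(
      c("retrograde", "anterograde", "stationary"),
      n_m, replace = TRUE, prob = config$direction_mix
    )
    speeds <- rtruncnorm1(
      n_m, config$speed_mean, config$speed_sd,
      config$speed_min, config$speed_max
    )
    speeds[dirs == "stationary"] <- 0
    for (i in seq_len(n_m)) {
      id <- id + 1L
      motile <- dirs[i] != "stationary"
      vis <- if (motile) {
        rexp(1, 1 / config$visible_length_mean)
      } else {
        Inf
      }
      if (config$label_onset && motile) {
        x0 <- geom$groove_length
        t0 <- 0
      } else {
        x0 <- runif(1, geom$window_start, geom$window_end)
        t0 <- runif(1, 0, max(0, config$movie_duration - 2 * dt))
      }
      v_signed <- switch(dirs[i],
        retrograde = -speeds[i],
        anterograde = speeds[i],
        stationary = 0
      )
      max_rel <- config$movie_duration - t0
      if (motile) {
        segs <- build_motion_segments(
          v_signed, config$pause_entry_rate, config$pause_mean_duration,
          vis, max_rel
        )
      } else {
        life <- min(
          rexp(1, config$speed_mean / config$visible_length_mean),
          max_rel
        )
        segs <- matrix(c(0, life, 0, 1),
          nrow = 1,
          dimnames = list(NULL, c("start", "duration", "velocity", "paused"))
        )
      }
      t_end_rel <- segs[nrow(segs), "start"] + segs[nrow(segs), "duration"]
      keep_t <- frame_times >= t0 & frame_times <= t0 + t_end_rel + 1e-9
      tq <- frame_times[keep_t]
      frames <- which(keep_t) - 1L
      n_emitted <- 0L
      span <- NA_real_
      paused_frac <- NA_real_
      paused_frac_obs <- NA_real_
      net_speed_true <- NA_real_
      if (length(tq) >= 2) {
        ev <- eval_motion(segs, x0, tq - t0)
        inside <- ev$x >= geom$window_start - 1e-9 &
          ev$x <= geom$window_end + 1e-9 &
          ev$x >= 0 & ev$x <= geom$groove_length
        if (sum(inside) >= 2) {
          tq_i <- tq[inside]
          xi <- ev$x[inside]
          # the pause observable (thresholded central-difference velocity,
          # default analysis settings) evaluated on the noise-free
          # trajectory: the estimator-correct recovery target
          obs_cfg <- kinetics_config()
          v_true <- velocity_one(xi, tq_i, obs_cfg$velocity_window)
          p_true <- pauses_one(tq_i, v_true, obs_cfg)
          x_obs <- xi + rnorm(length(xi), 0, config$localization_sd)
          x_obs <- pmin(pmax(x_obs, geom$window_start), geom$window_end)
          y_obs <- rnorm(length(xi), 0, config$localization_sd)
          n_emitted <- length(xi)
          span <- tq_i[n_emitted] - tq_i[1]
          paused_frac <- paused_time_in(
            segs, tq_i[1] - t0, tq_i[n_emitted] - t0
          ) / span
          paused_frac_obs <- min(sum(p_true$duration), span) / span
          net_speed_true <- abs(xi[n_emitted] - xi[1]) / span
          spots[[length(spots) + 1L]] <- tibble(
            track_id = id,
            movie = m,
            frame = frames[inside],
            t = tq_i,
            x = x_obs,
            y = y_obs,
            intensity = 52,
            channel = "A",
            replicate = 1L
          )
        }
      }
      truth[[length(truth) + 1L]] <- tibble(
        track_id = id, movie = m, direction = dirs[i],
        speed = speeds[i], x0 = x0, t0 = t0,
        visible_length = vis,
        censored = is.finite(vis) && t_end_rel < max_rel,
        n_frames = n_emitted,
        span = span,
        net_speed_true = net_speed_true,
        percent_pausing_true = 100 * paused_frac,
        percent_pausing_obs = 100 * paused_frac_obs
      )
    }
  }
  structure(
    list(
      spots = if (length(spots)) dplyr::bind_rows(spots) else empty_spots(),
      truth = dplyr::bind_rows(truth),
      config = config
    ),
    class = "sim_tracks"
  )
}

empty_spots <- function() {
  tibble(
    track_id = integer(), movie = integer(), frame = integer(),
    t = numeric(), x = numeric(), y = numeric(), intensity = numeric(),
    channel = character(), replicate = integer()
  )
}

#' @export
print.sim_tracks <- function(x, ...) {
  cat(sprintf(
    "<sim_tracks> %d tracks generated, %d emitted (%d spots), %d movie(s)\n",
    nrow(x$truth), dplyr::n_distinct(x$spots$track_id), nrow(x$spots),
    x$config$n_movies
  ))
  invisible(x)
}

#' Simulate a dual-channel track experiment
#'
#' Builds a two-channel data set in which a configurable fraction of
#' channel-A tracks have a channel-B partner sharing the same true
#' trajectory (each channel re-observed with independent localization
#' noise), emulating co-transported particles; the remaining B tracks are
#' generated independently from `config_b` so the two channels' speed
#' distributions can differ.
#'
#' @param config_a,config_b [sim_track_config()] for each channel; B's
#'   `n_tracks` counts only the independent (non-partnered) B tracks.
#' @param coloc_fraction Fraction of A tracks given a B partner, in `[0, 1]`.
#'   The number of partners is `round(coloc_fraction * n_A_emitted)`.
#' @param seed Integer seed.
#' @return A list of class `sim_dual` with `spots_a`, `spots_b`, `pairs`
#'   (ground-truth partner table), `truth_a`, `truth_b`.
#' @export
simulate_dual_channel <- function(config_a, config_b, coloc_fraction,
                                  seed = NULL) {
  if (coloc_fraction < 0 || coloc_fraction > 1) {
    abort("`coloc_fraction` must lie in [0, 1].")
  }
  with_seed(seed, {
    sim_a <- simulate_tracks_impl(config_a)
    sim_b <- simulate_tracks_impl(config_b)
    ids_a <- sort(unique(sim_a$spots$track_id))
    # the partnered count is set by the number of *generated* A tracks, so
    # a configured fraction gives a deterministic pair count by construction
    n_pairs <- min(
      round(coloc_fraction * nrow(sim_a$truth)),
      length(ids_a)
    )
    partner_ids <- if (n_pairs > 0) {
      sort(ids_a[sample.int(length(ids_a), n_pairs)])
    } else {
      integer()
    }
    offset <- if (nrow(sim_b$truth)) max(sim_b$truth$track_id) else 0L
    partners <- sim_a$spots |>
      dplyr::filter(.data$track_id %in% partner_ids) |>
      dplyr::mutate(
        partner_a = .data$track_id,
        track_id = offset + match(.data$track_id, !!partner_ids),
        channel = "B",
        # only observed (noisy) positions exist per channel, so the partner
        # is re-observed around the A observation with independent
        # localization error
        x = .data$x + rnorm(dplyr::n(), 0, config_b$localization_sd),
        y = .data$y + rnorm(dplyr::n(), 0, config_b$localization_sd)
      )
    geom_b <- config_b$geometry
    partners$x <- pmin(pmax(partners$x, geom_b$window_start), geom_b$window_end)
    pairs <- partners |>
      dplyr::distinct(.data$partner_a, .data$track_id) |>
      dplyr::rename(track_id_a = "partner_a", track_id_b = "track_id")
    spots_b <- dplyr::bind_rows(
      sim_b$spots,
      dplyr::select(partners, -"partner_a")
    )
    structure(
      list(
        spots_a = sim_a$spots,
        spots_b = spots_b,
        pairs = pairs,
        truth_a = sim_a$truth,
        truth_b = sim_b$truth
      ),
      class = "sim_dual"
    )
  })
}

#' Render a kymograph image from a track table
#'
#' Produces the standard time-versus-position representation of axonal
#' transport: rows are frames, columns are position bins across the imaging
#' window, and every observed spot is rendered as a Gaussian intensity
#' profile of width `psf_sd`. Moving particles appear as sloped lines whose
#' slope equals their speed.
#'
#' @param spots A spots tibble (needs `frame`, `x`, `intensity`).
#' @param geometry An [axon_geometry()]; sets the position axis.
#' @param psf_sd Gaussian profile sd in um (default 0.2).
#' @param background_noise_sd Additive Gaussian background noise (AU).
#' @param bin_width Position bin width in um (default 0.2).
#' @param n_frames Number of rows; defaults to `max(frame) + 1`.
#' @param seed Seed for the background noise.
#' @return A numeric matrix (frames x position bins) with attributes
#'   `positions` (bin centres, um) and `dt_frames`.
#' @export
render_kymograph <- function(spots, geometry = axon_geometry(),
                             psf_sd = 0.2, background_noise_sd = 0,
                             bin_width = 0.2, n_frames = NULL, seed = NULL) {
  if (psf_sd <= 0) abort("`psf_sd` must be positive.")
  if (is.null(n_frames)) {
    if (nrow(spots) == 0) abort("Empty track table and no `n_frames` given.")
    n_frames <- max(spots$frame) + 1L
  }
  centres <- seq(
    geometry$window_start + bin_width / 2, geometry$window_end, by = bin_width
  )
  img <- matrix(0, nrow = n_frames, ncol = length(centres))
  if (nrow(spots) > 0) {
    for (r in seq_len(nrow(spots))) {
      row <- spots$frame[r] + 1L
      if (row < 1 || row > n_frames) next
      prof <- exp(-((centres - spots$x[r])^2) / (2 * psf_sd^2))
      img[row, ] <- img[row, ] + spots$intensity[r] * prof
    }
  }
  if (background_noise_sd > 0) {
    img <- img + with_seed(
      seed,
      matrix(rnorm(length(img), 0, background_noise_sd), nrow = n_frames)
    )
  }
  attr(img, "positions") <- centres
  attr(img, "dt_frames") <- 1L
  img
}
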
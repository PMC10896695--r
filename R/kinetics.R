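check_track_table <- function(spots) {
  need <- c("track_id", "frame", "t", "x")
  miss <- setdiff(need, names(spots))
  if (length(miss)) {
    abort(paste0("Track table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(spots)
}

velocity_one <- function(x, t, window) {
  n <- length(x)
  # shorter tracks degrade gracefully to fully one-sided differences
  w <- (min(window, n) - 1L) %/% 2L
  w <- max(w, 1L)
  i <- seq_len(n)
  lo <- pmax(1L, i - w)
  hi <- pmin(n, i + w)
  (x[hi] - x[lo]) / (t[hi] - t[lo])
}

#' Instantaneous velocity along the axon axis
#'
#' Central-difference signed velocity per frame:
#' `v_i = (x[i+w] - x[i-w]) / (t[i+w] - t[i-w])` with
#' `w = (velocity_window - 1) / 2`; endpoints fall back to one-sided
#' differences. Negative values are retrograde (toward the cell body) under
#' the package's coordinate convention.
#'
#' @param spots Track table (`track_id`, `frame`, `t`, `x`, ...); may hold
#'   many tracks.
#' @param config A [kinetics_config()].
#' @return The input tibble with a `velocity` column appended (um/s).
#' @export
instantaneous_velocity <- function(spots, config = kinetics_config()) {
  check_track_table(spots)
  shortest <- min(table(spots$track_id))
  if (shortest < config$velocity_window) {
    abort("Velocity window larger than the shortest track.")
  }
  spots |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(
      velocity = velocity_one(.data$x, .data$t, config$velocity_window)
    ) |>
    dplyr::ungroup()
}

pauses_one <- function(t, v, config) {
  sub <- abs(v) < config$pause_speed_threshold
  n_frames <- length(t)
  dt <- median(diff(t))
  r <- rle(sub)
  vals <- r$values
  lens <- r$lengths
  # single-frame interruptions of a pause are smoothed away (same rationale
  # as the minimum pause duration: one-frame threshold crossings are noise)
  i <- 2L
  while (i < length(vals)) {
    if (!vals[i] && lens[i] == 1L && vals[i - 1] && vals[i + 1]) {
      lens[i - 1] <- lens[i - 1] + lens[i] + lens[i + 1]
      vals <- vals[-c(i, i + 1L)]
      lens <- lens[-c(i, i + 1L)]
    } else {
      i <- i + 1L
    }
  }
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  keep <- which(vals)
  # each sub-threshold frame contributes one frame interval of dwell,
  # capped at the track span so pauses can never exceed the duration
  out <- tibble(
    start = t[starts[keep]],
    end = t[ends[keep]],
    duration = pmin(lens[keep], n_frames - 1L) * dt
  )
  dplyr::filter(out, .data$duration >= config$min_pause_duration)
}

#' Detect pauses in tracks
#'
#' A pause is a maximal run of frames whose instantaneous speed is below
#' `pause_speed_threshold` (0.1 um/s by default) lasting at least
#' `min_pause_duration`. Events are reported per track with start, end and
#' duration in seconds.
#'
#' @inheritParams instantaneous_velocity
#' @return Tibble (`track_id`, `start`, `end`, `duration`); zero rows when
#'   no track pauses.
#' @export
detect_pauses <- function(spots, config = kinetics_config()) {
  sv <- instantaneous_velocity(spots, config)
  sv |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(
      \(d, g) pauses_one(d$t, d$velocity, config)
    ) |>
    dplyr::ungroup()
}

summary_one <- function(d, config) {
  o <- order(d$frame)
  x <- d$x[o]
  t <- d$t[o]
  dur <- t[length(t)] - t[1]
  if (dur <= 0) abort("Zero-duration track.")
  net <- x[length(x)] - x[1]
  path <- sum(abs(diff(x)))
  v <- velocity_one(x, t, config$velocity_window)
  p <- pauses_one(t, v, config)
  paused <- min(sum(p$duration), dur)
  motile <- abs(net) >= config$motile_min_displacement
  tibble(
    direction = if (!motile) {
      "stationary"
    } else if (net < 0) {
      "retrograde"
    } else {
      "anterograde"
    },
    mean_speed = if (config$speed_definition == "net") {
      abs(net) / dur
    } else {
      path / dur
    },
    mean_speed_net = abs(net) / dur,
    mean_speed_path = path / dur,
    run_length = abs(net),
    duration = dur,
    first_t = t[1],
    n_pauses = nrow(p),
    mean_pause_duration = if (nrow(p)) mean(p$duration) else NA_real_,
    percent_pausing = 100 * paused / dur,
    max_abs_velocity = max(abs(v)),
    passed_motile_filter = motile
  )
}

#' Per-track kinetics summaries
#'
#' Computes, for every track, the quantities reported per particle: mean
#' speed (net displacement over duration by default, matching "speed from
#' the beginning to the end of their track"; path-based also reported), run
#' length, direction by sign of net displacement (tracks moving less than
#' `motile_min_displacement` are stationary), pause metrics, percent of
#' time pausing, and the maximum absolute instantaneous velocity.
#'
#' @inheritParams instantaneous_velocity
#' @return Tibble with one row per track. Carries through `movie`,
#'   `replicate` and `channel` columns when present.
#' @examples
#' sim <- simulate_tracks(sim_track_config(n_tracks = 10, seed = 1))
#' track_summaries(sim$spots)
#' @export
track_summaries <- function(spots, config = kinetics_config()) {
  check_track_table(spots)
  meta <- intersect(c("movie", "replicate", "channel"), names(spots))
  out <- spots |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(\(d, g) summary_one(d, config)) |>
    dplyr::ungroup()
  if (length(meta)) {
    out <- spots |>
      dplyr::select("track_id", dplyr::all_of(meta)) |>
      dplyr::distinct(.data$track_id, .keep_all = TRUE) |>
      dplyr::right_join(out, by = "track_id")
  }
  out
}

sem <- function(x) sd(x) / sqrt(length(x))

#' Population-level kinetics summary
#'
#' Aggregates per-track summaries into the population tables reported for
#' each condition: motile-track means with SEM per direction (over tracks,
#' and over biological replicates when a `replicate` column is present —
#' both are reported because figure-level SEM is computed over replicates),
#' plus direction fractions over all tracks.
#'
#' @inheritParams instantaneous_velocity
#' @return An object of class `kinetics_population` with `tracks` (per
#'   track), `by_direction`, `by_replicate` (or `NULL`),
#'   `direction_fractions` and `status` (`"ok"` or `"empty"` when no track
#'   passes the motile filter).
#' @export
population_summary <- function(spots, config = kinetics_config()) {
  tracks <- track_summaries(spots, config)
  motile <- dplyr::filter(tracks, .data$passed_motile_filter)
  fractions <- tracks |>
    dplyr::count(.data$direction, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  if (nrow(motile) == 0) {
    return(structure(
      list(
        tracks = tracks, by_direction = NULL, by_replicate = NULL,
        direction_fractions = fractions, status = "empty"
      ),
      class = "kinetics_population"
    ))
  }
  by_direction <- motile |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(
      n_tracks = dplyr::n(),
      sem_speed = sem(.data$mean_speed),
      mean_speed = mean(.data$mean_speed),
      mean_run_length = mean(.data$run_length),
      sem_run_length = sem(.data$run_length),
      sem_percent_pausing = sem(.data$percent_pausing),
      mean_percent_pausing = mean(.data$percent_pausing),
      mean_n_pauses = mean(.data$n_pauses),
      .groups = "drop"
    ) |>
    dplyr::select(
      "direction", "n_tracks", "mean_speed", "sem_speed",
      "mean_run_length", "sem_run_length", "mean_percent_pausing",
      "sem_percent_pausing", "mean_n_pauses"
    )
  by_replicate <- NULL
  if ("replicate" %in% names(motile)) {
    rep_means <- motile |>
      dplyr::group_by(.data$direction, .data$replicate) |>
      dplyr::summarise(
        mean_speed = mean(.data$mean_speed),
        mean_percent_pausing = mean(.data$percent_pausing),
        n_tracks = dplyr::n(),
        .groups = "drop"
      )
    by_replicate <- rep_means |>
      dplyr::group_by(.data$direction) |>
      dplyr::summarise(
        n_replicates = dplyr::n(),
        sem_speed = sem(.data$mean_speed),
        mean_speed = mean(.data$mean_speed),
        sem_percent_pausing = sem(.data$mean_percent_pausing),
        mean_percent_pausing = mean(.data$mean_percent_pausing),
        .groups = "drop"
      ) |>
      dplyr::select(
        "direction", "n_replicates", "mean_speed", "sem_speed",
        "mean_percent_pausing", "sem_percent_pausing"
      )
  }
  structure(
    list(
      tracks = tracks, by_direction = by_direction,
      by_replicate = by_replicate, direction_fractions = fractions,
      status = "ok"
    ),
    class = "kinetics_population"
  )
}

#' @export
print.kinetics_population <- function(x, ...) {
  cat(sprintf(
    "<kinetics_population> %d tracks (%d motile), status: %s\n",
    nrow(x$tracks), sum(x$tracks$passed_motile_filter), x$status
  ))
  if (!is.null(x$by_direction)) print(x$by_direction)
  invisible(x)
}

#' @rdname population_summary
#' @param x A `kinetics_population` object.
#' @param ... Unused.
#' @export
tidy.kinetics_population <- function(x, ...) {
  x$by_direction %||%
    tibble(
      direction = character(), n_tracks = integer(), mean_speed = numeric()
    )
}

#' @rdname population_summary
#' @export
glance.kinetics_population <- function(x, ...) {
  tibble(
    n_tracks = nrow(x$tracks),
    n_motile = sum(x$tracks$passed_motile_filter),
    status = x$status
  )
}

#' Motile-event frequency per movie
#'
#' Counts tracks passing the motile filter in the stated direction in each
#' movie and converts to events per minute; the per-movie values are what
#' the study averages over videos.
#'
#' @inheritParams instantaneous_velocity
#' @param movie_duration Movie length in seconds.
#' @param direction `"retrograde"` (default) or `"anterograde"`.
#' @param n_movies Total number of movies (so movies with zero events are
#'   included); defaults to the movies present in the table.
#' @return Tibble (`movie`, `n_events`, `events_per_min`).
#' @export
event_frequency <- function(spots, movie_duration,
                            direction = "retrograde",
                            config = kinetics_config(), n_movies = NULL) {
  if (movie_duration <= 0) abort("`movie_duration` must be positive.")
  tracks <- track_summaries(spots, config)
  if (!"movie" %in% names(tracks)) tracks$movie <- 1L
  movies <- if (is.null(n_movies)) {
    sort(unique(tracks$movie))
  } else {
    seq_len(n_movies)
  }
  counts <- tracks |>
    dplyr::filter(.data$passed_motile_filter, .data$direction == !!direction) |>
    dplyr::count(.data$movie, name = "n_events")
  tibble(movie = movies) |>
    dplyr::left_join(counts, by = "movie") |>
    dplyr::mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      events_per_min = .data$n_events / (movie_duration / 60)
    )
}

#' First-arrival time of a motile particle
#'
#' For movies whose start coincides with label onset at the axon tip,
#' returns the time (minutes) of the first frame of the earliest track that
#' passes the motile filter in the given direction — the observable used to
#' discriminate stable cargo binding from motor exchange.
#'
#' @inheritParams event_frequency
#' @return Tibble (`movie`, `observed`, `arrival_min`); `observed = FALSE`
#'   and `NA` arrival when no qualifying track exists ("not observed").
#' @export
first_arrival_time <- function(spots, direction = "retrograde",
                               config = kinetics_config(), n_movies = NULL) {
  if (nrow(spots) == 0) {
    movies <- seq_len(n_movies %||% 1L)
    return(tibble(
      movie = movies, observed = FALSE, arrival_min = NA_real_
    ))
  }
  tracks <- track_summaries(spots, config)
  if (!"movie" %in% names(tracks)) tracks$movie <- 1L
  movies <- if (is.null(n_movies)) {
    sort(unique(tracks$movie))
  } else {
    seq_len(n_movies)
  }
  arrivals <- tracks |>
    dplyr::filter(.data$passed_motile_filter, .data$direction == !!direction) |>
    dplyr::group_by(.data$movie) |>
    dplyr::summarise(arrival_min = min(.data$first_t) / 60, .groups = "drop")
  tibble(movie = movies) |>
    dplyr::left_join(arrivals, by = "movie") |>
    dplyr::mutate(observed = !is.na(.data$arrival_min)) |>
    dplyr::select("movie", "observed", "arrival_min")
}
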
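#' Match tracks across two simultaneously imaged channels
#'
#' Candidate pairs are tracks with at least `min_overlap_frames` common
#' frames; a pair matches when the fraction of overlapping frames at
#' separation below `max_separation` is at least `min_overlap_fraction`.
#' Matched pairs are assigned one-to-one greedily by ascending mean
#' separation (ties broken by track ids), which is deterministic and, at
#' the track densities of these experiments, effectively optimal.
#'
#' @param spots_a,spots_b Track tables sharing the same frame clock
#'   (`track_id`, `frame`, `t`, `x`; `y` optional).
#' @param max_separation Distance threshold in um (default 0.5,
#'   sub-diffraction-scale proximity).
#' @param min_overlap_fraction Fraction of overlapping frames that must be
#'   close (default 0.5).
#' @param min_overlap_frames Minimum temporal overlap in frames (default 3).
#' @return Tibble of class-free matches: `track_id_a`, `track_id_b`,
#'   `overlap_frames`, `overlap_fraction` (of the shorter track),
#'   `mean_separation` (um), `close_fraction`.
#' @export
match_tracks <- function(spots_a, spots_b, max_separation = 0.5,
                         min_overlap_fraction = 0.5,
                         min_overlap_frames = 3) {
  check_track_table(spots_a)
  check_track_table(spots_b)
  empty <- tibble(
    track_id_a = integer(), track_id_b = integer(),
    overlap_frames = integer(), overlap_fraction = numeric(),
    mean_separation = numeric(), close_fraction = numeric()
  )
  if (nrow(spots_a) == 0 || nrow(spots_b) == 0) {
    return(empty)
  }
  dt_a <- median(diff(sort(unique(spots_a$t))))
  dt_b <- median(diff(sort(unique(spots_b$t))))
  if (is.finite(dt_a) && is.finite(dt_b) &&
        abs(dt_a - dt_b) > 1e-6 * max(dt_a, dt_b)) {
    abort("The two channels have different frame rates.")
  }
  ya <- if ("y" %in% names(spots_a)) spots_a$y else 0
  yb <- if ("y" %in% names(spots_b)) spots_b$y else 0
  a <- tibble(
    id_a = spots_a$track_id, frame = spots_a$frame, xa = spots_a$x, ya = ya
  )
  b <- tibble(
    id_b = spots_b$track_id, frame = spots_b$frame, xb = spots_b$x, yb = yb
  )
  len_a <- dplyr::count(a, .data$id_a, name = "len_a")
  len_b <- dplyr::count(b, .data$id_b, name = "len_b")
  joint <- dplyr::inner_join(a, b, by = "frame", relationship = "many-to-many")
  if (nrow(joint) == 0) {
    return(empty)
  }
  cand <- joint |>
    dplyr::mutate(
      sep = sqrt((.data$xa - .data$xb)^2 + (.data$ya - .data$yb)^2)
    ) |>
    dplyr::group_by(.data$id_a, .data$id_b) |>
    dplyr::summarise(
      overlap_frames = dplyr::n(),
      mean_separation = mean(.data$sep),
      close_fraction = mean(.data$sep < max_separation),
      .groups = "drop"
    ) |>
    dplyr::left_join(len_a, by = "id_a") |>
    dplyr::left_join(len_b, by = "id_b") |>
    dplyr::mutate(
      overlap_fraction = .data$overlap_frames / pmin(.data$len_a, .data$len_b)
    ) |>
    dplyr::filter(
      .data$overlap_frames >= min_overlap_frames,
      .data$close_fraction >= min_overlap_fraction
    ) |>
    dplyr::arrange(.data$mean_separation, .data$id_a, .data$id_b)
  used_a <- used_b <- character()
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    ka <- as.character(cand$id_a[r])
    kb <- as.character(cand$id_b[r])
    if (!(ka %in% used_a) && !(kb %in% used_b)) {
      keep[r] <- TRUE
      used_a <- c(used_a, ka)
      used_b <- c(used_b, kb)
    }
  }
  cand[keep, ] |>
    dplyr::transmute(
      track_id_a = .data$id_a, track_id_b = .data$id_b,
      overlap_frames = .data$overlap_frames,
      overlap_fraction = .data$overlap_fraction,
      mean_separation = .data$mean_separation,
      close_fraction = .data$close_fraction
    ) |>
    dplyr::arrange(.data$track_id_a, .data$track_id_b)
}

#' Summarize two-channel colocalization
#'
#' Computes the percent of colocalized tracks relative to each channel
#' (both are reported because the two channels can hold very different
#' track counts) and per-group speed summaries for A-only, B-only and
#' matched tracks. When a [kinetics_config()] is supplied, percentages are
#' taken over motile tracks only.
#'
#' @param matches Output of [match_tracks()] on these tables.
#' @param spots_a,spots_b The two channel track tables.
#' @param config Optional [kinetics_config()]; when given, only tracks
#'   passing the motile filter are counted and speed summaries use it.
#' @return An object of class `coloc_summary` with counts, percentages and
#'   a `speeds` tibble (`group`, `n`, `mean_speed`, `sem_speed`).
#' @export
summarize_colocalization <- function(matches, spots_a, spots_b,
                                     config = NULL) {
  kin <- config %||% kinetics_config()
  sum_a <- track_summaries(spots_a, kin)
  sum_b <- track_summaries(spots_b, kin)
  if (!is.null(config)) {
    sum_a <- dplyr::filter(sum_a, .data$passed_motile_filter)
    sum_b <- dplyr::filter(sum_b, .data$passed_motile_filter)
    matches <- dplyr::filter(
      matches,
      .data$track_id_a %in% sum_a$track_id,
      .data$track_id_b %in% sum_b$track_id
    )
  }
  n_a <- nrow(sum_a)
  n_b <- nrow(sum_b)
  n_m <- nrow(matches)
  grp <- function(d, label) {
    tibble(
      group = label, n = nrow(d),
      mean_speed = if (nrow(d)) mean(d$mean_speed) else NA_real_,
      sem_speed = if (nrow(d) > 1) sem(d$mean_speed) else NA_real_
    )
  }
  speeds <- dplyr::bind_rows(
    grp(dplyr::filter(sum_a, !.data$track_id %in% matches$track_id_a), "A_only"),
    grp(dplyr::filter(sum_b, !.data$track_id %in% matches$track_id_b), "B_only"),
    grp(dplyr::filter(sum_a, .data$track_id %in% matches$track_id_a), "matched")
  )
  structure(
    list(
      n_a = n_a, n_b = n_b, n_matched = n_m,
      percent_of_a = if (n_a) 100 * n_m / n_a else 0,
      percent_of_b = if (n_b) 100 * n_m / n_b else 0,
      speeds = speeds,
      matches = matches
    ),
    class = "coloc_summary"
  )
}

#' @export
print.coloc_summary <- function(x, ...) {
  cat(sprintf(
    "<coloc_summary> %d matches: %.1f%% of %d A tracks, %.1f%% of %d B tracks\n",
    x$n_matched, x$percent_of_a, x$n_a, x$percent_of_b, x$n_b
  ))
  print(x$speeds)
  invisible(x)
}

#' @rdname summarize_colocalization
#' @param x A `coloc_summary` object.
#' @param ... Unused.
#' @export
tidy.coloc_summary <- function(x, ...) {
  x$speeds
}

#' @rdname summarize_colocalization
#' @export
glance.coloc_summary <- function(x, ...) {
  tibble(
    n_a = x$n_a, n_b = x$n_b, n_matched = x$n_matched,
    percent_of_a = x$percent_of_a, percent_of_b = x$percent_of_b
  )
}
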
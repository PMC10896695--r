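trackmate_cols <- c(
  track_id = "TRACK_ID", frame = "FRAME", t = "POSITION_T",
  x = "POSITION_X", y = "POSITION_Y", intensity = "MEAN_INTENSITY"
)

#' Read a track table in the TrackMate-export dialect
#'
#' Reads a spots table as exported by particle-tracking software
#' (columns `TRACK_ID`, `FRAME`, `POSITION_T`, `POSITION_X`, and optionally
#' `POSITION_Y`, `MEAN_INTENSITY`), normalizes units to micrometres and
#' seconds with 0-based frames, and validates the result: a missing
#' required column, non-monotone frames within a track, and duplicated
#' (track, frame) rows are each distinct errors. Secondary header rows
#' (long names / units) that some exporters emit are skipped.
#'
#' @param path CSV or TSV file.
#' @param position_unit `"um"` (default) or `"nm"`.
#' @param time_unit `"s"` (default), `"ms"`, or `"frame"` (converted with
#'   `frame_rate`; a warning records the unit assumption when `POSITION_T`
#'   is absent and times are derived from frames).
#' @param frame_rate Hz, used only when times must be derived from frames.
#' @return Tibble (`track_id`, `frame`, `t`, `x`, `y`, `intensity`).
#' @export
read_tracks <- function(path, position_unit = c("um", "nm"),
                        time_unit = c("s", "ms", "frame"),
                        frame_rate = NULL) {
  position_unit <- match.arg(position_unit)
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  required <- trackmate_cols[c("track_id", "frame", "x")]
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    abort(paste0("Missing required column(s): ", paste(miss, collapse = ", ")))
  }
  # drop TrackMate's extra header rows (long names, units) if present
  numeric_frame <- suppressWarnings(!is.na(as.numeric(raw[[trackmate_cols["frame"]]])))
  raw <- raw[numeric_frame, , drop = FALSE]
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  out <- tibble(
    track_id = num("TRACK_ID"),
    frame = as.integer(num("FRAME")),
    t = if ("POSITION_T" %in% names(raw)) num("POSITION_T") else NA_real_,
    x = num("POSITION_X"),
    y = if ("POSITION_Y" %in% names(raw)) num("POSITION_Y") else 0,
    intensity = if ("MEAN_INTENSITY" %in% names(raw)) {
      num("MEAN_INTENSITY")
    } else {
      NA_real_
    }
  )
  if (position_unit == "nm") {
    out$x <- out$x / 1000
    out$y <- out$y / 1000
  }
  if (all(is.na(out$t))) {
    if (is.null(frame_rate)) {
      abort("No POSITION_T column; supply `frame_rate` to derive times.")
    }
    warn("No POSITION_T column: deriving times from frames (assumed 0-based).")
    out$t <- out$frame / frame_rate
  } else if (time_unit == "ms") {
    out$t <- out$t / 1000
  } else if (time_unit == "frame") {
    if (is.null(frame_rate)) abort("`time_unit = \"frame\"` needs `frame_rate`.")
    out$t <- out$t / frame_rate
  }
  dup <- duplicated(out[c("track_id", "frame")])
  if (any(dup)) {
    abort(sprintf(
      "Duplicated (track, frame) rows, first at track %s frame %d.",
      out$track_id[dup][1], out$frame[dup][1]
    ))
  }
  out <- dplyr::arrange(out, .data$track_id, .data$frame)
  mono <- out |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(ok = all(diff(.data$frame) > 0), .groups = "drop")
  if (any(!mono$ok)) {
    abort(sprintf(
      "Non-monotone frames within track %s.", mono$track_id[!mono$ok][1]
    ))
  }
  out
}

#' Write a track set in the TrackMate-export dialect
#'
#' Writes the three-table export: a spots file (per-spot rows), an edges
#' file (frame-to-frame displacements) and a tracks summary file.
#'
#' @param spots Track table (`track_id`, `frame`, `t`, `x`, ...).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default "sim").
#' @return Invisibly, the paths written (named `spots`, `edges`, `tracks`).
#' @export
write_tracks <- function(spots, dir, prefix = "sim") {
  check_track_table(spots)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    spots = file.path(dir, paste0(prefix, "_spots.csv")),
    edges = file.path(dir, paste0(prefix, "_edges.csv")),
    tracks = file.path(dir, paste0(prefix, "_tracks.csv"))
  )
  spots_out <- tibble(
    TRACK_ID = spots$track_id,
    FRAME = spots$frame,
    POSITION_T = spots$t,
    POSITION_X = spots$x,
    POSITION_Y = if ("y" %in% names(spots)) spots$y else 0,
    MEAN_INTENSITY = if ("intensity" %in% names(spots)) spots$intensity else NA
  )
  readr::write_csv(spots_out, paths["spots"], progress = FALSE)
  edges <- spots |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::reframe(
      FRAME_SOURCE = head(.data$frame, -1),
      FRAME_TARGET = tail(.data$frame, -1),
      DISPLACEMENT = abs(diff(.data$x)),
      DT = diff(.data$t)
    ) |>
    dplyr::rename(TRACK_ID = "track_id")
  readr::write_csv(edges, paths["edges"], progress = FALSE)
  tracks <- spots |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(TRACK_ID = .data$track_id) |>
    dplyr::summarise(
      NUMBER_SPOTS = dplyr::n(),
      TRACK_START = min(.data$t),
      TRACK_STOP = max(.data$t),
      TRACK_DISPLACEMENT = abs(.data$x[dplyr::n()] - .data$x[1]),
      .groups = "drop"
    )
  readr::write_csv(tracks, paths["tracks"], progress = FALSE)
  invisible(paths)
}

#' Read or write columnar intensity traces
#'
#' Traces travel as plain CSV with columns `trace_id` (optional on read for
#' a single trace), `frame`, `t`, `intensity`.
#'
#' @param path CSV file.
#' @return `read_traces()` returns a tibble; `write_traces()` its input,
#'   invisibly.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"intensity" %in% names(out)) {
    abort("Missing required column: intensity")
  }
  if (!"trace_id" %in% names(out)) out$trace_id <- 1L
  if (!"frame" %in% names(out)) {
    out <- out |>
      dplyr::group_by(.data$trace_id) |>
      dplyr::mutate(frame = dplyr::row_number() - 1L) |>
      dplyr::ungroup()
  }
  out
}

#' @rdname read_traces
#' @param traces Tibble with `trace_id`, `frame`, `t`, `intensity`.
#' @export
write_traces <- function(traces, path) {
  readr::write_csv(traces, path, progress = FALSE)
  invisible(traces)
}

#' Write a kymograph matrix as TIFF
#'
#' Stores a [render_kymograph()] image as a 32-bit float TIFF (intensities
#' rescaled to `[0, 1]`; the scale factor is returned so values can be
#' recovered).
#'
#' @param img Matrix from [render_kymograph()].
#' @param path Output .tif path.
#' @return Invisibly, the scale factor applied.
#' @export
write_kymograph_tiff <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("Package 'tiff' is required to write TIFF kymographs.")
  }
  lo <- min(img)
  hi <- max(img)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((img - lo) / scale, path, bits.per.sample = 32L)
  invisible(scale)
}

#' Default pipeline configuration
#'
#' One structured configuration covering every stage, with each default
#' traceable to an imaging-study value (2 Hz tracking, 30 Hz bleaching,
#' 0.1 um/s pause threshold, 10 um motile filter, ~26 AU step intensity,
#' 500 um groove at 1.76 um/s) or a documented package design decision.
#' Serialized as YAML by [write_pipeline_config()].
#'
#' @return A nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function() {
  structure(
    list(
      seed = 1L,
      geometry = list(groove_length = 500, window_start = 0, window_end = 110),
      tracks = list(
        frame_rate = 2, n_tracks = 50, speed_mean = 1.76, speed_sd = 0.5,
        speed_min = 0.3, speed_max = 5.0, pause_entry_rate = 0.05,
        pause_mean_duration = 4, localization_sd = 0.05,
        visible_length_mean = 35, label_onset = FALSE, movie_duration = 240,
        n_movies = 1
      ),
      traces = list(
        frame_rate = 30, n_traces = 100, n_frames = 600,
        molecule_count_pmf = list("1" = 0.6, "2" = 0.25, "3" = 0.15),
        copies_per_molecule = 2, labeling_efficiency = 0.9,
        step_intensity_mean = 26, step_intensity_sd = 4, bleach_rate = 0.25,
        noise_sd = 6, background = 20
      ),
      kinetics = list(
        pause_speed_threshold = 0.1, motile_min_displacement = 10,
        velocity_window = 3, min_pause_duration = 1.0,
        speed_definition = "net"
      ),
      coloc = list(
        max_separation = 0.5, min_overlap_fraction = 0.5,
        min_overlap_frames = 3
      ),
      steps = list(penalty = NULL, max_steps = 10, min_segment = 5),
      arrival = list(
        groove_length = 500, speed = 1.76, pause_fraction = 0,
        run_length_mean = 2, rebind_wait_mean = 5, n_replicates = 200
      ),
      stats = list(alpha = 0.05, adjustment = "holm")
    ),
    class = "pipeline_config"
  )
}

#' @rdname default_pipeline_config
#' @param config A `pipeline_config` list.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_pipeline_config())
  for (sec in names(cfg)) {
    if (is.list(base[[sec]]) && is.list(cfg[[sec]])) {
      base[[sec]] <- modifyList(base[[sec]], cfg[[sec]])
    } else {
      base[[sec]] <- cfg[[sec]]
    }
  }
  structure(base, class = "pipeline_config")
}
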
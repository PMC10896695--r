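#' Microfluidic groove geometry
#'
#' Describes the one-dimensional geometry used throughout the package: a
#' microfluidic groove of `groove_length` micrometres connecting the
#' somatodendritic compartment (x = 0) to the axonal compartment
#' (x = `groove_length`), with an imaging window `[window_start, window_end]`
#' at the proximal end. The defaults mirror a 500 um groove observed through
#' a ~110 um field of view.
#'
#' @param groove_length Groove length in um (default 500).
#' @param window_start,window_end Imaging window bounds in um
#'   (defaults 0 and 110).
#' @return An object of class `axon_geometry`.
#' @examples
#' axon_geometry()
#' @export
axon_geometry <- function(groove_length = 500, window_start = 0,
                          window_end = 110) {
  if (!is.numeric(groove_length) || groove_length <= 0) {
    abort("`groove_length` must be a positive number.")
  }
  if (!(window_start >= 0 && window_start < window_end &&
          window_end <= groove_length)) {
    abort("Require 0 <= window_start < window_end <= groove_length.")
  }
  structure(
    list(
      groove_length = groove_length,
      window_start = window_start,
      window_end = window_end
    ),
    class = "axon_geometry"
  )
}

#' @export
print.axon_geometry <- function(x, ...) {
  cat(sprintf(
    "<axon_geometry> groove %g um, imaging window [%g, %g] um\n",
    x$groove_length, x$window_start, x$window_end
  ))
  invisible(x)
}

#' Configuration for the synthetic track generator
#'
#' Parameterizes [simulate_tracks()]. Motion is a two-state (run/pause)
#' continuous-time Markov process with a constant per-track run speed drawn
#' from a truncated normal distribution, Gaussian localization noise per
#' frame, and exponential visible run length emulating particles drifting
#' out of focus. Defaults reflect retrograde dynein transport imaged at
#' 2 Hz: mean speed 1.76 um/s within the observed 0.3-5.0 um/s range.
#'
#' @param geometry An [axon_geometry()].
#' @param frame_rate Acquisition rate in Hz (default 2).
#' @param n_tracks Tracks to generate per movie.
#' @param direction_mix Named fractions for `retrograde`, `anterograde`,
#'   `stationary`; must sum to 1.
#' @param speed_mean,speed_sd Mean and sd of per-track run speed (um/s).
#' @param speed_min,speed_max Truncation bounds for the speed draw (um/s;
#'   defaults 0.3 and 5.0).
#' @param pause_entry_rate Rate of entering a pause while running (per s).
#' @param pause_mean_duration Mean pause duration (s).
#' @param localization_sd Gaussian localization noise sd (um; default 0.03,
#'   typical near-single-molecule HILO precision; chosen so that the
#'   velocity noise of the default 3-frame central difference stays well
#'   below the 0.1 um/s pause threshold).
#' @param visible_length_mean Mean of the exponential visible run length
#'   (um; default 35). Track ends are censoring events, not detachment.
#' @param label_onset If `TRUE`, motile particles start at
#'   `x = groove_length` at `t = 0`, emulating dye applied at the axon tip
#'   when the movie starts (the first-arrival experiment).
#' @param movie_duration Movie length in seconds.
#' @param n_movies Number of independent movies (default 1).
#' @param poisson_n If `TRUE`, the per-movie track count is drawn as
#'   Poisson(`n_tracks`) rather than fixed, giving a Poisson event flux.
#' @param seed Integer seed; same seed gives bit-identical output.
#' @return An object of class `sim_track_config`.
#' @export
sim_track_config <- function(geometry = axon_geometry(),
                             frame_rate = 2,
                             n_tracks = 50,
                             direction_mix = c(
                               retrograde = 0.7,
                               anterograde = 0.2,
                               stationary = 0.1
                             ),
                             speed_mean = 1.76,
                             speed_sd = 0.5,
                             speed_min = 0.3,
                             speed_max = 5.0,
                             pause_entry_rate = 0.05,
                             pause_mean_duration = 4,
                             localization_sd = 0.03,
                             visible_length_mean = 35,
                             label_onset = FALSE,
                             movie_duration = 240,
                             n_movies = 1,
                             poisson_n = FALSE,
                             seed = NULL) {
  stopifnot(inherits(geometry, "axon_geometry"))
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    abort("`frame_rate` must be positive.")
  }
  dm <- direction_mix[c("retrograde", "anterograde", "stationary")]
  if (anyNA(dm)) {
    abort("`direction_mix` needs retrograde, anterograde and stationary entries.")
  }
  if (any(dm < 0) || abs(sum(dm) - 1) > 1e-9) {
    abort("`direction_mix` fractions must be non-negative and sum to 1.")
  }
  if (speed_min >= speed_max) abort("`speed_min` must be below `speed_max`.")
  if (pause_entry_rate < 0 || pause_mean_duration < 0 ||
        localization_sd < 0 || visible_length_mean <= 0) {
    abort("Rates and scales must be non-negative (visible length positive).")
  }
  if (movie_duration <= 0) abort("`movie_duration` must be positive.")
  structure(
    list(
      geometry = geometry, frame_rate = frame_rate, n_tracks = n_tracks,
      direction_mix = dm, speed_mean = speed_mean, speed_sd = speed_sd,
      speed_min = speed_min, speed_max = speed_max,
      pause_entry_rate = pause_entry_rate,
      pause_mean_duration = pause_mean_duration,
      localization_sd = localization_sd,
      visible_length_mean = visible_length_mean,
      label_onset = label_onset, movie_duration = movie_duration,
      n_movies = n_movies, poisson_n = poisson_n, seed = seed
    ),
    class = "sim_track_config"
  )
}

#' Configuration for the synthetic bleaching-trace generator
#'
#' Parameterizes [simulate_bleach_traces()]. Each spot holds a number of
#' molecules drawn from `molecule_count_pmf`, each molecule carries
#' `copies_per_molecule` taggable subunits (2 for the dynein heavy chain,
#' 1 for the ARP11 subunit of dynactin), and each copy is labeled with
#' probability `labeling_efficiency`. Each labeled fluorophore contributes a
#' step intensity drawn once (mean ~26 AU) until its exponential bleaching
#' time; additive Gaussian noise is applied on top of a constant background.
#'
#' @param n_traces Number of traces.
#' @param frame_rate Acquisition rate in Hz (default 30).
#' @param n_frames Frames per trace (default 600, i.e. 20 s at 30 Hz).
#' @param molecule_count_pmf Named numeric vector: probability of each
#'   molecule count (names "1", "2", ...); must sum to 1.
#' @param copies_per_molecule Taggable copies per molecule.
#' @param labeling_efficiency Probability that a copy carries a fluorophore.
#' @param step_intensity_mean,step_intensity_sd Per-fluorophore intensity
#'   (AU; default mean 26).
#' @param bleach_rate Per-fluorophore bleaching rate (per s; default 0.25).
#' @param noise_sd Additive Gaussian noise sd (AU).
#' @param background Constant background level (AU).
#' @param seed Integer seed.
#' @return An object of class `sim_trace_config`.
#' @export
sim_trace_config <- function(n_traces = 100,
                             frame_rate = 30,
                             n_frames = 600,
                             molecule_count_pmf = c(
                               "1" = 0.6, "2" = 0.25, "3" = 0.15
                             ),
                             copies_per_molecule = 2,
                             labeling_efficiency = 0.9,
                             step_intensity_mean = 26,
                             step_intensity_sd = 4,
                             bleach_rate = 0.25,
                             noise_sd = 6,
                             background = 20,
                             seed = NULL) {
  if (frame_rate <= 0) abort("`frame_rate` must be positive.")
  if (length(molecule_count_pmf) == 0 || is.null(names(molecule_count_pmf))) {
    abort("`molecule_count_pmf` must be a named probability vector.")
  }
  if (any(molecule_count_pmf < 0) ||
        abs(sum(molecule_count_pmf) - 1) > 1e-9) {
    abort("`molecule_count_pmf` must be non-negative and sum to 1 (tol 1e-9).")
  }
  if (labeling_efficiency < 0 || labeling_efficiency > 1) {
    abort("`labeling_efficiency` must lie in [0, 1].")
  }
  if (step_intensity_mean < 0 || background < 0 || noise_sd < 0) {
    abort("Intensities must be non-negative.")
  }
  if (copies_per_molecule < 1 || copies_per_molecule != round(copies_per_molecule)) {
    abort("`copies_per_molecule` must be a positive integer.")
  }
  if (bleach_rate <= 0) abort("`bleach_rate` must be positive.")
  structure(
    list(
      n_traces = n_traces, frame_rate = frame_rate, n_frames = n_frames,
      molecule_count_pmf = molecule_count_pmf,
      copies_per_molecule = as.integer(copies_per_molecule),
      labeling_efficiency = labeling_efficiency,
      step_intensity_mean = step_intensity_mean,
      step_intensity_sd = step_intensity_sd,
      bleach_rate = bleach_rate, noise_sd = noise_sd,
      background = background, seed = seed
    ),
    class = "sim_trace_config"
  )
}

#' Kinetics thresholds and definitions
#'
#' Collects the parameters of the per-track kinetics analysis. Defaults
#' follow the analysis conventions of the imaging study the package
#' quantifies: pauses are frames slower than 0.1 um/s, only spots moving
#' more than 10 um (net) count as motile, instantaneous velocity is a
#' 3-frame central difference, and track speed is net displacement over
#' duration ("from the beginning to the end of their track").
#'
#' @param pause_speed_threshold Pause threshold (um/s, default 0.1).
#' @param motile_min_displacement Net displacement required to count a track
#'   as motile (um, default 10).
#' @param velocity_window Odd window (frames) of the central-difference
#'   instantaneous velocity (default 3).
#' @param min_pause_duration Minimum pause duration retained (s, default 1).
#' @param speed_definition `"net"` (net displacement / duration, default) or
#'   `"path"` (summed |dx| / duration).
#' @return An object of class `kinetics_config`.
#' @export
kinetics_config <- function(pause_speed_threshold = 0.1,
                            motile_min_displacement = 10,
                            velocity_window = 3,
                            min_pause_duration = 1.0,
                            speed_definition = c("net", "path")) {
  speed_definition <- match.arg(speed_definition)
  if (pause_speed_threshold <= 0 || motile_min_displacement <= 0 ||
        min_pause_duration <= 0) {
    abort("Kinetics thresholds must be positive.")
  }
  if (velocity_window < 1 || velocity_window %% 2 != 1) {
    abort("`velocity_window` must be a positive odd number of frames.")
  }
  structure(
    list(
      pause_speed_threshold = pause_speed_threshold,
      motile_min_displacement = motile_min_displacement,
      velocity_window = as.integer(velocity_window),
      min_pause_duration = min_pause_duration,
      speed_definition = speed_definition
    ),
    class = "kinetics_config"
  )
}

#' Configuration for first-arrival transport models
#'
#' Parameters shared by [stable_arrival()] and [exchange_arrival()]:
#' a labeled motor departs the axon tip (x = `groove_length`) at t = 0 and
#' must reach the proximal imaging window. Under stable binding it moves the
#' whole way at its run speed; under motor exchange it advances in
#' exponential runs of mean `run_length_mean` separated by stationary
#' rebinding waits of mean `rebind_wait_mean`.
#'
#' @param groove_length Distance to traverse (um, default 500).
#' @param speed Mean run speed (um/s, default 1.76).
#' @param speed_sd Between-particle speed sd used in simulation mode
#'   (um/s, default 0: all particles share `speed`).
#' @param pause_fraction Fraction of transit time spent paused, in `[0, 1)`.
#' @param run_length_mean Mean run length before detachment (um; exchange
#'   model, default 2).
#' @param rebind_wait_mean Mean wait before a labeled motor resumes moving
#'   (s; exchange model, default 5).
#' @param n_replicates Simulated particles (0 = closed form only).
#' @param seed Integer seed for simulation mode.
#' @return An object of class `arrival_config`.
#' @export
arrival_config <- function(groove_length = 500,
                           speed = 1.76,
                           speed_sd = 0,
                           pause_fraction = 0,
                           run_length_mean = 2,
                           rebind_wait_mean = 5,
                           n_replicates = 0,
                           seed = NULL) {
  if (groove_length <= 0) abort("`groove_length` must be positive.")
  if (speed <= 0) abort("`speed` must be positive.")
  if (pause_fraction < 0 || pause_fraction >= 1) {
    abort("`pause_fraction` must lie in [0, 1).")
  }
  if (run_length_mean <= 0) abort("`run_length_mean` must be positive.")
  if (rebind_wait_mean < 0) abort("`rebind_wait_mean` must be non-negative.")
  structure(
    list(
      groove_length = groove_length, speed = speed, speed_sd = speed_sd,
      pause_fraction = pause_fraction, run_length_mean = run_length_mean,
      rebind_wait_mean = rebind_wait_mean, n_replicates = n_replicates,
      seed = seed
    ),
    class = "arrival_config"
  )
}
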
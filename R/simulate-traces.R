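#' Simulate photobleaching intensity traces
#'
#' Generates seeded spot intensity traces with known stoichiometry for
#' validating the step detector. Each spot contains `m` molecules drawn from
#' `molecule_count_pmf`; each molecule carries `copies_per_molecule`
#' taggable subunits, each labeled independently with probability
#' `labeling_efficiency`, so the fluorophore count per spot is a mixture of
#' binomials (odd counts arise from partial labeling even with two copies
#' per molecule). Every fluorophore contributes its own step intensity
#' (drawn once) until an exponential bleaching time; the trace is the
#' background plus the sum of active fluorophores plus Gaussian noise.
#'
#' @param config A [sim_trace_config()].
#' @return A list of class `sim_traces` with
#'   * `traces`: tibble (`trace_id`, `frame`, `t`, `intensity`);
#'   * `truth`: tibble with one row per trace (`trace_id`, `n_molecules`,
#'     `n_fluorophores`, and list-columns `bleach_times` (s) and
#'     `step_sizes` (AU, one per fluorophore));
#'   * `config`.
#' @examples
#' sim <- simulate_bleach_traces(sim_trace_config(n_traces = 3, seed = 1))
#' sim$truth
#' @export
simulate_bleach_traces <- function(config) {
  stopifnot(inherits(config, "sim_trace_config"))
  with_seed(config$seed, {
    counts <- as.integer(names(config$molecule_count_pmf))
    if (anyNA(counts)) {
      abort("`molecule_count_pmf` names must be integer molecule counts.")
    }
    tgrid <- (seq_len(config$n_frames) - 1L) / config$frame_rate
    traces <- vector("list", config$n_traces)
    truth <- vector("list", config$n_traces)
    for (i in seq_len(config$n_traces)) {
      m <- counts[sample.int(length(counts), 1, prob = config$molecule_count_pmf)]
      f <- rbinom(1, m * config$copies_per_molecule, config$labeling_efficiency)
      bleach_times <- sort(rexp(f, config$bleach_rate))
      step_sizes <- pmax(
        rnorm(f, config$step_intensity_mean, config$step_intensity_sd), 0
      )
      signal <- rep(config$background, config$n_frames)
      if (f > 0) {
        for (k in seq_len(f)) {
          signal <- signal + step_sizes[k] * (tgrid < bleach_times[k])
        }
      }
      obs <- signal + rnorm(config$n_frames, 0, config$noise_sd)
      traces[[i]] <- tibble(
        trace_id = i,
        frame = seq_len(config$n_frames) - 1L,
        t = tgrid,
        intensity = obs
      )
      truth[[i]] <- tibble(
        trace_id = i,
        n_molecules = m,
        n_fluorophores = f,
        bleach_times = list(bleach_times),
        step_sizes = list(step_sizes)
      )
    }
    structure(
      list(
        traces = dplyr::bind_rows(traces),
        truth = dplyr::bind_rows(truth),
        config = config
      ),
      class = "sim_traces"
    )
  })
}

#' @export
print.sim_traces <- function(x, ...) {
  cat(sprintf(
    "<sim_traces> %d traces x %d frames at %g Hz\n",
    nrow(x$truth), x$config$n_frames, x$config$frame_rate
  ))
  invisible(x)
}

#' Exact fluorophore-count distribution implied by a labeling model
#'
#' Enumerates the mixture-of-binomials distribution of fluorophores per
#' spot: `sum_m pmf(m) * Binomial(m * copies, efficiency)`. Used as the
#' analytic ground truth for the stoichiometry of simulated populations.
#'
#' @inheritParams sim_trace_config
#' @return A tibble with `n_fluorophores` and `probability`.
#' @examples
#' fluorophore_count_pmf(c("1" = 0.6, "2" = 0.25, "3" = 0.15), 2, 0.9)
#' @export
fluorophore_count_pmf <- function(molecule_count_pmf, copies_per_molecule,
                                  labeling_efficiency) {
  counts <- as.integer(names(molecule_count_pmf))
  kmax <- max(counts) * copies_per_molecule
  p <- numeric(kmax + 1)
  for (j in seq_along(counts)) {
    n <- counts[j] * copies_per_molecule
    p[seq_len(n + 1)] <- p[seq_len(n + 1)] +
      molecule_count_pmf[j] * stats::dbinom(0:n, n, labeling_efficiency)
  }
  tibble(n_fluorophores = 0:kmax, probability = p)
}
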
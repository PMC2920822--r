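#' Synthetic probe map for one chromosome
#'
#' Generates strictly increasing probe positions on a single chromosome with
#' the p/q arm boundary at the midpoint (the first `floor(n/2)` probes are
#' p-arm).  `gap_model = "uniform"` places probes at constant spacing `gap`
#' (deterministic); `"lognormal"` draws gaps from a log-normal distribution,
#' emulating the wide inter-probe distance disparities of high-density
#' arrays.
#'
#' @param n_probes number of probes (at least 2).
#' @param gap_model `"uniform"` or `"lognormal"`.
#' @param seed integer seed (used by the lognormal model).
#' @param chromosome chromosome label (default `"1"`).
#' @param gap constant spacing in bp for the uniform model (default 1000).
#' @param meanlog,sdlog log-normal gap parameters (defaults
#'   `log(1000)`, 1: median gap 1000 bp with heavy right tail).
#' @return A [probe_map()].
#' @export
make_probe_map <- function(n_probes, gap_model = c("uniform", "lognormal"),
                           seed = 1L, chromosome = "1", gap = 1000,
                           meanlog = log(1000), sdlog = 1) {
  gap_model <- match.arg(gap_model)
  stopifnot(is_count(n_probes, min = 2L))
  gaps <- if (gap_model == "uniform") {
    rep(gap, n_probes - 1L)
  } else {
    set.seed(seed)
    pmax(1, round(rlnorm(n_probes - 1L, meanlog, sdlog)))
  }
  positions <- as.integer(1 + cumsum(c(0, gaps)))
  arm <- rep(c("p", "q"), c(floor(n_probes / 2), n_probes - floor(n_probes / 2)))
  probe_map(sprintf("P%05d", seq_len(n_probes)),
            rep(chromosome, n_probes), positions, arm)
}

#' A planted gain/loss event
#'
#' @param carriers integer indices (1-based) of the carrier samples.
#' @param start_probe,end_probe inclusive probe index range of the event.
#' @param amplitude log2-ratio shift added to carriers over the range;
#'   positive = gain, negative = loss.
#' @return A list of class `planted_event`.
#' @export
planted_event <- function(carriers, start_probe, end_probe, amplitude) {
  stopifnot(length(carriers) >= 1L, is_count(start_probe),
            is_count(end_probe), start_probe <= end_probe,
            is_scalar_num(amplitude))
  structure(list(carriers = sort(unique(as.integer(carriers))),
                 start_probe = as.integer(start_probe),
                 end_probe = as.integer(end_probe),
                 amplitude = as.double(amplitude)),
            class = "planted_event")
}

#' Generate an aCGH-like cohort with planted events
#'
#' Each entry is the sum of the amplitudes of the planted events carried by
#' the sample and covering the probe (overlapping events add), plus
#' independent Gaussian probe noise with standard deviation `noise_sd`.
#' Bit-identical under a fixed seed.
#'
#' @param n_samples number of samples.
#' @param probe_map a [probe_map()].
#' @param events list of [planted_event()] objects (may be empty).
#' @param noise_sd nonnegative Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return List with `profiles` (a [profile_matrix()]) and `events` (the
#'   ground-truth list).
#' @export
generate_dataset <- function(n_samples, probe_map, events = list(),
                             noise_sd = 0.3, seed = 1L) {
  validate_probe_map(probe_map)
  stopifnot(is_count(n_samples), is_scalar_num(noise_sd), noise_sd >= 0)
  p <- nrow(probe_map)
  for (ev in events) {
    stopifnot(inherits(ev, "planted_event"))
    if (ev$end_probe > p || max(ev$carriers) > n_samples) {
      stop("planted event out of range", call. = FALSE)
    }
    if (length(unique(probe_map$chromosome[ev$start_probe:ev$end_probe])) > 1L) {
      stop("planted event spans more than one chromosome", call. = FALSE)
    }
  }
  set.seed(seed)
  values <- matrix(rnorm(n_samples * p, 0, noise_sd), n_samples, p)
  for (ev in events) {
    rng <- ev$start_probe:ev$end_probe
    values[ev$carriers, rng] <- values[ev$carriers, rng] + ev$amplitude
  }
  profiles <- profile_matrix(values, probe_map,
                             sprintf("S%03d", seq_len(n_samples)))
  list(profiles = profiles, events = events)
}

#' Named fixture scenarios
#'
#' Preset cohorts spanning the event spectrum seen in tumor aCGH studies:
#'
#' * `"single-event"` (alias `"focal-gain"`): one +1.0 gain over 40 probes
#'   carried by 30% of samples — the canonical recovery benchmark.
#' * `"arm-loss"`: a -1.0 loss of the whole q arm, 30% prevalence.
#' * `"whole-chromosome"`: a +0.8 gain of every probe, 20% prevalence.
#' * `"nested"`: a 30%-prevalence whole-q-arm loss, with a +1.0 focal p-arm
#'   gain carried by half the loss carriers (15% of the cohort) — exercises
#'   depth-2 recovery under orthogonality.
#' * `"noise"`: no events (null cohort).
#'
#' Carriers are drawn at random under `seed`; noise is Gaussian.
#'
#' @param scenario scenario name.
#' @param n_samples cohort size (default 60).
#' @param n_probes probes on the single simulated chromosome (default 200).
#' @param noise_sd Gaussian probe noise sd (default 0.3).
#' @param seed integer seed.
#' @return As [generate_dataset()], plus `scenario`.
#' @export
scenario_dataset <- function(scenario = c("single-event", "focal-gain",
                                          "arm-loss", "whole-chromosome",
                                          "nested", "noise"),
                             n_samples = 60L, n_probes = 200L,
                             noise_sd = 0.3, seed = 1L) {
  scenario <- match.arg(scenario)
  pm <- make_probe_map(n_probes, "uniform", seed = seed)
  q_start <- floor(n_probes / 2) + 1L
  set.seed(seed)
  pick <- function(frac, from = seq_len(n_samples)) {
    sort(sample(from, max(1L, round(frac * length(from)))))
  }
  events <- switch(scenario,
    "single-event" = ,
    "focal-gain" = {
      lo <- round(0.4 * n_probes) + 1L
      list(planted_event(pick(0.3), lo, lo + round(0.2 * n_probes) - 1L, 1.0))
    },
    "arm-loss" = list(planted_event(pick(0.3), q_start, n_probes, -1.0)),
    "whole-chromosome" = list(planted_event(pick(0.2), 1L, n_probes, 0.8)),
    "nested" = {
      outer <- pick(0.3)
      inner <- pick(0.5, from = outer)
      lo <- round(0.15 * n_probes) + 1L
      list(planted_event(outer, q_start, n_probes, -1.0),
           planted_event(inner, lo, lo + round(0.1 * n_probes) - 1L, 1.0))
    },
    "noise" = list())
  out <- generate_dataset(n_samples, pm, events, noise_sd, seed)
  out$scenario <- scenario
  out
}

#' Ground-truth carrier flags of a planted event
#'
#' @param event a [planted_event()].
#' @param n_samples cohort size.
#' @return Integer vector of 0/1 carrier flags, length `n_samples`.
#' @export
event_membership <- function(event, n_samples) {
  as.integer(seq_len(n_samples) %in% event$carriers)
}
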
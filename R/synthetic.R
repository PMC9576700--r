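#' Specification of a synthetic MEA well
#'
#' Describes a ground-truth-known synthetic 64-electrode well: synchronized
#' network bursts recur as a jittered-regular renewal process at
#' `burst_rate`; during each burst, participating electrodes fire Poisson
#' spikes at `intra_burst_rate`; sparse background Poisson spiking runs
#' throughout; spikes are later embedded as stereotyped biphasic waveforms
#' in Gaussian noise ([embed_spikes_in_voltage()]). Burst onsets are drawn
#' as a renewal process with small inter-burst-interval jitter
#' (`interval_cv`, coefficient of variation <= 0.2) rather than as a Poisson
#' process: Poisson onsets have a flat spectrum and would carry no spectral
#' peak for the pipeline to recover.
#'
#' @param n_electrodes electrodes per well
#' @param duration recording length (s)
#' @param fs raw sampling rate (Hz)
#' @param burst_rate network-burst rate (Hz); feasible range ~0.05-1
#' @param burst_duration burst length (s); must satisfy
#'   `burst_duration < 1/burst_rate`
#' @param intra_burst_rate per-electrode firing rate inside a burst (Hz)
#' @param background_rate per-electrode background rate (Hz)
#' @param participation probability an electrode joins a given burst
#' @param spike_amplitude_sd spike amplitude in multiples of the noise SD
#' @param noise_sd noise standard deviation (µV)
#' @param interval_cv coefficient of variation of inter-burst intervals
#' @param seed integer seed
#' @return An object of class `synthetic_well_spec`.
#' @export
synthetic_well_spec <- function(n_electrodes = 64, duration = 300,
                                fs = 12500, burst_rate = 0.25,
                                burst_duration = 0.3,
                                intra_burst_rate = 120,
                                background_rate = 1,
                                participation = 0.9,
                                spike_amplitude_sd = 8, noise_sd = 5,
                                interval_cv = 0.1, seed = 1L) {
  rates <- c(burst_rate = burst_rate, intra_burst_rate = intra_burst_rate,
             background_rate = background_rate)
  if (any(rates < 0)) stop("invalid-config: rates must be >= 0")
  if (participation < 0 || participation > 1)
    stop("invalid-config: participation must be in [0, 1]")
  if (burst_rate > 0 && burst_duration * burst_rate >= 1)
    stop("invalid-config: burst duration x rate must be < 1 (bursts overlap)")
  if (interval_cv < 0 || interval_cv > 0.2)
    stop("invalid-config: interval_cv must be in [0, 0.2] so a spectral peak exists")
  structure(list(n_electrodes = as.integer(n_electrodes),
                 duration = as.numeric(duration), fs = as.numeric(fs),
                 burst_rate = burst_rate, burst_duration = burst_duration,
                 intra_burst_rate = intra_burst_rate,
                 background_rate = background_rate,
                 participation = participation,
                 spike_amplitude_sd = spike_amplitude_sd,
                 noise_sd = noise_sd, interval_cv = interval_cv,
                 seed = as.integer(seed)),
            class = "synthetic_well_spec")
}

#' Generate a bursting spike raster with ground truth
#'
#' Draws burst onsets as a jittered-regular renewal process (intervals
#' normal with mean `1/burst_rate` and CV `interval_cv`, truncated at
#' ±3 SD), assigns participating electrodes per burst, fills bursts with
#' Poisson spikes at the intra-burst rate, adds background Poisson spikes,
#' and returns both the raster and its exact ground truth.
#'
#' @param spec a [synthetic_well_spec()]
#' @return list with `raster` (a [spike_raster()], kind `"electrode"`) and
#'   `ground_truth` (burst onsets, per-electrode true spike times, spec
#'   echo).
#' @export
generate_burst_raster <- function(spec) {
  stopifnot(inherits(spec, "synthetic_well_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(spec$seed)
  onsets <- numeric(0)
  if (spec$burst_rate > 0) {
    mu <- 1 / spec$burst_rate
    sd <- spec$interval_cv * mu
    t <- stats::rnorm(1, mu / 2, sd)  # phase of the first burst
    while (t < spec$duration - spec$burst_duration) {
      onsets <- c(onsets, max(t, 0))
      gap <- stats::rnorm(1, mu, sd)
      gap <- min(max(gap, mu - 3 * sd), mu + 3 * sd)
      t <- t + gap
    }
  }
  times <- vector("list", spec$n_electrodes)
  for (e in seq_len(spec$n_electrodes)) {
    spk <- numeric(0)
    if (spec$background_rate > 0) {
      n_bg <- stats::rpois(1, spec$background_rate * spec$duration)
      spk <- stats::runif(n_bg, 0, spec$duration)
    }
    for (on in onsets) {
      if (stats::runif(1) <= spec$participation) {
        n_in <- stats::rpois(1, spec$intra_burst_rate * spec$burst_duration)
        spk <- c(spk, stats::runif(n_in, on, on + spec$burst_duration))
      }
    }
    times[[e]] <- unique(sort(spk))
  }
  raster <- spike_raster(times, duration = spec$duration,
                         source_ids = seq_len(spec$n_electrodes),
                         kind = "electrode")
  list(raster = raster,
       ground_truth = list(burst_onsets = onsets,
                           spike_times = times, spec = spec))
}

#' Stereotyped biphasic spike waveform
#'
#' Fixed ~1 ms negative-then-positive template, unit negative peak,
#' sampled at `fs`. Versioned constant of the generator.
#'
#' @param fs sampling frequency (Hz)
#' @return numeric vector; its minimum is -1 at the alignment sample
#' @export
spike_template <- function(fs = 12500) {
  n <- max(7L, as.integer(round(fs / 1000)) + 1L)  # ~1 ms support
  tt <- seq(0, 1, length.out = n)
  w <- -sin(2 * pi * tt) * exp(-3 * tt)  # damped biphasic: sharp trough, soft rebound
  w / max(abs(w))
}

#' Embed spike times into noisy raw voltage
#'
#' Per electrode, draws Gaussian noise of the specified SD and adds the
#' [spike_template()] scaled to `spike_amplitude_sd * noise_sd`, aligned so
#' the template's negative extremum falls at each spike time.
#'
#' @param raster a [spike_raster()] whose duration matches the spec
#' @param spec a [synthetic_well_spec()]
#' @return A [voltage_recording()] at `spec$fs`.
#' @export
embed_spikes_in_voltage <- function(raster, spec) {
  stopifnot(inherits(raster, "spike_raster"),
            inherits(spec, "synthetic_well_spec"))
  if (abs(raster$duration - spec$duration) > 1e-9)
    stop("invalid-config: raster duration does not match the well spec")
  if (spec$spike_amplitude_sd <= 0)
    stop("invalid-config: spike amplitude must be > 0")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(derive_seed(spec$seed, "voltage"))
  n_samp <- as.integer(round(spec$duration * spec$fs))
  tpl <- spike_template(spec$fs) * spec$spike_amplitude_sd * spec$noise_sd
  align <- which.min(tpl)  # negative extremum lands on the spike time
  out <- matrix(0, n_samp, length(raster$times))
  for (e in seq_along(raster$times)) {
    v <- stats::rnorm(n_samp, sd = spec$noise_sd)
    for (t in raster$times[[e]]) {
      i0 <- as.integer(round(t * spec$fs)) + 1L - (align - 1L)
      idx <- seq(i0, i0 + length(tpl) - 1L)
      ok <- idx >= 1L & idx <= n_samp
      v[idx[ok]] <- v[idx[ok]] + tpl[ok]
    }
    out[, e] <- v
  }
  voltage_recording(out, fs = spec$fs, electrode_ids = raster$source_ids)
}
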
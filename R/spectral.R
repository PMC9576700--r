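`%||%` <- function(a, b) if (is.null(a)) b else a

#' Welch estimator settings
#'
#' Defaults: Hann window, segment length 2^16 samples (about 65.5 s at
#' 1 kHz, frequency resolution about 0.015 Hz) with 50% overlap. When
#' `segment_length` is `NULL` it is taken as `min(2^16, length(train))`, so
#' shorter recordings fall back to a single full-length segment (still
#' resolving sub-1 Hz peaks: a 60 s train gives about 0.017 Hz resolution).
#'
#' @param segment_length samples per Welch segment, or `NULL` for automatic
#' @param overlap fractional overlap between segments in \[0, 1)
#' @param window window name; only `"hann"` is implemented
#' @return A `welch_settings` list.
#' @export
welch_settings <- function(segment_length = NULL, overlap = 0.5,
                           window = "hann") {
  if (!is.null(segment_length) &&
      (!is.numeric(segment_length) || segment_length < 8))
    stop("invalid-config: segment_length must be >= 8 samples")
  if (overlap < 0 || overlap >= 1)
    stop("invalid-config: overlap must be in [0, 1)")
  window <- match.arg(window, "hann")
  structure(list(segment_length = if (is.null(segment_length)) NULL
                 else as.integer(segment_length),
                 overlap = as.numeric(overlap), window = window),
            class = "welch_settings")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)

#' Welch power spectral density of a binary spike train
#'
#' Averaged modified periodogram over Hann-windowed, overlapping,
#' mean-detrended segments of the 1 kHz binary train; one-sided density
#' scaling. The per-segment mean is removed so the (excluded) DC component
#' does not leak into the sub-1 Hz band of interest.
#'
#' @param train a [binned_train()]
#' @param settings a [welch_settings()]
#' @return A `raw_spectrum`: list with `freq` (Hz, ascending from 0),
#'   `power`, `n_segments`, `settings`, `source_id`, and a `degenerate` flag
#'   for all-zero input.
#' @export
welch_psd <- function(train, settings = welch_settings()) {
  stopifnot(inherits(train, "binned_train"))
  x <- as.numeric(train$x)
  n <- length(x)
  fs <- train$fs
  nseg <- settings$segment_length %||% min(65536L, n)
  if (n < nseg)
    stop("invalid-input: train of ", n / fs,
         " s is shorter than one Welch segment; need at least ",
         nseg / fs, " s")
  step <- max(1L, as.integer(floor(nseg * (1 - settings$overlap))))
  starts <- seq.int(1L, n - nseg + 1L, by = step)
  win <- hann_window(nseg)
  scale <- 1 / (fs * sum(win^2))
  n_freq <- nseg %/% 2L + 1L
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(stats::fft(seg)[seq_len(n_freq)])^2 * scale
    # one-sided: double everything except DC and (for even nseg) Nyquist
    dbl <- rep(2, n_freq); dbl[1] <- 1
    if (nseg %% 2L == 0L) dbl[n_freq] <- 1
    acc <- acc + sp * dbl
  }
  structure(list(freq = (seq_len(n_freq) - 1) * fs / nseg,
                 power = acc / length(starts),
                 n_segments = length(starts),
                 settings = settings,
                 source_id = train$source_id,
                 degenerate = all(train$x == 0L)),
            class = "raw_spectrum")
}

#' Surrogate spectrum from randomly permuted spike trains
#'
#' Randomly permutes the 1 ms bins of the binary train (spike count exactly
#' preserved, temporal patterning destroyed) and averages the Welch PSD over
#' `n_surrogates` independent permutations. Dividing the signal PSD by this
#' surrogate removes rate and flat-noise structure.
#'
#' @param train a [binned_train()]
#' @param n_surrogates number of permutations averaged
#' @param seed integer seed making the permutations reproducible
#' @param settings a [welch_settings()]
#' @param method `"bin"` permutes 1 ms bins (default); `"isi"` shuffles
#'   inter-spike intervals instead
#' @return A `raw_spectrum` (average over permutations).
#' @export
surrogate_spectrum <- function(train, n_surrogates = 1, seed = 1L,
                               settings = welch_settings(),
                               method = c("bin", "isi")) {
  method <- match.arg(method)
  stopifnot(inherits(train, "binned_train"))
  if (sum(train$x) == 0L)
    stop("degenerate-input: empty train has no surrogate spectrum")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- length(train$x)
  acc <- NULL
  for (k in seq_len(n_surrogates)) {
    xs <- if (method == "bin") {
      train$x[sample.int(n)]
    } else {
      idx <- which(train$x == 1L)
      gaps <- diff(c(0L, idx))
      pos <- cumsum(gaps[sample.int(length(gaps))])
      out <- integer(n); out[pos] <- 1L; out
    }
    stopifnot(sum(xs) == sum(train$x))  # permutation invariant
    sp <- welch_psd(binned_train(xs, train$duration, train$source_id),
                    settings)
    acc <- if (is.null(acc)) sp$power else acc + sp$power
    freq <- sp$freq; n_segments <- sp$n_segments
  }
  structure(list(freq = freq, power = acc / n_surrogates,
                 n_segments = n_segments, settings = settings,
                 source_id = train$source_id, degenerate = FALSE,
                 n_surrogates = as.integer(n_surrogates)),
            class = "raw_spectrum")
}

#' Decibel ratio of a signal spectrum against its surrogate
#'
#' Computes `10 * log10(P_signal / P_surrogate)` per frequency bin. Powers
#' are floored at the smallest positive observed power times 1e-6 before the
#' ratio, so sparse trains cannot divide by zero; the result records whether
#' the floor was applied.
#'
#' @param signal,surrogate `raw_spectrum` objects on identical frequency
#'   grids
#' @return A `db_spectrum`: list with `freq`, `power_db`, `source_id`,
#'   `n_surrogates`, `settings`, `floored`.
#' @export
db_ratio <- function(signal, surrogate) {
  if (length(signal$freq) != length(surrogate$freq) ||
      any(signal$freq != surrogate$freq))
    stop("invalid-input: signal and surrogate frequency grids differ")
  pos <- c(signal$power[signal$power > 0], surrogate$power[surrogate$power > 0])
  if (!length(pos))
    stop("degenerate-input: both spectra are identically zero")
  eps <- min(pos) * 1e-6
  floored <- any(signal$power < eps) || any(surrogate$power < eps)
  structure(list(freq = signal$freq,
                 power_db = 10 * log10(pmax(signal$power, eps) /
                                         pmax(surrogate$power, eps)),
                 source_id = signal$source_id,
                 n_surrogates = surrogate$n_surrogates %||% NA_integer_,
                 settings = signal$settings,
                 floored = floored),
            class = "db_spectrum")
}

#' @export
print.db_spectrum <- function(x, ...) {
  cat(sprintf("dB spectrum: %d bins, %.4g-%.4g Hz (resolution %.4g Hz), %s surrogates\n",
              length(x$freq), min(x$freq), max(x$freq),
              x$freq[2] - x$freq[1], x$n_surrogates))
  invisible(x)
}

#' Peak network-burst frequency with the sub-1 Hz inclusion rule
#'
#' Locates the global maximum of the surrogate-normalized spectrum over all
#' frequencies above 0 (the DC bin is never eligible). If the maximum falls
#' in the half-open band (0, 1\] Hz its frequency is returned; a global peak
#' outside the band means the train does not exhibit the slow synchronous
#' bursting of interest and the result is flagged excluded, never clamped
#' into band. A spectrum whose global maximum does not exceed 0 dB carries
#' no temporal patterning beyond its own permuted surrogate (the chance
#' level) and is likewise excluded, with reason `"no-patterning"`. Exact
#' ties resolve to the lowest frequency and are flagged.
#'
#' @param spectrum a [db_ratio()] `db_spectrum`
#' @param band upper band edge (Hz) of the inclusion rule
#' @return A `burst_frequency_result`: list with `source_id`,
#'   `peak_frequency` (Hz, `NA` when excluded), `peak_db`, `excluded`,
#'   `reason`, `tie`, `band`.
#' @export
peak_burst_frequency <- function(spectrum, band = 1) {
  stopifnot(inherits(spectrum, "db_spectrum"))
  keep <- spectrum$freq > 0
  f <- spectrum$freq[keep]
  p <- spectrum$power_db[keep]
  res <- list(source_id = spectrum$source_id, peak_frequency = NA_real_,
              peak_db = NA_real_, excluded = TRUE, reason = "", tie = FALSE,
              band = band)
  if (!length(p) || diff(range(p)) == 0) {
    res$reason <- "degenerate-spectrum"
    return(structure(res, class = "burst_frequency_result"))
  }
  at_max <- which(p == max(p))
  res$tie <- length(at_max) > 1L
  i <- at_max[1L]  # lowest-frequency winner on exact ties
  if (p[i] <= 0) {
    res$reason <- "no-patterning"
    res$peak_db <- p[i]
    return(structure(res, class = "burst_frequency_result"))
  }
  if (f[i] <= band) {
    res$peak_frequency <- f[i]
    res$peak_db <- p[i]
    res$excluded <- FALSE
  } else {
    res$reason <- "peak-outside-band"
    res$peak_db <- p[i]
  }
  structure(res, class = "burst_frequency_result")
}

#' @export
print.burst_frequency_result <- function(x, ...) {
  if (x$excluded)
    cat(sprintf("Burst frequency [%s]: excluded (%s)\n", x$source_id, x$reason))
  else
    cat(sprintf("Burst frequency [%s]: %.4g Hz (%.2f dB)%s\n", x$source_id,
                x$peak_frequency, x$peak_db, if (x$tie) " [tie]" else ""))
  invisible(x)
}

#' Population-average surrogate-normalized spectrum
#'
#' Runs the full per-source chain (1 kHz binning, Welch PSD, permuted
#' surrogate, dB ratio) for every source with at least one spike and
#' averages the dB spectra across sources.
#'
#' @param raster a [spike_raster()]
#' @param settings a [welch_settings()]
#' @param n_surrogates surrogate permutations per source
#' @param seed master seed; per-source surrogate seeds are derived from it
#' @return A `db_spectrum` whose `source_id` is `"population-average"`, with
#'   `n_sources` used and `n_skipped` empty sources recorded.
#' @export
population_average_spectrum <- function(raster, settings = welch_settings(),
                                        n_surrogates = 1, seed = 1L) {
  stopifnot(inherits(raster, "spike_raster"))
  trains <- bin_to_1khz(raster)
  nonempty <- which(vapply(trains, function(tr) sum(tr$x) > 0L, logical(1)))
  if (!length(nonempty))
    stop("degenerate-input: all spike trains are empty")
  acc <- NULL
  for (i in nonempty) {
    sig <- welch_psd(trains[[i]], settings)
    sur <- surrogate_spectrum(trains[[i]], n_surrogates,
                              seed = derive_seed(seed, "surrogate", i),
                              settings = settings)
    db <- db_ratio(sig, sur)
    acc <- if (is.null(acc)) db$power_db else acc + db$power_db
    freq <- db$freq
  }
  structure(list(freq = freq, power_db = acc / length(nonempty),
                 source_id = "population-average",
                 n_surrogates = as.integer(n_surrogates),
                 settings = settings,
                 n_sources = length(nonempty),
                 n_skipped = length(trains) - length(nonempty),
                 floored = FALSE),
            class = "db_spectrum")
}

#' Normalized change in peak frequency relative to an isogenic control
#'
#' `(median(mutant) - median(wt)) / median(wt)`: negative values mean the
#' mutant bursts more slowly than its isogenic wild type.
#'
#' @param mutant_peaks,wt_peaks numeric vectors of per-source peak
#'   frequencies (Hz); `NA`s (excluded sources) are dropped
#' @return numeric scalar
#' @export
normalize_to_isogenic <- function(mutant_peaks, wt_peaks) {
  m <- stats::median(mutant_peaks, na.rm = TRUE)
  w <- stats::median(wt_peaks, na.rm = TRUE)
  if (!length(mutant_peaks) || !length(wt_peaks) || is.na(m) || is.na(w))
    stop("degenerate-input: empty peak collection")
  if (w == 0) stop("degenerate-input: zero wild-type median")
  (m - w) / w
}

#' Derive a reproducible sub-seed
#'
#' Stable integer hash of (master seed, stage name, replicate index), kept
#' below 2^31 so it is a valid R seed. Used so every stage of a run draws
#' from an independent, reconstructible stream.
#'
#' @param master integer master seed
#' @param stage stage name (string)
#' @param index replicate index
#' @return integer seed
#' @export
derive_seed <- function(master, stage, index = 0L) {
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  h <- (h * 1031 + as.double(index)) %% 2147483647
  as.integer(h)
}
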
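#' Multi-channel extracellular voltage recording
#'
#' Raw MEA voltage: one column per electrode, sampled at `fs` Hz (12.5 kHz
#' in the study's recordings), amplitudes in microvolts.
#'
#' @param data numeric matrix, samples x electrodes (µV)
#' @param fs sampling frequency (Hz)
#' @param electrode_ids optional ids, one per column
#' @return An object of class `voltage_recording` with fields `data`, `fs`,
#'   `duration`, `electrode_ids`.
#' @export
voltage_recording <- function(data, fs = 12500,
                              electrode_ids = seq_len(ncol(data))) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), fs > 0, length(electrode_ids) == ncol(data))
  structure(list(data = data, fs = as.numeric(fs),
                 duration = nrow(data) / fs,
                 electrode_ids = electrode_ids),
            class = "voltage_recording")
}

#' @export
print.voltage_recording <- function(x, ...) {
  cat(sprintf("Voltage recording: %d electrodes, %.4g s at %g Hz (%d samples)\n",
              ncol(x$data), x$duration, x$fs, nrow(x$data)))
  invisible(x)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies a Butterworth bandpass (default 200-3000 Hz, the spike band)
#' forward and backward ([signal::filtfilt()]) to each electrode, removing
#' DC and low-frequency field potentials with zero phase distortion.
#'
#' @param recording a [voltage_recording()]
#' @param low,high band edges (Hz); must satisfy `low < high < fs/2`
#' @param order Butterworth order (applied twice by filtfilt)
#' @return A filtered `voltage_recording`.
#' @export
bandpass <- function(recording, low = 200, high = 3000, order = 3) {
  stopifnot(inherits(recording, "voltage_recording"))
  if (!(low < high && high < recording$fs / 2))
    stop("invalid-config: need low < high < fs/2 (fs = ", recording$fs, " Hz)")
  bf <- signal::butter(order, c(low, high) / (recording$fs / 2), type = "pass")
  out <- apply(recording$data, 2, function(v) signal::filtfilt(bf, v))
  voltage_recording(out, fs = recording$fs,
                    electrode_ids = recording$electrode_ids)
}

#' Adaptive-threshold extracellular spike detection
#'
#' Per electrode, the noise scale is estimated robustly as the median
#' absolute deviation of the filtered trace divided by 0.6745 (the Gaussian
#' consistency constant), and events are detected where `|v|` exceeds
#' `k` times that scale (default k = 6). Each supra-threshold excursion
#' yields one spike at the time of its absolute extremum; events closer
#' than the dead time are merged (first kept). A flat, zero-variance
#' channel yields an empty train rather than an error. With
#' `window_s` set, the threshold adapts over non-overlapping windows of
#' that length instead of the whole trace.
#'
#' @param filtered a band-passed [voltage_recording()]
#' @param k threshold in multiples of the robust noise SD
#' @param dead_time_ms minimum separation between events (ms)
#' @param window_s optional window length (s) for a sliding noise estimate
#' @return A [spike_raster()] of kind `"electrode"`.
#' @export
detect_spikes <- function(filtered, k = 6, dead_time_ms = 1,
                          window_s = NULL) {
  stopifnot(inherits(filtered, "voltage_recording"))
  fs <- filtered$fs
  dead <- max(1L, as.integer(round(dead_time_ms / 1000 * fs)))
  times <- lapply(seq_len(ncol(filtered$data)), function(j) {
    v <- filtered$data[, j]
    thr <- if (is.null(window_s)) {
      rep(k * stats::mad(v), length(v))
    } else {
      wlen <- max(2L, as.integer(round(window_s * fs)))
      idx <- ceiling(seq_along(v) / wlen)
      sds <- tapply(v, idx, stats::mad)
      k * as.numeric(sds)[idx]
    }
    if (all(thr == 0)) return(numeric(0))  # flat channel: inactive
    above <- abs(v) > thr
    if (!any(above)) return(numeric(0))
    d <- diff(c(FALSE, above))
    starts <- which(d == 1L)
    ends <- which(d == -1L) - 1L
    if (length(ends) < length(starts)) ends <- c(ends, length(v))
    peaks <- mapply(function(s, e) s - 1L + which.max(abs(v[s:e])),
                    starts, ends)
    keep <- logical(length(peaks))
    last <- -Inf
    for (i in seq_along(peaks)) {
      if (peaks[i] - last >= dead) { keep[i] <- TRUE; last <- peaks[i] }
    }
    (peaks[keep] - 1) / fs
  })
  spike_raster(times, duration = filtered$duration,
               source_ids = filtered$electrode_ids, kind = "electrode")
}

#' Write / read multi-channel voltage as delimited text
#'
#' Plain tab-separated text, one row per sample and one column per
#' electrode, with a `#`-comment header carrying the sampling frequency,
#' units and electrode ids, so a recording round-trips losslessly through
#' disk.
#'
#' @param recording a [voltage_recording()]
#' @param path file path
#' @return `write_voltage` returns `path` invisibly; `read_voltage` a
#'   [voltage_recording()].
#' @export
write_voltage <- function(recording, path) {
  stopifnot(inherits(recording, "voltage_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# burstnet voltage recording v1",
               sprintf("# fs_hz: %.10g", recording$fs),
               "# units: uV",
               sprintf("# electrodes: %s",
                       paste(recording$electrode_ids, collapse = ","))), con)
  utils::write.table(format(recording$data, digits = 8, trim = TRUE,
                            scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_voltage
#' @export
read_voltage <- function(path) {
  hdr <- readLines(path, n = 4L)
  if (!startsWith(hdr[1], "# burstnet voltage recording"))
    stop("invalid-input: not a burstnet voltage file: ", path)
  fs <- as.numeric(sub("# fs_hz: ", "", hdr[2]))
  ids <- strsplit(sub("# electrodes: ", "", hdr[4]), ",")[[1]]
  m <- as.matrix(utils::read.table(path, comment.char = "#", sep = "\t"))
  dimnames(m) <- NULL
  voltage_recording(m, fs = fs, electrode_ids = ids)
}
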
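#' Spike raster container
#'
#' Per-source spike-time lists with duration and source metadata. Sources are
#' simulated neurons or MEA electrodes; spike times are seconds from the
#' start of the recording, strictly increasing per source.
#'
#' @param times list of numeric vectors of spike times (s), one per source
#' @param duration recording duration (s)
#' @param source_ids optional character/integer ids, one per source
#' @param kind `"simulated-neuron"` or `"electrode"`
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(times, duration,
                         source_ids = seq_along(times),
                         kind = c("simulated-neuron", "electrode")) {
  kind <- match.arg(kind)
  stopifnot(is.list(times), length(source_ids) == length(times),
            is.numeric(duration), duration > 0)
  times <- lapply(times, function(tt) {
    tt <- as.numeric(tt)
    if (any(!is.finite(tt)) || any(tt < 0) || any(tt > duration))
      stop("invalid-input: spike times must lie in [0, duration]")
    if (is.unsorted(tt, strictly = TRUE)) tt <- sort(tt)
    tt
  })
  structure(list(times = times, duration = as.numeric(duration),
                 source_ids = source_ids, kind = kind),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  n_spk <- sum(lengths(x$times))
  cat(sprintf("Spike raster: %d %s sources, %d spikes over %g s (mean rate %.3g Hz/source)\n",
              length(x$times), x$kind, n_spk,
              x$duration, n_spk / length(x$times) / x$duration))
  invisible(x)
}

#' Total number of spikes in a raster
#' @param raster a [spike_raster()]
#' @return integer spike count summed over sources
#' @export
n_spikes <- function(raster) sum(lengths(raster$times))

#' Bin spike trains into 1 kHz binary sequences
#'
#' Converts each source's spike times to a binary train at 1 ms resolution:
#' bin k covers the half-open interval \[k, k+1) ms and is 1 iff at least one
#' spike falls inside it. This is the representation fed to the Welch
#' spectral estimator and permuted for the surrogate.
#'
#' @param raster a [spike_raster()]
#' @return A list of `binned_train` objects (fields `x` 0/1 integer vector,
#'   `fs` = 1000, `duration`, `source_id`).
#' @export
bin_to_1khz <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  n_bins <- round(raster$duration * 1000)
  lapply(seq_along(raster$times), function(i) {
    x <- integer(n_bins)
    idx <- floor(raster$times[[i]] * 1000) + 1L
    idx[idx > n_bins] <- n_bins  # only a spike at exactly `duration`
    x[idx] <- 1L
    binned_train(x, duration = raster$duration,
                 source_id = raster$source_ids[[i]])
  })
}

#' Binary 1 kHz spike train
#'
#' @param x integer 0/1 vector, one value per 1 ms bin
#' @param duration duration (s)
#' @param source_id source identifier
#' @return An object of class `binned_train`.
#' @export
binned_train <- function(x, duration, source_id = NA) {
  x <- as.integer(x)
  if (any(!x %in% c(0L, 1L))) stop("invalid-input: binned train must be 0/1")
  structure(list(x = x, fs = 1000, duration = as.numeric(duration),
                 source_id = source_id),
            class = "binned_train")
}

#' Electrode activity criterion
#'
#' An electrode is active if it fired at least 5 spikes per minute over the
#' recording.
#'
#' @param spike_times numeric vector of spike times (s) for one electrode,
#'   or a `binned_train`
#' @param duration recording duration (s); ignored for a `binned_train`
#' @param min_rate_per_min activity threshold (spikes/min)
#' @return logical
#' @export
electrode_is_active <- function(spike_times, duration,
                                min_rate_per_min = 5) {
  if (inherits(spike_times, "binned_train")) {
    duration <- spike_times$duration
    count <- sum(spike_times$x)
  } else {
    count <- length(spike_times)
  }
  if (!is.numeric(duration) || duration <= 0)
    stop("invalid-input: duration must be > 0")
  (count / duration * 60) >= min_rate_per_min
}

#' Well-level quality-control filter
#'
#' A 64-electrode well passes QC iff at least 32 electrodes are active.
#'
#' @param active logical vector of per-electrode activity flags (length 64)
#' @param min_active required number of active electrodes
#' @param n_electrodes expected number of electrodes
#' @return logical
#' @export
well_passes_qc <- function(active, min_active = 32, n_electrodes = 64) {
  if (!is.logical(active) || length(active) != n_electrodes)
    stop("invalid-input: expected ", n_electrodes, " electrode activity flags")
  sum(active) >= min_active
}

#' Write / read a spike raster as two-column delimited text
#'
#' The on-disk dialect is plain whitespace-delimited text: one row per
#' spike, column 1 the source id, column 2 the spike time in seconds, with
#' `#`-prefixed header lines carrying duration, kind and source count. A
#' source with no spikes is preserved via the header's source list.
#'
#' @param raster a [spike_raster()]
#' @param path file path
#' @return `write_raster` returns `path` invisibly; `read_raster` returns a
#'   [spike_raster()].
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# burstnet spike raster v1"),
               sprintf("# duration_s: %.10g", raster$duration),
               sprintf("# kind: %s", raster$kind),
               sprintf("# sources: %s", paste(raster$source_ids, collapse = ","))),
             con)
  df <- data.frame(
    source = rep(raster$source_ids, lengths(raster$times)),
    time_s = unlist(raster$times, use.names = FALSE))
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  hdr <- readLines(path, n = 4L)
  if (!startsWith(hdr[1], "# burstnet spike raster"))
    stop("invalid-input: not a burstnet raster file: ", path)
  duration <- as.numeric(sub("# duration_s: ", "", hdr[2]))
  kind <- sub("# kind: ", "", hdr[3])
  ids <- strsplit(sub("# sources: ", "", hdr[4]), ",")[[1]]
  df <- tryCatch(
    utils::read.table(path, comment.char = "#",
                      col.names = c("source", "time_s"),
                      colClasses = c("character", "numeric")),
    error = function(e) data.frame(source = character(), time_s = numeric()))
  times <- lapply(ids, function(id) sort(df$time_s[df$source == id]))
  spike_raster(times, duration = duration, source_ids = ids, kind = kind)
}
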
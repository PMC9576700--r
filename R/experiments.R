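#' Analyze a simulated raster for its peak network-burst frequency
#'
#' Convenience wrapper chaining [population_average_spectrum()] and
#' [peak_burst_frequency()] — the same analysis applied to recorded MEA
#' spike trains, applied to a simulated population.
#'
#' @param raster a [spike_raster()]
#' @param settings a [welch_settings()]
#' @param n_surrogates surrogate permutations per source
#' @param seed seed for the surrogate permutations
#' @param band upper band edge (Hz) of the inclusion rule
#' @return list with `spectrum` (a `db_spectrum`) and `peak` (a
#'   `burst_frequency_result`)
#' @export
analyze_raster <- function(raster, settings = welch_settings(),
                           n_surrogates = 10, seed = 1L, band = 1) {
  spec <- population_average_spectrum(raster, settings, n_surrogates, seed)
  list(spectrum = spec, peak = peak_burst_frequency(spec, band))
}

simulate_and_analyze <- function(config, params, n_surrogates, seed) {
  cfg <- config
  cfg$seed <- as.integer(seed)
  # scans budget 100 Hz/neuron: saturated runaway states are marked failed
  # rather than simulated to completion
  raster <- simulate_network(cfg, params,
                             max_spikes = 100 * cfg$n_neurons * cfg$duration)
  if (n_spikes(raster) == 0L)
    return(list(peak_frequency = NA_real_, peak_db = NA_real_,
                status = "excluded", reason = "no-spikes"))
  res <- tryCatch(
    analyze_raster(raster, n_surrogates = n_surrogates,
                   seed = derive_seed(seed, "analysis")),
    error = function(e) NULL)
  if (is.null(res))
    return(list(peak_frequency = NA_real_, peak_db = NA_real_,
                status = "failed", reason = "analysis-error"))
  if (res$peak$excluded)
    list(peak_frequency = NA_real_, peak_db = res$peak$peak_db,
         status = "excluded", reason = res$peak$reason)
  else
    list(peak_frequency = res$peak$peak_frequency,
         peak_db = res$peak$peak_db, status = "ok", reason = "")
}

scan_row <- function(combo, config, params, n_surrogates, seed, cache_dir) {
  tag <- paste0(paste(names(combo), unlist(combo), sep = "=",
                      collapse = "_"), "_seed", seed)
  cache <- if (!is.null(cache_dir))
    file.path(cache_dir, paste0(gsub("[^A-Za-z0-9_.=-]", "-", tag), ".csv"))
  if (!is.null(cache_dir) && file.exists(cache)) {
    row <- utils::read.csv(cache, stringsAsFactors = FALSE)
    row$peak_frequency <- as.numeric(row$peak_frequency)
    row$peak_db <- as.numeric(row$peak_db)
    row$reason <- as.character(row$reason)
    row$reason[is.na(row$reason)] <- ""
    return(row)
  }
  out <- tryCatch(
    simulate_and_analyze(config, params, n_surrogates, seed),
    error = function(e) list(peak_frequency = NA_real_, peak_db = NA_real_,
                             status = "failed", reason = conditionMessage(e)))
  row <- cbind(as.data.frame(combo), seed = seed,
               peak_frequency = out$peak_frequency, peak_db = out$peak_db,
               status = out$status, reason = out$reason,
               stringsAsFactors = FALSE)
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(row, cache, row.names = FALSE)
  }
  row
}

#' Two-dimensional (C_m, tau_m) fit scan
#'
#' Simulates the network at every combination of membrane capacitance and
#' membrane time constant (realized as `g_L = C_m / tau_m`), analyzes each
#' run with the spectral burst pipeline, and tabulates peak burst frequency
#' per combination and seed. Default grid ranges span physiologically
#' plausible patch-clamp values: `C_m` 20-120 pF, `tau_m` 10-60 ms. Rows
#' whose simulation fails are marked `failed` and the scan continues; a
#' `cache_dir` makes the scan resumable per combination.
#'
#' @param C_m_values capacitance grid (pF)
#' @param tau_m_values membrane time-constant grid (ms)
#' @param params base [neuron_parameters()] supplying all other constants
#' @param config a [network_config()]; its seed is overridden per replicate
#' @param seeds integer vector of replicate seeds
#' @param n_surrogates surrogate permutations per source (scan default 2,
#'   trading variance for runtime across many combinations)
#' @param cache_dir optional directory of per-combination result rows
#' @return A `scan_result` data.frame: one row per combination x seed with
#'   `peak_frequency`, `peak_db`, `status` (`ok`/`excluded`/`failed`).
#' @export
run_fit_scan <- function(C_m_values = seq(20, 120, by = 25),
                         tau_m_values = seq(10, 60, by = 12.5),
                         params = genotype_fixture("WT")$params,
                         config = scaled_network_config(),
                         seeds = 1:3, n_surrogates = 2, cache_dir = NULL) {
  if (!length(C_m_values) || !length(tau_m_values))
    stop("invalid-config: empty scan grid")
  rows <- list()
  for (C_m in C_m_values) for (tau_m in tau_m_values) {
    p <- params
    p$C_m <- C_m
    p$g_L <- C_m / tau_m
    p <- do.call(neuron_parameters, unclass(p))
    for (s in seeds)
      rows[[length(rows) + 1L]] <-
        scan_row(list(C_m = C_m, tau_m = tau_m), config, p,
                 n_surrogates, s, cache_dir)
  }
  structure(do.call(rbind, rows), class = c("scan_result", "data.frame"))
}

#' Select the best-fitting scan combination
#'
#' Groups the scan by parameter combination, takes the median peak
#' frequency over replicate seeds (excluded/failed rows dropped), and
#' returns the combination with the smallest absolute difference from the
#' target peak frequency. Ties break by smaller seed-to-seed dispersion
#' (IQR), then by lexicographic parameter order; a tie is flagged.
#'
#' @param scan a [run_fit_scan()] / [run_connectivity_scan()] result
#' @param target_peak target peak burst frequency (Hz), e.g. the mean of
#'   recorded data
#' @return one-row data.frame with the winning combination, its median
#'   peak, dispersion, and a `tie` flag
#' @export
select_top_fit <- function(scan, target_peak) {
  stopifnot(is.data.frame(scan), is.numeric(target_peak))
  par_cols <- setdiff(names(scan),
                      c("seed", "peak_frequency", "peak_db", "status", "reason"))
  key <- interaction(scan[par_cols], drop = TRUE, lex.order = TRUE)
  ok <- scan$status == "ok"
  meds <- tapply(scan$peak_frequency[ok], droplevels(key[ok]), stats::median)
  if (!length(meds)) stop("no-fit: every scan row is excluded or failed")
  iqrs <- tapply(scan$peak_frequency[ok], droplevels(key[ok]), stats::IQR)
  diff_target <- abs(meds - target_peak)
  best <- which(diff_target - min(diff_target) < 1e-9)
  tie <- length(best) > 1L
  if (tie) best <- best[order(iqrs[best],
                              match(names(meds)[best], levels(key)))]
  win <- names(meds)[best[1L]]
  row <- scan[ok & key == win, , drop = FALSE][1L, par_cols, drop = FALSE]
  cbind(row, median_peak = unname(meds[win]), iqr = unname(iqrs[win]),
        abs_diff = unname(diff_target[win]), tie = tie,
        row.names = NULL)
}

#' Swap a named parameter subset between genotype sets
#'
#' The drop-out primitive: returns `base` with one subset of its parameters
#' replaced by the donor's values. `"adaptation"` swaps the adaptation
#' triple (`a`, `b`, `tau_w`) — the model's representation of voltage-gated
#' Na+/K+ currents; `"membrane"` swaps capacitance and resting potential
#' (`C_m`, `E_L`). Subset membership is overridable.
#'
#' @param base,donor [genotype_parameter_set()] objects
#' @param subset `"adaptation"` or `"membrane"`
#' @param adaptation_fields,membrane_fields field names defining each subset
#' @return a new [genotype_parameter_set()] labelled
#'   `"<base>+<donor>-<subset>"`
#' @export
dropout_swap <- function(base, donor,
                         subset = c("adaptation", "membrane"),
                         adaptation_fields = c("a", "b", "tau_w"),
                         membrane_fields = c("C_m", "E_L")) {
  if (!is.character(subset) || !subset[1L] %in% c("adaptation", "membrane"))
    stop("invalid-config: subset must be 'adaptation' or 'membrane'")
  subset <- subset[1L]
  stopifnot(inherits(base, "genotype_parameter_set"),
            inherits(donor, "genotype_parameter_set"))
  fields <- if (subset == "adaptation") adaptation_fields else membrane_fields
  p <- unclass(base$params)
  for (f in fields) p[[f]] <- donor$params[[f]]
  genotype_parameter_set(
    label = paste0(base$label, "+", donor$label, "-", subset),
    params = do.call(neuron_parameters, p),
    provenance = sprintf("%s with %s's %s subset (%s)", base$label,
                         donor$label, subset, paste(fields, collapse = ", ")))
}

#' Parameter drop-out experiment
#'
#' Simulates and analyzes the six drop-out conditions: the two pure
#' genotypes, the null with the wild type's adaptation or membrane subset
#' dropped in, and the reciprocal swaps on the wild type. Each condition
#' runs over replicate seeds; per-condition failures are recorded without
#' aborting the rest.
#'
#' @param wt,null [genotype_parameter_set()] objects
#' @param config a [network_config()]
#' @param seeds replicate seeds
#' @param n_surrogates surrogate permutations per source
#' @param keep_rasters keep one raster per condition (first seed) for
#'   raster-plot style inspection
#' @return list with `table` (condition x seed peak-frequency data.frame)
#'   and `rasters` (named list, possibly empty)
#' @export
run_dropout_experiment <- function(wt, null, config = scaled_network_config(),
                                   seeds = 1:3, n_surrogates = 2,
                                   keep_rasters = FALSE) {
  conditions <- list(
    wt, null,
    dropout_swap(null, wt, "adaptation"),
    dropout_swap(null, wt, "membrane"),
    dropout_swap(wt, null, "adaptation"),
    dropout_swap(wt, null, "membrane"))
  rows <- list()
  rasters <- list()
  for (gs in conditions) {
    for (s in seeds)
      rows[[length(rows) + 1L]] <-
        scan_row(list(condition = gs$label), config, gs$params,
                 n_surrogates, s, cache_dir = NULL)
    if (keep_rasters) {
      cfg <- config
      cfg$seed <- as.integer(seeds[1L])
      rasters[[gs$label]] <- simulate_network(cfg, gs$params)
    }
  }
  list(table = structure(do.call(rbind, rows),
                         class = c("scan_result", "data.frame")),
       rasters = rasters)
}

#' Adaptation-vs-connectivity scan
#'
#' Scans subthreshold adaptation `a` against connection probability `p`,
#' simulating and analyzing every grid point over replicate seeds, and
#' summarizes the direction of the burst-frequency response: the Spearman
#' sign of median peak frequency vs `p` at each `a`, and the median effect
#' range of each axis.
#'
#' @param a_values subthreshold adaptation grid (nS), study range 4-10
#' @param p_values connection-probability grid, study range 0.05-0.35
#' @param params base [neuron_parameters()]
#' @param config a [network_config()]
#' @param seeds replicate seeds
#' @param n_surrogates surrogate permutations per source
#' @param cache_dir optional resumable cache
#' @return A `scan_result` data.frame with attribute `summary`: per-`a`
#'   Spearman correlation of median peak vs `p`, and the ranges of medians
#'   along each axis.
#' @export
run_connectivity_scan <- function(a_values = c(4, 7, 10),
                                  p_values = c(0.05, 0.15, 0.25, 0.35),
                                  params = genotype_fixture("WT")$params,
                                  config = scaled_network_config(),
                                  seeds = 1:3, n_surrogates = 2,
                                  cache_dir = NULL) {
  stopifnot(all(a_values >= 0), all(p_values >= 0 & p_values <= 1))
  rows <- list()
  for (a in a_values) for (p in p_values) {
    prm <- params
    prm$a <- a
    prm <- do.call(neuron_parameters, unclass(prm))
    cfg <- config
    cfg$connection_probability <- p
    for (s in seeds)
      rows[[length(rows) + 1L]] <-
        scan_row(list(a = a, p = p), cfg, prm, n_surrogates, s, cache_dir)
  }
  scan <- structure(do.call(rbind, rows),
                    class = c("scan_result", "data.frame"))
  ok <- scan$status == "ok"
  if (!any(ok)) {
    attr(scan, "summary") <- list(spearman_peak_vs_p_by_a = numeric(0),
                                  effect_range_p = NA_real_,
                                  effect_range_a = NA_real_,
                                  medians = scan[integer(0), ])
    return(scan)
  }
  med <- stats::aggregate(peak_frequency ~ a + p, data = scan[ok, ],
                          FUN = stats::median)
  rho_by_a <- vapply(unique(med$a), function(av) {
    sub <- med[med$a == av, ]
    if (nrow(sub) < 2) return(NA_real_)
    suppressWarnings(stats::cor(sub$p, sub$peak_frequency,
                                method = "spearman"))
  }, numeric(1))
  names(rho_by_a) <- unique(med$a)
  effect_p <- stats::aggregate(peak_frequency ~ p, med, stats::median)
  effect_a <- stats::aggregate(peak_frequency ~ a, med, stats::median)
  attr(scan, "summary") <- list(
    spearman_peak_vs_p_by_a = rho_by_a,
    effect_range_p = diff(range(effect_p$peak_frequency)),
    effect_range_a = diff(range(effect_a$peak_frequency)),
    medians = med)
  scan
}
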
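#' Reproducible run configuration
#'
#' Fully serializable description of a run: experiment name, network
#' configuration, genotype label(s), analysis settings and seed policy.
#' Round-trips losslessly through YAML ([write_run_config()] /
#' [read_run_config()]). All randomness in a run derives from the single
#' master seed via [derive_seed()].
#'
#' @param experiment one of `"simulate"`, `"analyze"`, `"scan"`,
#'   `"dropout"`, `"synth"`
#' @param network a [network_config()]
#' @param genotypes character vector of genotype fixture labels
#' @param analysis list of analysis settings: `segment_length`, `overlap`,
#'   `n_surrogates`, `band`
#' @param master_seed integer master seed
#' @param output_dir artifact directory
#' @return An object of class `run_config`.
#' @export
run_config <- function(experiment = "simulate",
                       network = network_config(),
                       genotypes = "WT",
                       analysis = list(segment_length = NULL, overlap = 0.5,
                                       n_surrogates = 10, band = 1),
                       master_seed = 1L,
                       output_dir = "burstnet-out") {
  experiment <- match.arg(experiment,
                          c("simulate", "analyze", "scan", "dropout", "synth"))
  stopifnot(inherits(network, "network_config"))
  structure(list(experiment = experiment, network = network,
                 genotypes = genotypes, analysis = analysis,
                 master_seed = as.integer(master_seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`
#' @param path YAML file path
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$network <- unclass(x$network)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("invalid-config: no such config file: ", path)
  x <- yaml::read_yaml(path)
  net <- do.call(network_config, x$network[!vapply(x$network, is.null,
                                                   logical(1))])
  run_config(experiment = x$experiment, network = net,
             genotypes = x$genotypes, analysis = x$analysis,
             master_seed = x$master_seed, output_dir = x$output_dir)
}

#' Write a run manifest
#'
#' Records everything needed to regenerate a run's artifacts: the full
#' configuration, the master seed, the package version and a content hash
#' of the serialized config.
#'
#' @param config a [run_config()]
#' @param dir output directory
#' @param extra optional named list appended to the manifest
#' @return the manifest path, invisibly
#' @export
write_manifest <- function(config, dir, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(dir, "config.yaml")
  write_run_config(config, cfg_path)
  hash <- sum(utf8ToInt(paste(readLines(cfg_path), collapse = "\n")) *
                (seq_along(utf8ToInt(paste(readLines(cfg_path),
                                           collapse = "\n"))) %% 97 + 1))
  manifest <- c(list(config_file = "config.yaml",
                     config_hash = unname(hash),
                     master_seed = config$master_seed,
                     package_version =
                       as.character(utils::packageVersion("burstnet")),
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                extra)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Execute a configured run
#'
#' Dispatches a [run_config()] to the matching pipeline stage, writes its
#' artifacts (rasters, spectra, result tables) and a manifest to the output
#' directory, and logs stage timings and exclusion counts. This is the
#' engine behind the command-line interface in `inst/cli/burstnet`.
#'
#' @param config a [run_config()]
#' @param scaled use the reduced 200-neuron / 60 s profile
#' @param quiet suppress progress messages
#' @return invisibly, a named list of written artifact paths
#' @export
execute_run <- function(config, scaled = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  net <- config$network
  if (scaled) { net$n_neurons <- 200L; net$duration <- 60 }
  an <- config$analysis
  settings <- welch_settings(segment_length = an$segment_length,
                             overlap = an$overlap %||% 0.5)
  out <- list()

  if (config$experiment %in% c("simulate", "analyze")) {
    for (g in config$genotypes) {
      gs <- genotype_fixture(g)
      net$seed <- derive_seed(config$master_seed, "sim", match(g, config$genotypes))
      raster <- simulate_network(net, gs$params)
      rp <- file.path(config$output_dir, paste0("raster-", g, ".tsv"))
      write_raster(raster, rp)
      out[[paste0("raster_", g)]] <- rp
      say("simulated %s: %d spikes", g, n_spikes(raster))
      if (config$experiment == "analyze") {
        res <- analyze_raster(raster, settings,
                              n_surrogates = an$n_surrogates %||% 10,
                              seed = derive_seed(config$master_seed, "an"),
                              band = an$band %||% 1)
        sp <- file.path(config$output_dir, paste0("spectrum-", g, ".tsv"))
        write_spectrum(res$spectrum, sp)
        out[[paste0("spectrum_", g)]] <- sp
        say("%s: %s", g, utils::capture.output(print(res$peak)))
      }
    }
  } else if (config$experiment == "scan") {
    scan <- run_connectivity_scan(config = net,
                                  seeds = config$master_seed + 0:2,
                                  cache_dir = file.path(config$output_dir,
                                                        "cache"))
    sp <- file.path(config$output_dir, "scan.tsv")
    write_table_with_header(scan, sp, settings)
    out$scan <- sp
    n_exc <- sum(scan$status != "ok")
    say("scan: %d rows, %d excluded/failed", nrow(scan), n_exc)
  } else if (config$experiment == "dropout") {
    res <- run_dropout_experiment(genotype_fixture("WT"),
                                  genotype_fixture("NULL"),
                                  config = net,
                                  seeds = config$master_seed + 0:2)
    sp <- file.path(config$output_dir, "dropout.tsv")
    write_table_with_header(res$table, sp, settings)
    out$dropout <- sp
    say("dropout: %d rows", nrow(res$table))
  } else if (config$experiment == "synth") {
    ws <- synthetic_well_spec(seed = config$master_seed)
    gen <- generate_burst_raster(ws)
    rp <- file.path(config$output_dir, "synthetic-raster.tsv")
    write_raster(gen$raster, rp)
    gt <- file.path(config$output_dir, "ground-truth.yaml")
    yaml::write_yaml(list(burst_onsets = gen$ground_truth$burst_onsets,
                          burst_rate = ws$burst_rate), gt)
    out$raster <- rp; out$ground_truth <- gt
    say("synth: %d bursts, %d spikes",
        length(gen$ground_truth$burst_onsets), n_spikes(gen$raster))
  }
  write_manifest(config, config$output_dir,
                 extra = list(scaled = scaled,
                              elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                              units = "secs"))))
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(out)
}

#' Write a dB spectrum or result table as delimited text
#'
#' Tab-separated values preceded by a `#`-comment block carrying the Welch
#' settings, so every artifact records the analysis that produced it.
#'
#' @param spectrum a `db_spectrum`
#' @param path file path
#' @return the path, invisibly
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  s <- spectrum$settings
  writeLines(c("# burstnet dB spectrum v1",
               sprintf("# source: %s", spectrum$source_id),
               sprintf("# n_surrogates: %s", spectrum$n_surrogates),
               sprintf("# welch: segment=%s overlap=%g window=%s",
                       s$segment_length %||% "auto", s$overlap, s$window)),
             con)
  utils::write.table(data.frame(freq_hz = spectrum$freq,
                                power_db = spectrum$power_db),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_table_with_header <- function(tab, path, settings) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# burstnet result table v1",
               sprintf("# welch: segment=%s overlap=%g window=%s",
                       settings$segment_length %||% "auto",
                       settings$overlap, settings$window)), con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import pre-exported spike-time CSVs
#'
#' Stub importer for spike times exported from acquisition software as CSV
#' with columns `electrode` and `time_s` (proprietary raw formats are not
#' read).
#'
#' @param path CSV path
#' @param duration recording duration (s); defaults to the latest spike
#'   time rounded up
#' @param n_electrodes total electrode count (silent electrodes included)
#' @return a [spike_raster()] of kind `"electrode"`
#' @export
import_spike_csv <- function(path, duration = NULL, n_electrodes = 64) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("electrode", "time_s") %in% names(df)))
    stop("invalid-input: CSV must have columns 'electrode' and 'time_s'")
  if (is.null(duration)) duration <- ceiling(max(df$time_s, 0) + 1e-9)
  ids <- seq_len(n_electrodes)
  times <- lapply(ids, function(e) sort(df$time_s[df$electrode == e]))
  spike_raster(times, duration = duration, source_ids = ids,
               kind = "electrode")
}
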
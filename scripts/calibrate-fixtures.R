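#!/usr/bin/env Rscript

# Calibration grid search behind the genotype fixture constants in
# R/fixtures.R. Simulates candidate parameter sets at the scaled profile
# (200 neurons, 60 s, 3 seeds), analyzes each with the spectral pipeline,
# and prints the peak-frequency table so the frozen constants can be
# re-derived or re-tuned. Expect ~10 minutes.
#
#   Rscript scripts/calibrate-fixtures.R [--seeds 3]

library(burstnet)

args <- commandArgs(trailingOnly = TRUE)
n_seeds <- {
  i <- which(args == "--seeds")
  if (length(i)) as.integer(args[i + 1]) else 3L
}

peak_median <- function(params, seeds = seq_len(n_seeds)) {
  pks <- vapply(seeds, function(s) {
    cfg <- scaled_network_config(seed = s)
    r <- simulate_network(cfg, params)
    if (n_spikes(r) < 10) return(NA_real_)
    res <- tryCatch(analyze_raster(r, n_surrogates = 2,
                                   seed = derive_seed(s, "calib")),
                    error = function(e) NULL)
    if (is.null(res) || res$peak$excluded) NA_real_
    else res$peak$peak_frequency
  }, numeric(1))
  c(median = stats::median(pks, na.rm = TRUE), n_ok = sum(!is.na(pks)))
}

cat("frozen fixtures:\n")
for (g in c("WT", "NULL", "L124W")) {
  out <- peak_median(genotype_fixture(g)$params)
  cat(sprintf("  %-6s median peak %.3f Hz (%d/%d seeds in band)\n",
              g, out["median"], out["n_ok"], n_seeds))
}

cat("\nadaptation-increment neighbourhood around WT:\n")
base <- genotype_fixture("WT")$params
for (b in c(500, 800, 1100, 1600)) {
  p <- base; p$b <- b
  p <- do.call(neuron_parameters, unclass(p))
  out <- peak_median(p)
  cat(sprintf("  b=%4.0f pA: median peak %.3f Hz (%d/%d)\n",
              b, out["median"], out["n_ok"], n_seeds))
}

cat("\nadaptation time-constant neighbourhood around WT:\n")
for (tw in c(800, 1000, 1300, 1600)) {
  p <- base; p$tau_w <- tw
  p <- do.call(neuron_parameters, unclass(p))
  out <- peak_median(p)
  cat(sprintf("  tau_w=%4.0f ms: median peak %.3f Hz (%d/%d)\n",
              tw, out["median"], out["n_ok"], n_seeds))
}
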
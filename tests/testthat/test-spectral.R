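test_that("a periodic train concentrates spectral mass at its rate", {
  tr <- periodic_train(period_s = 4, duration_s = 300)
  sp <- welch_psd(tr)
  # Dirac-comb oracle: power at 0.25 Hz and harmonics dominates
  i_peak <- which.max(sp$power[sp$freq > 0])
  f_peak <- sp$freq[sp$freq > 0][i_peak]
  df <- sp$freq[2] - sp$freq[1]
  expect_lt(abs(f_peak %% 0.25), 2 * df)  # at a harmonic of 0.25 Hz
  expect_gt(max(sp$power[sp$freq > 0]), 50 * median(sp$power[sp$freq > 0]))
})

test_that("an all-zero train yields a zero, degenerate spectrum", {
  tr <- binned_train(integer(60000), duration = 60)
  sp <- welch_psd(tr)
  expect_true(sp$degenerate)
  expect_true(all(sp$power == 0))
})

test_that("a Bernoulli train has a flat spectrum within sampling error", {
  tr <- bernoulli_train(0.02, 300, seed = 4)
  sp <- welch_psd(tr)
  keep <- sp$freq > 1  # away from the few low-f bins
  ratio <- sp$power[keep] / mean(sp$power[keep])
  # white point-process limit: no bin grossly above the mean level
  expect_lt(max(10 * log10(ratio)), 10)
  expect_lt(abs(stats::median(ratio) - 1), 0.15)
})

test_that("welch_psd rejects trains shorter than a segment", {
  tr <- binned_train(rep(0:1, 500), duration = 1)
  expect_error(welch_psd(tr, welch_settings(segment_length = 4096)),
               "at least")
})

test_that("surrogate permutation preserves the spike count and kills rhythm", {
  tr <- periodic_train(4, 300)
  sur <- surrogate_spectrum(tr, n_surrogates = 5, seed = 7)
  sig <- welch_psd(tr)
  # flatness: no surrogate bin towers over the median as the true peak does
  expect_lt(max(sur$power[sur$freq > 0]) /
              stats::median(sur$power[sur$freq > 0]), 20)
  expect_gt(max(sig$power[sig$freq > 0]) /
              stats::median(sig$power[sig$freq > 0]), 50)
  # determinism given seed
  sur2 <- surrogate_spectrum(tr, n_surrogates = 5, seed = 7)
  expect_identical(sur$power, sur2$power)
  expect_error(surrogate_spectrum(binned_train(integer(1000), 1)),
               "degenerate-input")
})

test_that("more surrogates reduce variance without shifting the mean", {
  tr <- bernoulli_train(0.05, 120, seed = 9)
  s2 <- lapply(1:6, function(k)
    surrogate_spectrum(tr, n_surrogates = 2, seed = k)$power)
  s20 <- lapply(1:6, function(k)
    surrogate_spectrum(tr, n_surrogates = 20, seed = 100 + k)$power)
  m2 <- rowMeans(do.call(cbind, s2))
  m20 <- rowMeans(do.call(cbind, s20))
  expect_lt(abs(mean(m2) - mean(m20)) / mean(m20), 0.05)
  v2 <- mean(apply(do.call(cbind, s2), 1, var))
  v20 <- mean(apply(do.call(cbind, s20), 1, var))
  expect_lt(v20, v2)
})

test_that("db_ratio implements the log identity with aligned grids", {
  tr <- bernoulli_train(0.05, 60, seed = 2)
  sp <- welch_psd(tr)
  db0 <- db_ratio(sp, sp)
  expect_true(all(abs(db0$power_db) < 1e-10))
  sp10 <- sp
  sp10$power <- sp$power / 10
  expect_true(all(abs(db_ratio(sp, sp10)$power_db - 10) < 1e-9))
  bad <- welch_psd(bernoulli_train(0.05, 30, seed = 2))
  expect_error(db_ratio(sp, bad), "grids differ")
})

test_that("near-periodic trains vs their surrogates peak at the true rate", {
  # exact periodicity leaves all comb harmonics tied; physiological jitter
  # concentrates the global maximum at the fundamental
  for (seed in 1:3) {
    tr <- jittered_train(0.25, 300, cv = 0.05, seed = seed)
    db <- db_ratio(welch_psd(tr), surrogate_spectrum(tr, 10, seed = 3))
    pk <- peak_burst_frequency(db)
    df <- db$freq[2] - db$freq[1]
    expect_false(pk$excluded)
    expect_lt(abs(pk$peak_frequency - 0.25), df + 1e-9)
  }
})

test_that("the peak rule excludes out-of-band and chance-level spectra", {
  mk <- function(freq, power_db) structure(
    list(freq = freq, power_db = power_db, source_id = "x",
         n_surrogates = 1L, settings = welch_settings(), floored = FALSE),
    class = "db_spectrum")
  f <- seq(0, 5, by = 0.02)
  p <- rep(1, length(f)); p[f == 0.4] <- 8
  res <- peak_burst_frequency(mk(f, p))
  expect_equal(res$peak_frequency, 0.4)
  p2 <- rep(1, length(f)); p2[f == 1.5] <- 8
  res2 <- peak_burst_frequency(mk(f, p2))
  expect_true(res2$excluded)
  expect_equal(res2$reason, "peak-outside-band")
  # exact tie between 0.4 and 0.6: lowest frequency wins, flagged
  p3 <- rep(1, length(f)); p3[f %in% c(0.4, 0.6)] <- 8
  res3 <- peak_burst_frequency(mk(f, p3))
  expect_equal(res3$peak_frequency, 0.4)
  expect_true(res3$tie)
  # all-equal spectrum is degenerate
  expect_true(peak_burst_frequency(mk(f, rep(2, length(f))))$excluded)
  # a global max at or below 0 dB carries no patterning
  p4 <- -abs(sin(f)) - 0.1
  res4 <- peak_burst_frequency(mk(f, p4))
  expect_true(res4$excluded)
  expect_equal(res4$reason, "no-patterning")
  # DC bin never eligible even if largest
  p5 <- rep(1, length(f)); p5[1] <- 50; p5[f == 0.3] <- 8
  expect_equal(peak_burst_frequency(mk(f, p5))$peak_frequency, 0.3)
})

test_that("population average of identical trains equals the single train", {
  x <- jittered_train(0.5, 120, cv = 0.05, seed = 8)$x
  ras <- spike_raster(rep(list(which(x == 1L) / 1000 - 5e-4), 3),
                      duration = 120)
  pop <- population_average_spectrum(ras, n_surrogates = 3, seed = 5)
  # oracle: average the three per-source dB spectra computed independently
  # with the same derived surrogate seeds
  per <- lapply(1:3, function(i) {
    tr <- bin_to_1khz(ras)[[i]]
    db_ratio(welch_psd(tr),
             surrogate_spectrum(tr, 3, seed = derive_seed(5, "surrogate", i)))
  })
  manual <- rowMeans(do.call(cbind, lapply(per, `[[`, "power_db")))
  expect_equal(pop$power_db, manual)
  expect_equal(pop$n_sources, 3)
  # all-empty raster errors
  empty <- spike_raster(list(numeric(0), numeric(0)), duration = 10)
  expect_error(population_average_spectrum(empty), "degenerate-input")
})

test_that("surrogate normalization removes rate information", {
  # two Bernoulli trains with different rates both sit near 0 dB
  for (p in c(0.01, 0.08)) {
    tr <- bernoulli_train(p, 120, seed = round(p * 1000))
    db <- db_ratio(welch_psd(tr), surrogate_spectrum(tr, 10, seed = 1))
    expect_lt(abs(stats::median(db$power_db[db$freq > 0])), 1)
  }
})

test_that("normalized change against the isogenic control is correct", {
  expect_equal(normalize_to_isogenic(0.2, 0.4), -0.5)
  expect_equal(normalize_to_isogenic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(normalize_to_isogenic(0.44, 0.40), 0.1)
  expect_error(normalize_to_isogenic(0.2, 0), "degenerate-input")
  expect_error(normalize_to_isogenic(numeric(0), 0.4), "degenerate-input")
})

test_that("derived seeds are stable, distinct and valid", {
  s1 <- derive_seed(1, "sim", 1)
  expect_identical(s1, derive_seed(1, "sim", 1))
  expect_false(s1 == derive_seed(1, "sim", 2))
  expect_false(s1 == derive_seed(2, "sim", 1))
  expect_false(s1 == derive_seed(1, "analysis", 1))
  expect_true(s1 >= 0 && s1 < 2^31)
})
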
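# scan/dropout tests run the simulator on deliberately tiny profiles: the
# point here is plumbing (tables, statuses, caching, tie-breaks), not the
# bursting regime, which test-acceptance.R exercises at the scaled profile.

tiny_scan_config <- function() network_config(n_neurons = 30, duration = 4,
                                              seed = 1)

test_that("a one-point fit scan equals a direct simulate-and-analyze call", {
  cfg <- tiny_scan_config()
  p <- genotype_fixture("WT")$params
  scan <- run_fit_scan(C_m_values = 100, tau_m_values = 10, params = p,
                       config = cfg, seeds = 4, n_surrogates = 2)
  expect_equal(nrow(scan), 1)
  expect_true(scan$status %in% c("ok", "excluded", "failed"))
  direct <- burstnet:::simulate_and_analyze(cfg, p, n_surrogates = 2, seed = 4)
  if (scan$status == "ok")
    expect_equal(scan$peak_frequency, direct$peak_frequency)
  else
    expect_equal(scan$status, direct$status)
})

test_that("scan tables contain every combination x seed with a status", {
  scan <- run_fit_scan(C_m_values = c(80, 100), tau_m_values = c(10, 20),
                       config = tiny_scan_config(), seeds = 1:2,
                       n_surrogates = 2)
  expect_equal(nrow(scan), 8)
  expect_setequal(unique(scan$C_m), c(80, 100))
  expect_true(all(table(scan$C_m, scan$tau_m) == 2))
  expect_true(all(scan$status %in% c("ok", "excluded", "failed")))
  expect_error(run_fit_scan(C_m_values = numeric(0)), "invalid-config")
})

test_that("scan caching makes reruns identical and resumable", {
  cache <- file.path(tempdir(), "burstnet-cache-test")
  unlink(cache, recursive = TRUE)
  s1 <- run_fit_scan(C_m_values = 100, tau_m_values = c(10, 15),
                     config = tiny_scan_config(), seeds = 1,
                     n_surrogates = 2, cache_dir = cache)
  expect_length(list.files(cache), 2)
  s2 <- run_fit_scan(C_m_values = 100, tau_m_values = c(10, 15),
                     config = tiny_scan_config(), seeds = 1,
                     n_surrogates = 2, cache_dir = cache)
  expect_equal(s1$peak_frequency, s2$peak_frequency)
  unlink(cache, recursive = TRUE)
})

test_that("select_top_fit takes the argmin with documented tie-breaks", {
  scan <- structure(data.frame(
    C_m = rep(c(80, 100, 120), each = 2), tau_m = 10,
    seed = rep(1:2, 3),
    peak_frequency = c(0.2, 0.2, 0.35, 0.35, 0.6, 0.6),
    peak_db = 5, status = "ok", reason = ""),
    class = c("scan_result", "data.frame"))
  top <- select_top_fit(scan, target_peak = 0.33)
  expect_equal(top$C_m, 100)
  expect_equal(top$median_peak, 0.35)
  expect_false(top$tie)
  # single row
  one <- scan[1:2, ]
  expect_equal(select_top_fit(one, 0.9)$C_m, 80)
  # equidistant rows: tie flagged, broken by dispersion then order
  scan$peak_frequency <- c(0.30, 0.30, 0.40, 0.40, 0.6, 0.6)
  top2 <- select_top_fit(scan, 0.35)
  expect_true(top2$tie)
  expect_equal(top2$C_m, 80)  # equal dispersion: lexicographic order
  # all excluded
  scan$status <- "excluded"
  expect_error(select_top_fit(scan, 0.3), "no-fit")
})

test_that("dropout_swap exchanges exactly the named subset", {
  wt <- genotype_fixture("WT")
  nul <- genotype_fixture("NULL")
  # identity swap
  same <- dropout_swap(wt, wt, "adaptation")
  expect_identical(unclass(same$params), unclass(wt$params))
  # adaptation swap: donor (a, b, tau_w), everything else from base
  res <- dropout_swap(nul, wt, "adaptation")
  expect_identical(res$params[c("a", "b", "tau_w")],
                   wt$params[c("a", "b", "tau_w")])
  expect_identical(res$params[c("C_m", "E_L", "g_L", "w_e")],
                   nul$params[c("C_m", "E_L", "g_L", "w_e")])
  # membrane swap: donor (C_m, E_L) only
  res2 <- dropout_swap(wt, nul, "membrane")
  expect_identical(res2$params[c("C_m", "E_L")],
                   nul$params[c("C_m", "E_L")])
  expect_identical(res2$params[c("a", "b", "tau_w", "g_L")],
                   wt$params[c("a", "b", "tau_w", "g_L")])
  expect_error(dropout_swap(wt, nul, "synapse"), "invalid-config")
})

test_that("swapping both disjoint subsets back restores the base set", {
  wt <- genotype_fixture("WT")
  nul <- genotype_fixture("NULL")
  once <- dropout_swap(nul, wt, "adaptation")
  back <- dropout_swap(once, nul, "adaptation")
  expect_identical(unclass(back$params), unclass(nul$params))
})

test_that("the dropout experiment tabulates all six conditions", {
  res <- run_dropout_experiment(genotype_fixture("WT"),
                                genotype_fixture("NULL"),
                                config = tiny_scan_config(), seeds = 1,
                                n_surrogates = 2)
  expect_equal(nrow(res$table), 6)
  expect_length(unique(res$table$condition), 6)
  expect_true(all(res$table$status %in% c("ok", "excluded", "failed")))
})

test_that("identical genotype inputs give statistically identical conditions", {
  wt <- genotype_fixture("WT")
  res <- run_dropout_experiment(wt, wt, config = tiny_scan_config(),
                                seeds = 3, n_surrogates = 2)
  # same params + same seed => identical rows modulo the condition label
  expect_equal(length(unique(res$table$peak_frequency)), 1)
  expect_equal(length(unique(res$table$status)), 1)
})

test_that("connectivity scan reports per-a monotonicity summaries", {
  scan <- run_connectivity_scan(a_values = 4, p_values = c(0.05, 0.2),
                                config = tiny_scan_config(), seeds = 1:2,
                                n_surrogates = 2)
  expect_equal(nrow(scan), 4)
  s <- attr(scan, "summary")
  expect_named(s, c("spearman_peak_vs_p_by_a", "effect_range_p",
                    "effect_range_a", "medians"), ignore.order = TRUE)
})
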
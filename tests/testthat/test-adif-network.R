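test_that("connectivity graph matches its Bernoulli edge model", {
  g <- build_connectivity(1000, 0.05, seed = 1)
  # mean out-degree within 3 binomial standard errors of p*(n-1)
  se <- sqrt(0.05 * 0.95 * 999 / 1000)
  expect_lt(abs(g$mean_out_degree - 0.05 * 999), 3 * se)
  # no self-edges, valid indices
  expect_false(any(vapply(seq_len(1000),
                          function(i) i %in% g$targets[[i]], logical(1))))
  expect_true(all(unlist(g$targets) >= 1 & unlist(g$targets) <= 1000))
  # out-degree dispersion consistent with Binomial(n-1, p)
  deg <- lengths(g$targets)
  expect_lt(abs(var(deg) - 999 * 0.05 * 0.95), 0.25 * 999 * 0.05 * 0.95)
})

test_that("connectivity handles degenerate probabilities and is seeded", {
  expect_equal(build_connectivity(7, 0, seed = 1)$n_edges, 0)
  g1 <- build_connectivity(5, 1, seed = 3)
  expect_equal(g1$n_edges, 20)  # complete digraph without self-edges
  g2 <- build_connectivity(50, 0.2, seed = 11)
  g3 <- build_connectivity(50, 0.2, seed = 11)
  expect_identical(g2, g3)
  expect_error(build_connectivity(10, 1.5), "invalid-config")
})

test_that("external drive is Poisson with the configured mean", {
  cfg <- network_config(n_neurons = 20000, duration = 1, seed = 1)
  set.seed(5)
  counts <- draw_external_drive(cfg)
  # mean count per step: 100 synapses * 20 Hz * 0.1 ms = 0.2
  expect_lt(abs(mean(counts) - 0.2), 3 * sqrt(0.2 / 20000))
  cfg0 <- network_config(n_neurons = 100, ext_rate = 0)
  expect_true(all(draw_external_drive(cfg0) == 0))
})

test_that("batched external drive reproduces the per-step stream", {
  cfg <- network_config(n_neurons = 30, duration = 1, seed = 1)
  set.seed(9)
  m <- draw_external_drive(cfg, n_steps = 50)
  set.seed(9)
  singles <- vapply(1:50, function(k) draw_external_drive(cfg),
                    integer(cfg$n_neurons))
  expect_identical(m, singles)
})

test_that("per-synapse empirical rate over a long draw is the nominal 20 Hz", {
  cfg <- network_config(n_neurons = 1, duration = 300, seed = 1)
  set.seed(21)
  events <- sum(draw_external_drive(cfg, n_steps = 300 * 10000))
  rate <- events / (cfg$n_ext_synapses * 300)
  se <- sqrt(20 / (100 * 300))  # Poisson standard error per synapse
  expect_lt(abs(rate - 20), 3 * se)
})

test_that("leak relaxation follows its closed form within 1%", {
  p <- passive_params(g_L = 5)  # tau_m = C_m/g_L = 20 ms
  st <- network_state(V = p$E_L + 10)
  dt <- 0.1
  for (k in 1:400) st <- integrate_step(st, p, dt)  # 40 ms = 2 tau_m
  expected <- p$E_L + 10 * exp(-40 * p$g_L / p$C_m)
  expect_lt(abs(st$V - expected) / abs(10 * exp(-2)), 0.01)
  expect_equal(st$t, 40)
  # convergence is monotone from above toward E_L
  st2 <- network_state(V = p$E_L + 10)
  path <- replicate(100, {st2 <<- integrate_step(st2, p, dt); st2$V})
  expect_true(all(diff(path) < 0) && all(path > p$E_L))
})

test_that("adaptation current decays exponentially when V is held at E_L", {
  p <- neuron_parameters(a = 0, b = 80, w_e = 0)
  st <- network_state(V = p$E_L, w = p$b)
  for (k in 1:1000) {
    st <- integrate_step(st, p, 0.1)
    st$V <- p$E_L  # clamp
  }
  expect_lt(abs(st$w - p$b * exp(-100 / p$tau_w)) / p$b, 0.01)
})

test_that("clamped synaptic conductance drives V to its fixed point", {
  p <- passive_params()
  gstar <- 4
  st <- network_state(V = p$E_L, g_e = gstar)
  for (k in 1:5000) {
    st <- integrate_step(st, p, 0.1)
    st$g_e[] <- gstar  # clamp the conductance
  }
  v_fix <- (p$g_L * p$E_L + gstar * p$E_e) / (p$g_L + gstar)
  # independent oracle: brute-force integration at 100x finer step
  v <- p$E_L
  for (k in 1:500000) v <- v + 0.001 *
    (p$g_L * (p$E_L - v) + gstar * (p$E_e - v)) / p$C_m
  expect_lt(abs(st$V - v_fix), 0.05)
  expect_lt(abs(v - v_fix), 0.05)
})

test_that("g_e decays by the exact exponential factor", {
  p <- passive_params()
  st <- network_state(V = rep(p$E_L, 3), g_e = c(1, 2, 3))
  st2 <- integrate_step(st, p, 0.1)
  expect_equal(st2$g_e, c(1, 2, 3) * exp(-0.1 / p$tau_e))
})

test_that("integrate_step names the offending neuron on numeric failure", {
  p <- passive_params()
  st <- network_state(V = c(-65, NaN, -65))
  expect_error(integrate_step(st, p, 0.1), "neuron index 2")
})

test_that("resets record spikes, reset V, bump w and deliver to targets", {
  p <- neuron_parameters()
  graph <- list(targets = list(c(2L, 3L, 4L), integer(0), integer(0),
                               integer(0), integer(0)),
                n_neurons = 5L)
  st <- network_state(V = c(p$V_th + 1, rep(p$E_L, 4)))
  out <- apply_resets(st, p, graph)
  expect_equal(out$spikers, 1L)
  expect_equal(out$state$V[1], p$V_r)
  expect_equal(out$state$w[1], p$b)
  expect_equal(out$state$g_e, c(0, p$w_e, p$w_e, p$w_e, 0))
})

test_that("coincident presynaptic spikes accumulate conductance", {
  p <- neuron_parameters()
  graph <- list(targets = list(3L, 3L, integer(0)), n_neurons = 3L)
  st <- network_state(V = c(p$V_th, p$V_th, p$E_L))
  out <- apply_resets(st, p, graph)
  # event-by-event brute force: two deliveries of w_e each
  expect_equal(out$state$g_e[3], 2 * p$w_e)
  expect_setequal(out$spikers, c(1L, 2L))
})

test_that("no threshold crossing leaves the state untouched", {
  p <- neuron_parameters()
  graph <- build_connectivity(4, 0.5, seed = 1)
  st <- network_state(V = rep(p$E_L, 4), g_e = runif(4), w = runif(4))
  out <- apply_resets(st, p, graph)
  expect_identical(out$state[c("V", "g_e", "w")], st[c("V", "g_e", "w")])
  expect_length(out$spikers, 0)
})

test_that("simulation without any drive produces zero spikes", {
  cfg <- tiny_config(ext_rate = 0)
  raster <- simulate_network(cfg, neuron_parameters(w_e = 0))
  expect_equal(n_spikes(raster), 0)
})

test_that("compiled and reference engines are bit-identical", {
  cfg <- network_config(n_neurons = 40, duration = 1.5, seed = 77)
  p <- neuron_parameters()
  r_cpp <- simulate_network(cfg, p, engine = "cpp")
  r_ref <- simulate_network(cfg, p, engine = "r")
  expect_gt(n_spikes(r_cpp), 0)
  expect_identical(r_cpp, r_ref)
})

test_that("simulation is reproducible and respects its seed", {
  cfg <- tiny_config()
  p <- neuron_parameters()
  r1 <- simulate_network(cfg, p)
  r2 <- simulate_network(cfg, p)
  expect_identical(r1, r2)
  cfg2 <- tiny_config()
  cfg2$seed <- 43L
  r3 <- simulate_network(cfg2, p)
  expect_false(identical(r1$times, r3$times))
})

test_that("every threshold crossing yields exactly one raster entry", {
  # conservation of events: spike count equals reset count, tracked by
  # stepping the reference engine manually
  cfg <- network_config(n_neurons = 30, duration = 0.4, seed = 5)
  p <- neuron_parameters()
  raster <- simulate_network(cfg, p, engine = "r")
  set.seed(cfg$seed)
  graph <- build_connectivity(cfg$n_neurons, cfg$connection_probability)
  st <- network_state(V = rep(p$E_L, 30))
  n_resets <- 0L
  for (k in seq_len(4000)) {
    st$g_e <- st$g_e + cfg$w_ext * stats::rpois(30, 0.2)
    st <- integrate_step(st, p, 0.1)
    out <- apply_resets(st, p, graph)
    st <- out$state
    n_resets <- n_resets + length(out$spikers)
    expect_true(all(st$V <= p$V_th))
  }
  expect_equal(n_spikes(raster), n_resets)
})

test_that("invalid configurations are rejected before any compute", {
  expect_error(network_config(duration = 1, dt = 0.3), "near-integer")
  expect_error(network_config(ext_rate = -1), "invalid-config")
  expect_error(neuron_parameters(V_r = -40), "V_r")
  expect_error(neuron_parameters(C_m = 0), "C_m")
})
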
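# Shared fixtures for the test suite. Everything is generated in code at
# test time; sizes are kept small so the default run stays fast.

# a strictly periodic binned train: one spike every `period_s`, at 1 kHz
periodic_train <- function(period_s, duration_s, phase_s = 0) {
  n <- duration_s * 1000
  x <- integer(n)
  idx <- seq(phase_s * 1000 + 1, n, by = period_s * 1000)
  x[idx] <- 1L
  binned_train(x, duration = duration_s, source_id = "periodic")
}

# near-periodic train: renewal intervals with a small CV. A perfectly
# periodic binary train is a Dirac comb whose harmonics all tie for the
# global maximum, so the "peak frequency" of an exactly periodic train is
# ill-posed; physiological trains carry timing jitter that concentrates the
# surrogate-normalized maximum at the fundamental.
jittered_train <- function(rate, duration_s, cv = 0.05, seed = 1) {
  set.seed(seed)
  mu <- 1 / rate
  t <- mu / 2
  spikes <- numeric(0)
  while (t < duration_s) {
    spikes <- c(spikes, t)
    t <- t + max(mu / 4, rnorm(1, mu, cv * mu))
  }
  x <- integer(duration_s * 1000)
  x[floor(spikes * 1000) + 1] <- 1L
  binned_train(x, duration = duration_s, source_id = "jittered")
}

# homogeneous Bernoulli train
bernoulli_train <- function(p, duration_s, seed) {
  set.seed(seed)
  binned_train(rbinom(duration_s * 1000, 1, p), duration = duration_s,
               source_id = "bernoulli")
}

# a small network configuration that simulates in well under a second
tiny_config <- function(...) {
  network_config(n_neurons = 25, duration = 0.5, seed = 42, ...)
}

# quasi-steady-state test params: no adaptation, no synapses
passive_params <- function(...) {
  neuron_parameters(a = 0, b = 0, w_e = 0, ...)
}
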
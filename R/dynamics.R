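#' Network state container
#'
#' Per-neuron membrane potential `V` (mV), excitatory conductance `g_e`
#' (nS), adaptation current `w` (pA) and the current time `t` (ms).
#'
#' @param V,g_e,w numeric vectors of equal length
#' @param t current time (ms)
#' @return An object of class `network_state`.
#' @export
network_state <- function(V, g_e = numeric(length(V)),
                          w = numeric(length(V)), t = 0) {
  stopifnot(length(g_e) == length(V), length(w) == length(V))
  structure(list(V = as.numeric(V), g_e = as.numeric(g_e),
                 w = as.numeric(w), t = as.numeric(t)),
            class = "network_state")
}

#' Draw one step of external Poisson drive
#'
#' Each neuron receives `n_ext_synapses` independent Poisson input synapses
#' firing at `ext_rate` Hz; over one step of `dt` ms the summed event count
#' per neuron is Poisson with mean `n_ext_synapses * ext_rate * dt / 1000`.
#' Each event increments that neuron's `g_e` by the external weight.
#'
#' @param config a [network_config()]
#' @param step_index step number (unused by the stationary process; kept for
#'   interface completeness)
#' @param n_steps draw this many consecutive steps at once; the result is
#'   then an `n_neurons` x `n_steps` matrix whose columns reproduce exactly
#'   the sequence of single-step draws
#' @return integer vector of event counts, one per neuron (or a matrix when
#'   `n_steps > 1`)
#' @export
draw_external_drive <- function(config, step_index = NULL, n_steps = 1L) {
  lambda <- config$n_ext_synapses * config$ext_rate * config$dt / 1000
  if (!is.finite(lambda) || lambda < 0)
    stop("invalid-config: external drive rate must be finite and >= 0")
  if (n_steps == 1L) return(stats::rpois(config$n_neurons, lambda))
  matrix(stats::rpois(config$n_neurons * n_steps, lambda),
         nrow = config$n_neurons, ncol = n_steps)
}

#' Forward-Euler integration of the membrane and adaptation equations
#'
#' Advances `V` and `w` by one forward-Euler step of the AdIF equations
#' \deqn{C_m \dot V = g_L (E_L - V) + g_e (E_e - V) - w}
#' \deqn{\tau_w \dot w = a (V - E_L) - w}
#' and applies the exact exponential decay factor `exp(-dt/tau_e)` to the
#' synaptic conductance. No threshold/reset handling happens here; see
#' [apply_resets()].
#'
#' @param state a [network_state()]
#' @param params a [neuron_parameters()]
#' @param dt step (ms)
#' @return The advanced `network_state`.
#' @export
integrate_step <- function(state, params, dt) {
  if (dt <= 0) stop("invalid-config: dt must be > 0")
  bad <- which(!is.finite(state$V) | !is.finite(state$w) | !is.finite(state$g_e))
  if (length(bad))
    stop("numeric-failure: non-finite state at neuron index ", bad[1])
  V <- state$V; w <- state$w; g_e <- state$g_e
  dV <- (params$g_L * (params$E_L - V) + g_e * (params$E_e - V) - w) / params$C_m
  dw <- (params$a * (V - params$E_L) - w) / params$tau_w
  network_state(V = V + dt * dV,
                g_e = g_e * exp(-dt / params$tau_e),
                w = w + dt * dw,
                t = state$t + dt)
}

#' Threshold crossing, reset and synaptic delivery
#'
#' For every neuron with `V >= V_th`: a spike is recorded, `V` is reset to
#' `V_r`, the adaptation current is incremented by `b`, and every
#' postsynaptic target's conductance is incremented by `w_e`. Increments
#' accumulate when a target has several presynaptic partners spiking in the
#' same step. Synaptic delivery is same-step (no axonal delay).
#'
#' @param state a [network_state()]
#' @param params a [neuron_parameters()]
#' @param graph a [build_connectivity()] graph
#' @return list with `state` (updated) and `spikers` (integer ids of
#'   neurons that crossed threshold this step)
#' @export
apply_resets <- function(state, params, graph) {
  spikers <- which(state$V >= params$V_th)
  if (length(spikers)) {
    state$V[spikers] <- params$V_r
    state$w[spikers] <- state$w[spikers] + params$b
    tgt <- unlist(graph$targets[spikers], use.names = FALSE)
    if (length(tgt))
      state$g_e <- state$g_e +
        params$w_e * tabulate(tgt, nbins = length(state$V))
  }
  list(state = state, spikers = spikers)
}

#' Simulate the recurrent AdIF network
#'
#' Runs the full simulation loop: per step, external Poisson events are
#' delivered, the membrane/adaptation equations advance by forward Euler
#' with exact synaptic decay, and threshold crossings are reset with
#' same-step recurrent delivery. Initial condition is `V = E_L` (optionally
#' Gaussian-jittered), `w = 0`, `g_e = 0`. The run is bit-reproducible:
#' connectivity, initialization and drive all derive from `config$seed`.
#'
#' @param config a [network_config()]
#' @param params a [neuron_parameters()]
#' @param graph optional pre-built [build_connectivity()] graph; when `NULL`
#'   one is drawn from the run's RNG stream
#' @param engine `"cpp"` (compiled core, default) or `"r"` (pure-R reference
#'   loop built from [integrate_step()]/[apply_resets()]); the two consume
#'   the RNG identically and produce bit-identical rasters
#' @param max_spikes abort with a `runaway-network` error once the raster
#'   exceeds this many spikes — a guard against saturated reverberation
#'   states far outside the model's physiological regime, used by the
#'   parameter scans to mark such combinations failed instead of spending
#'   minutes simulating them; `Inf` disables the guard
#' @return A [spike_raster()] of kind `"simulated-neuron"`.
#' @export
#' @examples
#' cfg <- network_config(n_neurons = 50, duration = 2, seed = 7)
#' ras <- simulate_network(cfg, neuron_parameters())
#' n_spikes(ras)
simulate_network <- function(config, params, graph = NULL,
                             engine = c("cpp", "r"), max_spikes = Inf) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "network_config"),
            inherits(params, "neuron_parameters"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  if (is.null(graph))
    graph <- build_connectivity(config$n_neurons,
                                config$connection_probability)
  n <- config$n_neurons
  V0 <- rep(params$E_L, n)
  if (config$jitter_init > 0)
    V0 <- V0 + stats::rnorm(n, sd = config$jitter_init)
  w_ext <- if (is.null(config$w_ext)) params$w_e else config$w_ext
  n_steps <- as.integer(round(config$duration * 1000 / config$dt))
  lambda <- config$n_ext_synapses * config$ext_rate * config$dt / 1000

  if (engine == "cpp") {
    res <- simulate_adif_cpp(
      V0, graph$targets, n_steps, config$dt, lambda, w_ext,
      params$C_m, params$g_L, params$E_L, params$E_e, params$V_th,
      params$V_r, params$tau_w, params$a, params$b, params$tau_e,
      params$w_e, max_spikes)
    spk_neuron <- res$neuron
    spk_time <- res$time_ms
  } else {
    state <- network_state(V = V0, t = 0)
    spk_neuron <- vector("list", n_steps)
    n_spk <- 0
    for (k in seq_len(n_steps)) {
      if (lambda > 0)
        state$g_e <- state$g_e + w_ext * stats::rpois(n, lambda)
      state <- integrate_step(state, params, config$dt)
      rs <- apply_resets(state, params, graph)
      state <- rs$state
      spk_neuron[[k]] <- rs$spikers
      n_spk <- n_spk + length(rs$spikers)
      if (n_spk > max_spikes)
        stop(sprintf("runaway-network: spike budget exceeded at t = %.1f ms",
                     k * config$dt))
    }
    counts <- lengths(spk_neuron)
    spk_time <- rep(seq_len(n_steps) * config$dt, counts)
    spk_neuron <- unlist(spk_neuron, use.names = FALSE)
    if (is.null(spk_neuron)) spk_neuron <- integer(0)
  }
  times <- split(spk_time / 1000, factor(spk_neuron, levels = seq_len(n)))
  names(times) <- NULL
  spike_raster(times, duration = config$duration,
               source_ids = seq_len(n), kind = "simulated-neuron")
}
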
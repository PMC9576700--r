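#' Single-neuron model constants for the adaptive integrate-and-fire neuron
#'
#' Bundles every constant of the two-variable AdIF model: the membrane
#' equation \deqn{C_m \dot V = g_L (E_L - V) + g_e (E_e - V) - w} and the
#' adaptation equation \deqn{\tau_w \dot w = a (V - E_L) - w,} with reset
#' rules \eqn{V \to V_r}, \eqn{w \to w + b} on threshold crossing and
#' exponential synaptic decay \eqn{\tau_e \dot g_e = -g_e}. Units are fixed
#' internally at pF / nS / mV / pA / ms.
#'
#' @param C_m membrane capacitance (pF)
#' @param g_L leak conductance (nS)
#' @param E_L resting (leak reversal) potential (mV)
#' @param E_e excitatory reversal potential (mV); must exceed `V_th`
#' @param V_th spike threshold (mV)
#' @param V_r reset potential (mV); must be below `V_th`
#' @param tau_w adaptation time constant (ms)
#' @param a subthreshold adaptation conductance (nS)
#' @param b spike-triggered adaptation increment (pA)
#' @param tau_e excitatory synaptic time constant (ms)
#' @param w_e recurrent synaptic weight: conductance increment per
#'   presynaptic spike (nS)
#'
#' @return An object of class `neuron_parameters` (a validated named list).
#' @seealso [network_config()], [genotype_fixture()], [simulate_network()]
#' @export
#' @examples
#' p <- neuron_parameters()
#' p$C_m / p$g_L  # membrane time constant tau_m in ms
neuron_parameters <- function(C_m = 100, g_L = 10, E_L = -65, E_e = 0,
                              V_th = -50, V_r = -60, tau_w = 1000,
                              a = 4, b = 800, tau_e = 5, w_e = 2.5) {
  p <- list(C_m = C_m, g_L = g_L, E_L = E_L, E_e = E_e, V_th = V_th,
            V_r = V_r, tau_w = tau_w, a = a, b = b, tau_e = tau_e, w_e = w_e)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("invalid-config: '", nm, "' must be a single finite number")
    p[[nm]] <- as.numeric(v)
  }
  if (p$C_m <= 0) stop("invalid-config: C_m must be > 0")
  if (p$g_L <= 0) stop("invalid-config: g_L must be > 0")
  if (p$tau_w <= 0) stop("invalid-config: tau_w must be > 0")
  if (p$tau_e <= 0) stop("invalid-config: tau_e must be > 0")
  if (p$V_r >= p$V_th) stop("invalid-config: V_r must be below V_th")
  if (p$E_L >= p$V_th) stop("invalid-config: E_L must be below V_th")
  if (p$E_e <= p$V_th) stop("invalid-config: E_e must be above V_th")
  if (p$a < 0 || p$b < 0 || p$w_e < 0)
    stop("invalid-config: a, b and w_e must be >= 0")
  structure(p, class = "neuron_parameters")
}

#' @export
print.neuron_parameters <- function(x, ...) {
  cat("AdIF neuron parameters\n")
  cat(sprintf("  membrane:   C_m = %g pF, g_L = %g nS (tau_m = %.3g ms), E_L = %g mV\n",
              x$C_m, x$g_L, x$C_m / x$g_L, x$E_L))
  cat(sprintf("  spiking:    V_th = %g mV, V_r = %g mV\n", x$V_th, x$V_r))
  cat(sprintf("  adaptation: tau_w = %g ms, a = %g nS, b = %g pA\n",
              x$tau_w, x$a, x$b))
  cat(sprintf("  synapse:    E_e = %g mV, tau_e = %g ms, w_e = %g nS\n",
              x$E_e, x$tau_e, x$w_e))
  invisible(x)
}

#' Network-level simulation configuration
#'
#' Population size, random connectivity, external Poisson drive, duration and
#' integration step for [simulate_network()]. Defaults reproduce the study
#' conditions: 1000 neurons connected with probability 0.05, driven by 100
#' external Poisson synapses per neuron at 20 Hz, simulated for 300 s at a
#' 0.1 ms step.
#'
#' @param n_neurons number of neurons (>= 1)
#' @param connection_probability probability of each ordered directed
#'   connection, in \[0, 1\]
#' @param n_ext_synapses number of independent external Poisson input
#'   synapses per neuron
#' @param ext_rate firing rate of each external synapse (Hz)
#' @param w_ext external synaptic weight (nS). The default 0.26 nS places
#'   the summed external drive just below threshold, so spiking between
#'   network bursts is rare and fluctuation-driven and collective bursts
#'   are ignited by recurrent amplification; set `w_ext = NULL` to tie it
#'   to the recurrent weight `w_e` instead
#' @param duration simulated time (s)
#' @param dt integration step (ms); `duration/dt` must be near-integer
#' @param seed integer random seed controlling connectivity, drive and
#'   initial-condition jitter
#' @param jitter_init standard deviation (mV) of optional Gaussian jitter
#'   added to initial membrane potentials to break symmetry; 0 disables it
#'
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_neurons = 1000, connection_probability = 0.05,
                           n_ext_synapses = 100, ext_rate = 20,
                           w_ext = 0.26, duration = 300, dt = 0.1,
                           seed = 1L, jitter_init = 0) {
  if (!is.numeric(n_neurons) || n_neurons < 1)
    stop("invalid-config: n_neurons must be >= 1")
  if (!is.numeric(connection_probability) ||
      connection_probability < 0 || connection_probability > 1)
    stop("invalid-config: connection_probability must be in [0, 1]")
  if (!is.numeric(ext_rate) || ext_rate < 0)
    stop("invalid-config: ext_rate must be >= 0")
  if (!is.numeric(duration) || duration <= 0)
    stop("invalid-config: duration must be > 0")
  if (!is.numeric(dt) || dt <= 0)
    stop("invalid-config: dt must be > 0")
  n_steps <- duration * 1000 / dt
  if (abs(n_steps - round(n_steps)) > 1e-6)
    stop("invalid-config: duration/dt must be a near-integer number of steps")
  if (!is.null(w_ext) && (!is.numeric(w_ext) || w_ext < 0))
    stop("invalid-config: w_ext must be >= 0")
  structure(list(n_neurons = as.integer(n_neurons),
                 connection_probability = as.numeric(connection_probability),
                 n_ext_synapses = as.integer(n_ext_synapses),
                 ext_rate = as.numeric(ext_rate),
                 w_ext = if (is.null(w_ext)) NULL else as.numeric(w_ext),
                 duration = as.numeric(duration),
                 dt = as.numeric(dt),
                 seed = as.integer(seed),
                 jitter_init = as.numeric(jitter_init)),
            class = "network_config")
}

#' Scaled-profile network configuration
#'
#' Convenience constructor for the reduced profile used in scans and test
#' work: 200 neurons simulated for 60 s (other fields as [network_config()]).
#'
#' @param ... overrides passed to [network_config()]
#' @return A `network_config`.
#' @export
scaled_network_config <- function(...) {
  args <- list(...)
  defaults <- list(n_neurons = 200, duration = 60)
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(network_config, args)
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("Network config: %d neurons, p = %g, %g s at dt = %g ms, seed %d\n",
              x$n_neurons, x$connection_probability, x$duration, x$dt, x$seed))
  cat(sprintf("  external drive: %d Poisson synapses/neuron at %g Hz (w_ext = %s)\n",
              x$n_ext_synapses, x$ext_rate,
              if (is.null(x$w_ext)) "w_e" else paste0(x$w_ext, " nS")))
  invisible(x)
}

#' Labelled genotype parameter set
#'
#' Couples a label (e.g. `"WIBR3-WT"`) with a [neuron_parameters()] set and a
#' provenance note recording which patch-clamp property motivated each value.
#'
#' @param label unique label for the genotype
#' @param params a `neuron_parameters` object
#' @param provenance free-text note on where the values come from
#' @return An object of class `genotype_parameter_set`.
#' @export
genotype_parameter_set <- function(label, params, provenance = "") {
  stopifnot(is.character(label), length(label) == 1L)
  if (!inherits(params, "neuron_parameters"))
    stop("invalid-config: params must be a neuron_parameters object")
  structure(list(label = label, params = params, provenance = provenance),
            class = "genotype_parameter_set")
}

#' @export
print.genotype_parameter_set <- function(x, ...) {
  cat("Genotype parameter set:", x$label, "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  print(x$params)
  invisible(x)
}
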
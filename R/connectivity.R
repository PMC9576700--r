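#' Random excitatory connectivity graph
#'
#' Draws a directed Erdos-Renyi graph over `n_neurons` sources: each ordered
#' pair (i, j), i != j, is an edge independently with probability
#' `connection_probability`. Self-connections are excluded. At the study
#' defaults (1000 neurons, p = 0.05) this yields an average of about 50
#' synapses per cell.
#'
#' @param n_neurons number of neurons
#' @param connection_probability edge probability in \[0, 1\]
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   consumed (used inside [simulate_network()], which seeds once per run)
#'
#' @return An object of class `connectivity_graph`: a list with `targets`
#'   (list of integer vectors, postsynaptic targets per presynaptic neuron),
#'   `n_neurons`, `n_edges` and `mean_out_degree`.
#' @export
#' @examples
#' g <- build_connectivity(1000, 0.05, seed = 1)
#' g$mean_out_degree  # ~ 0.05 * 999
build_connectivity <- function(n_neurons, connection_probability, seed = NULL) {
  if (!is.numeric(connection_probability) ||
      connection_probability < 0 || connection_probability > 1)
    stop("invalid-config: connection_probability must be in [0, 1]")
  if (!is.numeric(n_neurons) || n_neurons < 1)
    stop("invalid-config: n_neurons must be >= 1")
  n <- as.integer(n_neurons)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  targets <- vector("list", n)
  for (i in seq_len(n)) {
    hit <- which(stats::runif(n) < connection_probability)
    targets[[i]] <- hit[hit != i]
  }
  n_edges <- sum(lengths(targets))
  structure(list(targets = targets, n_neurons = n,
                 n_edges = n_edges, mean_out_degree = n_edges / n),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("Connectivity graph: %d neurons, %d directed edges, mean out-degree %.2f\n",
              x$n_neurons, x$n_edges, x$mean_out_degree))
  invisible(x)
}

# Save / restore .Random.seed so seeded helpers do not perturb callers.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
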
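#' Genotype parameter fixtures
#'
#' Documented stand-in parameter sets for the wild-type, MECP2-null and
#' L124W missense genotypes. The underlying patch-clamp study reports the
#' qualitative directions of change, not numeric model constants, so these
#' values are versioned calibration constants (see
#' `scripts/calibrate-fixtures.R`) chosen to respect every directional
#' relation and to place simulated peak burst frequencies in the order
#' NULL < WT < L124W, all below 1 Hz:
#'
#' * `NULL` vs WT: decreased cell capacitance (`C_m` down), depolarized
#'   resting potential (`E_L` up), higher input resistance (`g_L` down),
#'   and impaired voltage-gated Na+/K+ currents represented by stronger,
#'   slower adaptation (`a`, `b`, `tau_w` up).
#' * `L124W` vs WT: unchanged capacitance and resting potential; higher
#'   input resistance (`g_L` down) and mildly reduced adaptation
#'   (`a`, `b` down), speeding bursting slightly.
#'
#' @param label `"WT"`, `"NULL"` or `"L124W"` (optionally prefixed, e.g.
#'   `"WIBR3-WT"`; the suffix after the last `-` is used)
#' @return A [genotype_parameter_set()].
#' @export
#' @examples
#' genotype_fixture("WT")$params$C_m
genotype_fixture <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  core <- toupper(sub(".*-", "", label))
  params <- switch(
    core,
    "WT" = neuron_parameters(C_m = 100, g_L = 10, E_L = -65,
                             tau_w = 1000, a = 4, b = 800, w_e = 2.5),
    "NULL" = neuron_parameters(C_m = 90, g_L = 9.9, E_L = -64.9,
                               tau_w = 1300, a = 5, b = 1100, w_e = 2.5),
    "L124W" = neuron_parameters(C_m = 100, g_L = 9.9, E_L = -65,
                                tau_w = 1000, a = 3.8, b = 500, w_e = 2.5),
    stop("invalid-config: unknown genotype label '", label, "'"))
  prov <- switch(
    core,
    "WT" = "isogenic control; membrane constants mid-physiological",
    "NULL" = paste("MECP2 null direction: lower C_m, depolarized E_L,",
                   "higher input resistance (lower g_L), impaired Na+/K+",
                   "currents as stronger/slower adaptation (a, b, tau_w up)"),
    "L124W" = paste("L124W direction: C_m and E_L unchanged from WT, higher",
                    "input resistance (lower g_L), mildly reduced",
                    "adaptation (a, b down)"))
  genotype_parameter_set(label, params, prov)
}
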
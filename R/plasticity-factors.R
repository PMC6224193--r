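# Derivation of the monocular-deprivation plasticity factors from measured
# charge ratios: delta_E and delta_I (thalamocortical depression onto
# excitatory / inhibitory cells), pi (potentiation of recurrent excitation
# onto inhibition) and rho_EI = delta_E / delta_I.

#' Derive the thalamocortical depression factor onto inhibitory neurons
#'
#' The deprived/control shift in the pyramidal/PV EPSC charge ratio equals
#' `delta_E / delta_I` (both cell types are driven by the same thalamic
#' afferents, so the shared depression cancels). Given the directly measured
#' `delta_E`, the inhibitory factor is
#' `delta_I = delta_E / (ratio_deprived / ratio_control)`.
#'
#' @param delta_e Measured thalamocortical depression factor onto excitatory
#'   neurons (fraction of control strength, e.g. 0.9).
#' @param ratio_control,ratio_deprived Pyramidal/PV EPSC charge ratios in the
#'   control and deprived hemispheres.
#' @return `delta_i` (dimensionless fraction).
#' @examples
#' derive_delta_i(0.9, 1, 1.5)          # shift of 1.5 -> 0.6
#' derive_delta_i(0.9, 0.260, 0.369)    # from the measured group means
#' @export
derive_delta_i <- function(delta_e, ratio_control, ratio_deprived) {
  for (v in list(delta_e = delta_e, ratio_control = ratio_control,
                 ratio_deprived = ratio_deprived)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop_l4ei("l4ei_invalid_ratio", "all arguments must be positive finite scalars")
    }
  }
  delta_e / (ratio_deprived / ratio_control)
}

#' Derive the feedback potentiation factor from intracortical E-I ratios
#'
#' The deprived/control shift of the intracortical E-I charge ratio is
#' attributed entirely to potentiation of excitatory drive onto inhibitory
#' interneurons (PV-to-pyramidal inhibitory synapses are unchanged by brief
#' deprivation), giving `pi = ratio_control / ratio_deprived`. Note that the
#' printed group means (0.091 / 0.066) give 1.38 while simulations
#' conventionally use the rounded 1.5; both are legitimate inputs to
#' [make_factors()].
#'
#' @param ic_ratio_control,ic_ratio_deprived Intracortical E-I charge ratios
#'   in control and deprived hemispheres.
#' @return `pi` (dimensionless potentiation factor).
#' @examples
#' derive_pi(0.15, 0.10)     # 1.5
#' derive_pi(0.091, 0.066)   # 1.379 from the measured group means
#' @export
derive_pi <- function(ic_ratio_control, ic_ratio_deprived) {
  if (!is.numeric(ic_ratio_control) || ic_ratio_control <= 0 ||
      !is.numeric(ic_ratio_deprived) || ic_ratio_deprived <= 0) {
    stop_l4ei("l4ei_invalid_ratio", "both ratios must be positive")
  }
  ic_ratio_control / ic_ratio_deprived
}

#' Bundle the scenario factors
#'
#' @param delta_e,delta_i Thalamocortical depression factors (fractions of
#'   control weight); values above 1 trigger a warning since these represent
#'   depression.
#' @param pi_fb Potentiation factor of recurrent excitation onto inhibition.
#' @return An object of class `scenario_factors` with fields `delta_e`,
#'   `delta_i`, `pi_fb` and the derived `rho_ei = delta_e / delta_i`. Carries
#'   the attribution assumption (PV-to-pyramidal strength unchanged) as an
#'   attribute.
#' @examples
#' make_factors(0.9, 0.6, 1.5)   # the measured early-deprivation factors
#' make_factors(1, 1, 1)         # baseline
#' @export
make_factors <- function(delta_e = 1, delta_i = 1, pi_fb = 1) {
  for (v in list(delta_e = delta_e, delta_i = delta_i, pi_fb = pi_fb)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop_l4ei("l4ei_invalid_factor", "all factors must be positive finite scalars")
    }
  }
  if (delta_e > 1 || delta_i > 1) {
    warning("depression factors above 1 imply potentiation of thalamic drive",
            call. = FALSE)
  }
  structure(list(delta_e = delta_e, delta_i = delta_i, pi_fb = pi_fb,
                 rho_ei = delta_e / delta_i),
            class = "scenario_factors",
            assumption = "PV->pyramidal inhibitory strength assumed unchanged")
}

#' @export
print.scenario_factors <- function(x, ...) {
  cat(sprintf("<scenario_factors> delta_E = %.4g, delta_I = %.4g, pi = %.4g (rho_EI = %.4g)\n",
              x$delta_e, x$delta_i, x$pi_fb, x$rho_ei))
  invisible(x)
}
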
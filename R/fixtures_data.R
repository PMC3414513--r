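#' Frozen fixture constants
#'
#' Numerical constants used by the canonical model fixtures: the static
#' gate relations of the planar reductions (least-squares fits over
#' spiking/burst trajectories of the full models, frozen here with their
#' provenance) and the calcium-conductance / pump-current pairings of the
#' augmented Hodgkin-Huxley model. Each pump current compensates its
#' calcium conductance so that the models share a comparable resting
#' potential; the pairs are treated as given constants, not recomputed.
#'
#' @format a named list:
#' \describe{
#'   \item{h_of_n}{linear sodium-inactivation relation \code{h = a + b n}
#'     for the reduced HH models.}
#'   \item{d_of_n}{power law \code{d = c n^p} slaving L-type calcium
#'     activation to the recovery variable.}
#'   \item{tc_h_of_n, tc_mT_of_n}{the merged-gate relations of the reduced
#'     TC model (fit over the burst window of the complete model).}
#'   \item{ca_sweep}{data frame of \code{(g_ca, i_pump)} pairs spanning
#'     the calcium-conductance sweep.}
#'   \item{fig_ca}{the high-calcium pair used by the canonical
#'     step-response fixture.}
#' }
#' @export
hourglass_fixture_constants <- list(
  ## linear h(n) over a tonic HH spiking trajectory (see fit_static_gate)
  h_of_n = c(a = 0.8658, b = -1.0532),
  ## static calcium activation at burst onset
  d_of_n = c(c = 1.5, p = 3),
  ## TC merged-gate relations, fit over the burst window of the complete
  ## model (the mT power law in log space to respect resting activations)
  tc_h_of_n = c(a = 0.9792, b = -1.3283),
  tc_mT_of_n = c(c = 1.5833, p = 0.5047),
  ## calcium conductance (mS/cm^2) / pump current (uA/cm^2) pairings
  ca_sweep = data.frame(g_ca = c(0, 1, 1.5, 3),
                        i_pump = c(0, -0.74, -2.78, -15.6)),
  fig_ca = c(g_ca = 3, i_pump = -15.6)
)
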
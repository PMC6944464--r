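#' Instantaneous valve flows and aortic pressure
#'
#' Valves are ideal diodes realized by flow clamping: mitral inflow
#' `Qmv = max(0, (Pat - P)/Rmv)` and aortic outflow
#' `Qao = max(0, (P - Pwk)/(R1 + R2))`; the aortic (central) pressure is
#' `Pao = Pwk + Qao * R2`, which reduces to the Windkessel pressure when
#' `R2 = 0`. No regurgitation is possible by construction.
#'
#' @param P Left-ventricular pressure (kPa).
#' @param state A list with at least `Pwk` and `Pat` (kPa), e.g.
#'   [circulation_state()].
#' @param cp A [circ_params()] object.
#' @return A list with `Qmv`, `Qao` (ml/s) and `Pao` (kPa).
#' @export
lv_flows <- function(P, state, cp) {
  stopifnot(inherits(cp, "circ_params"))
  if (!all(is.finite(c(P, state$Pwk, state$Pat))))
    abort("pressures must be finite")
  Qmv <- pmax(0, (state$Pat - P) / cp$Rmv)
  Qao <- pmax(0, (P - state$Pwk) / (cp$R1 + cp$R2))
  list(Qmv = Qmv, Qao = Qao, Pao = state$Pwk + Qao * cp$R2)
}

#' Circulation state container
#'
#' @param Pwk Windkessel capacitor pressure (kPa, >= 0).
#' @param Pat Current atrial pressure (kPa).
#' @return A list of class `circulation_state` with derived valve flags
#'   (set post hoc from flow signs during simulation).
#' @export
circulation_state <- function(Pwk, Pat) {
  if (any(Pwk < 0)) abort("Windkessel pressure must be >= 0")
  structure(list(Pwk = Pwk, Pat = Pat, mitral_open = NA, aortic_open = NA),
            class = "circulation_state")
}

#' Time derivative of the circulation state
#'
#' Windkessel capacitor: `dPwk/dt = (Qao - Pwk/R3) / Cwk`. Atrium: constant
#' mode holds `Pat` fixed; capacitor mode discharges as `dPat/dt = -Qmv/Cat`.
#'
#' @param state A list with `Pwk` and `Pat` (kPa).
#' @param Qmv,Qao Valve flows (ml/s), as returned by [lv_flows()] for the
#'   same state.
#' @param cp A [circ_params()] object.
#' @return A list with `dPwk` and `dPat` (kPa/s).
#' @export
circulation_derivative <- function(state, Qmv, Qao, cp) {
  stopifnot(inherits(cp, "circ_params"))
  dPwk <- (Qao - state$Pwk / cp$R3) / cp$Cwk
  dPat <- if (cp$atrium_mode == "capacitor") -Qmv / cp$Cat else 0 * Qmv
  list(dPwk = dPwk, dPat = dPat)
}
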
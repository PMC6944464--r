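#' Intracellular calcium transient
#'
#' Biexponential transient: diastolic level before activation onset, then
#' `Ca_d + Ca_amp * k * (exp(-s/tau2) - exp(-s/tau1))` for s = t - t_act >= 0,
#' with k chosen so the peak equals `Ca_d + Ca_amp`. Continuous in t.
#'
#' @param t Time within the beat (ms); vectorized.
#' @param p A [cell_params()] object.
#' @return Calcium concentration (uM).
#' @export
calcium_transient <- function(t, p) {
  stopifnot(inherits(p, "cell_params"))
  s <- t - p$t_act
  s_peak <- p$tau1 * p$tau2 / (p$tau2 - p$tau1) * log(p$tau2 / p$tau1)
  k <- 1 / (exp(-s_peak / p$tau2) - exp(-s_peak / p$tau1))
  ca <- p$Ca_d + p$Ca_amp * k * (exp(-s / p$tau2) - exp(-s / p$tau1))
  ca[s < 0] <- p$Ca_d
  ca
}

#' Cell state container
#'
#' @param A Activation gate in `[0, 1]`.
#' @param F Bound crossbridge fraction in `[0, 1]`.
#' @return A named list of class `cell_state`.
#' @export
cell_state <- function(A = 0, F = 0) {
  if (any(A < 0 | A > 1) || any(F < 0 | F > 1))
    abort("cell state components must lie in [0, 1]")
  structure(list(A = A, F = F), class = "cell_state")
}

#' Myofilament state derivative (f1 of the cell-unit contract)
#'
#' Default rate laws: `dA/dt = k_on * H(Ca) * (1 - A) - k_off * A` with the
#' Hill activation `H(Ca) = Ca^nA / (Ca^nA + Ca50^nA)`, and
#' `dF/dt = fXB * A * (1 - F) - gXB * F`. The stretch argument is part of the
#' stable interface (alternative cell units may use it) but does not enter
#' the default kinetics.
#'
#' @param s A [cell_state()].
#' @param lam Myofilament stretch (> 0).
#' @param ca Calcium concentration (uM, >= 0).
#' @param p A [cell_params()] object.
#' @return A `cell_state`-shaped list of time derivatives (1/s).
#' @export
cell_derivative <- function(s, lam, ca, p) {
  stopifnot(inherits(p, "cell_params"))
  if (any(ca < 0)) abort("calcium concentration must be >= 0")
  if (any(lam <= 0)) abort("stretch must be positive")
  H <- ifelse(ca > 0, (ca / p$Ca50)^p$nA / (1 + (ca / p$Ca50)^p$nA), 0)
  dA <- p$k_on * H * (1 - s$A) - p$k_off * s$A
  dF <- p$fXB * s$A * (1 - s$F) - p$gXB * s$F
  list(A = dA, F = dF)
}

#' Active tension map (f2 of the cell-unit contract)
#'
#' `Ta = Sa * F * L(lam)` with the linear length-dependence factor
#' `L(lam) = max(0, (lam - n0) / (1 - n0))`: no force below the minimum
#' stretch n0, unit factor at lam = 1.
#'
#' @inheritParams cell_derivative
#' @return Active tension (kPa, >= 0).
#' @export
active_tension <- function(s, lam, p) {
  stopifnot(inherits(p, "cell_params"))
  if (any(lam <= 0)) abort("stretch must be positive")
  L <- pmax(0, (lam - p$n0) / (1 - p$n0))
  p$Sa * s$F * L
}

#' Closed-form steady state of the cell unit at constant calcium
#'
#' At constant calcium the gate settles at
#' `A_ss = k_on * H / (k_on * H + k_off)` and the bound fraction at
#' `F_ss = fXB * A_ss / (fXB * A_ss + gXB)`.
#'
#' @param ca Calcium concentration (uM).
#' @param p A [cell_params()] object.
#' @return A list with `A`, `F` and the steady tension `Ta` at `lam`.
#' @param lam Stretch at which to evaluate the steady tension.
#' @export
cell_steady_state <- function(ca, p, lam = 1) {
  stopifnot(inherits(p, "cell_params"))
  if (any(ca < 0)) abort("calcium concentration must be >= 0")
  H <- ifelse(ca > 0, (ca / p$Ca50)^p$nA / (1 + (ca / p$Ca50)^p$nA), 0)
  A <- p$k_on * H / (p$k_on * H + p$k_off)
  F <- p$fXB * A / (p$fXB * A + p$gXB)
  list(A = A, F = F, Ta = p$Sa * F * pmax(0, (lam - p$n0) / (1 - p$n0)))
}

#' Integrate an isolated twitch at fixed stretch
#'
#' Isometric reference experiment: the cell unit is driven by its calcium
#' transient at a clamped stretch; states are integrated with fixed-step RK4.
#' Used to size the tension scale and to cross-check the compiled simulator.
#'
#' @param p A [cell_params()] object.
#' @param lam Clamped stretch.
#' @param t_end Duration (ms).
#' @param dt Time step (ms).
#' @param ca Optional constant calcium (uM); overrides the transient.
#' @return A tibble with `t_ms`, `Ca_uM`, `A`, `F`, `Ta_kPa`.
#' @export
simulate_twitch <- function(p, lam = 1.1, t_end = 1000, dt = 0.1, ca = NULL) {
  stopifnot(inherits(p, "cell_params"))
  n <- round(t_end / dt)
  tgrid <- seq(0, t_end, by = dt)
  ca_t <- if (is.null(ca)) calcium_transient(tgrid, p) else rep(ca, n + 1)
  A <- F <- numeric(n + 1)
  f <- function(y, cav) {
    H <- if (cav > 0) (cav / p$Ca50)^p$nA / (1 + (cav / p$Ca50)^p$nA) else 0
    c((p$k_on * H * (1 - y[1]) - p$k_off * y[1]) / 1000,
      (p$fXB * y[1] * (1 - y[2]) - p$gXB * y[2]) / 1000)
  }
  y <- c(0, 0)
  for (i in seq_len(n)) {
    ca_mid <- if (is.null(ca)) calcium_transient((i - 0.5) * dt, p) else ca
    k1 <- f(y, ca_t[i])
    k2 <- f(y + dt / 2 * k1, ca_mid)
    k3 <- f(y + dt / 2 * k2, ca_mid)
    k4 <- f(y + dt * k3, ca_t[i + 1])
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    A[i + 1] <- y[1]
    F[i + 1] <- y[2]
  }
  L <- max(0, (lam - p$n0) / (1 - p$n0))
  tibble(t_ms = tgrid, Ca_uM = ca_t, A = A, F = F, Ta_kPa = p$Sa * F * L)
}
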
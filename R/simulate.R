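#' Solver settings for beat simulations
#'
#' @param dt Integration step (ms); fixed-step RK4, must divide the period.
#' @param dt_out Output sampling interval (ms); must be a multiple of `dt`.
#' @param period Pacing cycle length (ms); default 1000 ms (60 bpm).
#' @param n_beats Maximum number of beats to integrate.
#' @param ss_tol Steady-state criterion: relative end-diastolic volume change
#'   between consecutive beats below this value stops the run.
#' @return A list of class `solver_settings`.
#' @export
solver_settings <- function(dt = 0.1, dt_out = 1, period = 1000,
                            n_beats = 20, ss_tol = 1e-3) {
  if (n_beats < 1) abort("n_beats must be >= 1")
  if (dt <= 0 || dt_out < dt) abort("need 0 < dt <= dt_out")
  structure(list(dt = dt, dt_out = dt_out, period = period,
                 n_beats = as.integer(n_beats), ss_tol = ss_tol),
            class = "solver_settings")
}

# The compiled integrator implements the default cell unit; the interface in
# R/cell.R defines the contract an alternative (e.g. a richer published
# myofilament model) must satisfy, and its provenance field is checked here
# so a swapped-in unit fails loudly rather than being silently ignored.
check_cell_model <- function(cp) {
  if (!identical(cp$model, "default"))
    abort(sprintf(
      "cell model '%s' has no compiled integrator; only the 'default' unit can be simulated",
      cp$model))
  invisible(cp)
}

# shared assembly of the returned trace tibble
build_trace <- function(res, dt_out, period) {
  tr <- tibble(
    t_ms = res$t, P_kPa = res$P, V_ml = res$V, Pao_kPa = res$Pao,
    Qmv_ml_s = res$Qmv, Qao_ml_s = res$Qao, lambda = res$lambda,
    Pat_kPa = res$Pat, Pwk_kPa = res$Pwk)
  tr$phase <- lv_phases(tr$Qmv_ml_s, tr$Qao_ml_s)
  attr(tr, "converged") <- res$converged
  attr(tr, "beats_run") <- res$beats_run
  attr(tr, "edv_history") <- res$edv_history
  attr(tr, "period_ms") <- period
  if (!is.null(res$Vsub)) attr(tr, "V_sub") <- res$Vsub
  attr(tr, "partition_residual") <- res$partition_residual
  class(tr) <- c("lv_trace", class(tr))
  tr
}

#' Simulate paced beats of the single-element low-order ventricle
#'
#' Integrates the coupled system (cell states, cavity volume, Windkessel and
#' atrial pressures) with fixed-step RK4; ventricular pressure is eliminated
#' algebraically through the passive law and the tension-to-pressure
#' transform. The run stops early once the end-diastolic volume is
#' beat-to-beat stable (steady state); the returned trace is the final beat.
#' The result is bitwise deterministic for identical inputs and settings.
#'
#' @param lp An [lo_params()] object.
#' @param cp A [cell_params()] object.
#' @param hp A [circ_params()] object.
#' @param solver A [solver_settings()] object.
#' @return A tibble of class `lv_trace` with columns `t_ms`, `P_kPa`, `V_ml`,
#'   `Pao_kPa`, `Qmv_ml_s`, `Qao_ml_s`, `lambda`, `Pat_kPa`, `Pwk_kPa`,
#'   `phase`, and attributes `converged`, `beats_run`, `edv_history`.
#' @export
simulate_beats <- function(lp, cp, hp, solver = solver_settings()) {
  stopifnot(inherits(lp, "lo_params"), inherits(cp, "cell_params"),
            inherits(hp, "circ_params"), inherits(solver, "solver_settings"))
  check_cell_model(cp)
  res <- sim_lv_cpp(
    0L, lp$mu1, 1.0,
    lp$mu1, lp$mu2, lp$gamma, lp$alpha, lp$beta, lp$a, lp$b, lp$c, lp$V0,
    cp$fXB, cp$gXB, cp$n0, cp$nA, cp$Sa, cp$tau1, cp$tau2, cp$Ca_d,
    cp$Ca_amp, cp$Ca50, cp$k_on, cp$k_off, cp$t_act,
    hp$Pat0, hp$atrium_mode == "capacitor", hp$Cat, hp$Rmv, hp$R1, hp$R2,
    hp$R3, hp$Cwk,
    solver$period, solver$n_beats, solver$dt, solver$dt_out, solver$ss_tol,
    FALSE, FALSE)
  build_trace(res, solver$dt_out, solver$period)
}

#' Multi-element model configuration
#'
#' Parallel subunits share the cavity volume but carry their own
#' volume-to-stretch scale mu1(xi), varying linearly over `mu1_range`;
#' series subunits share the pressure and contribute volume subportions,
#' with the coefficients `{alpha, a, b, c, mu2}` scaled by a weight w(xi)
#' varying linearly over `w_range` (beta optionally included via
#' `weight_beta`). The xi in `[0, 1]` grid is the midpoint discretization
#' into `n_sub` equal cells.
#'
#' @param mode `"parallel"` or `"series"`.
#' @param n_sub Number of subunits (>= 2; default 256).
#' @param mu1_range Endpoints `[mu1(0), mu1(1)]` for parallel heterogeneity.
#' @param w_range Endpoints `[w(0), w(1)]` for series heterogeneity.
#' @param base An [lo_params()] object shared by the subunits.
#' @param cell A [cell_params()] object shared by the subunits.
#' @param weight_beta Whether the series weights also scale beta (default
#'   FALSE: only `{alpha, a, b, c, mu2}` are weighted).
#' @return A list of class `multi_config`.
#' @export
multi_config <- function(mode = c("parallel", "series"), n_sub = 256,
                         mu1_range = c(0.01, 0.179), w_range = c(0.6, 1.0),
                         base = lo_params_normal(), cell = cell_params(),
                         weight_beta = FALSE) {
  mode <- match.arg(mode)
  if (n_sub < 2) abort("n_sub must be >= 2")
  rng <- if (mode == "parallel") mu1_range else w_range
  if (length(rng) != 2 || any(rng <= 0))
    abort("heterogeneity range endpoints must be positive")
  stopifnot(inherits(base, "lo_params"), inherits(cell, "cell_params"))
  structure(list(mode = mode, n_sub = as.integer(n_sub),
                 mu1_range = mu1_range, w_range = w_range, base = base,
                 cell = cell, weight_beta = weight_beta),
            class = "multi_config")
}

# midpoint xi grid mapped linearly onto the heterogeneity range
subunit_grid <- function(cfg) {
  xi <- (seq_len(cfg$n_sub) - 0.5) / cfg$n_sub
  rng <- if (cfg$mode == "parallel") cfg$mu1_range else cfg$w_range
  rng[1] + xi * (rng[2] - rng[1])
}

#' Simulate a multi-element (parallel or series) low-order model
#'
#' @param cfg A [multi_config()] object.
#' @param hp A [circ_params()] object.
#' @param solver A [solver_settings()] object.
#' @param return_subunits If TRUE, attach the per-subunit volume trace of the
#'   final beat (series mode) as attribute `V_sub`.
#' @return A tibble of class `lv_trace` (see [simulate_beats()]).
#' @export
simulate_multi <- function(cfg, hp, solver = solver_settings(),
                           return_subunits = FALSE) {
  stopifnot(inherits(cfg, "multi_config"), inherits(hp, "circ_params"),
            inherits(solver, "solver_settings"))
  check_cell_model(cfg$cell)
  lp <- cfg$base
  cp <- cfg$cell
  grid <- subunit_grid(cfg)
  if (cfg$mode == "parallel") {
    mu1_sub <- grid
    w_sub <- rep(1, cfg$n_sub)
    mode <- 0L
  } else {
    mu1_sub <- rep(lp$mu1, cfg$n_sub)
    w_sub <- grid
    mode <- 1L
  }
  res <- sim_lv_cpp(
    mode, mu1_sub, w_sub,
    lp$mu1, lp$mu2, lp$gamma, lp$alpha, lp$beta, lp$a, lp$b, lp$c, lp$V0,
    cp$fXB, cp$gXB, cp$n0, cp$nA, cp$Sa, cp$tau1, cp$tau2, cp$Ca_d,
    cp$Ca_amp, cp$Ca50, cp$k_on, cp$k_off, cp$t_act,
    hp$Pat0, hp$atrium_mode == "capacitor", hp$Cat, hp$Rmv, hp$R1, hp$R2,
    hp$R3, hp$Cwk,
    solver$period, solver$n_beats, solver$dt, solver$dt_out, solver$ss_tol,
    isTRUE(cfg$weight_beta), return_subunits)
  build_trace(res, solver$dt_out, solver$period)
}

#' Partition a total volume across series subunits at a common pressure
#'
#' Solves, for given subunit states, the algebraic constraint of the series
#' configuration: a common pressure P and subunit volumes `V_i` with
#' `Ppass_i(V_i) + mu2_i * Ta_i(V_i) = P` for every subunit and the
#' xi-average of `V_i` equal to `V_total`. Solved by a damped Newton
#' iteration on P with per-subunit monotone inversions, to a pressure
#' residual below 1e-9 kPa.
#'
#' @param V_total Total cavity volume (ml).
#' @param F_sub Bound crossbridge fraction per subunit (recycled to
#'   `n_sub`).
#' @param cfg A [multi_config()] object with `mode = "series"`.
#' @param V_guess Optional warm-start subunit volumes.
#' @return A list with the common pressure `P` (kPa), subunit volumes
#'   `V_sub` (ml), and the worst per-subunit pressure `residual` (kPa).
#' @export
partition_volumes <- function(V_total, F_sub, cfg, V_guess = NULL) {
  stopifnot(inherits(cfg, "multi_config"))
  if (cfg$mode != "series") abort("partitioning applies to series mode only")
  lp <- cfg$base
  cp <- cfg$cell
  w <- subunit_grid(cfg)
  F_sub <- rep_len(F_sub, cfg$n_sub)
  if (is.null(V_guess)) V_guess <- rep(V_total, cfg$n_sub)
  res <- partition_cpp(V_total, F_sub, w, lp$mu1, lp$mu2, lp$gamma, lp$alpha,
                       lp$beta, lp$a, lp$b, lp$c, lp$V0, cp$n0, cp$Sa,
                       isTRUE(cfg$weight_beta), V_guess,
                       passive_pressure(V_total, lp))
  if (res$residual > 1e-9)
    abort(sprintf(
      "series partition did not converge (pressure residual %.3e kPa)",
      res$residual))
  if (abs(mean(res$V_sub) - V_total) > 1e-9)
    abort("series partition did not conserve volume")
  res
}
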
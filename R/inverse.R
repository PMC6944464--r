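#' Clinical contraction-index targets
#'
#' The four global indices the inverse problem matches: ejection fraction,
#' ejection time, isovolumic relaxation time and aortic pulse pressure,
#' plus the admissible central aortic pressure band whose violation is
#' penalized.
#'
#' @param EF_pct Target ejection fraction (%).
#' @param t_ej_ms Target ejection time (ms).
#' @param t_ivr_ms Target isovolumic relaxation time (ms).
#' @param PP_ao_mmHg Target aortic pulse pressure (mmHg).
#' @param band Admissible aortic pressure range `c(low, high)` (mmHg).
#' @return A list of class `clinical_targets`.
#' @export
clinical_targets <- function(EF_pct, t_ej_ms, t_ivr_ms, PP_ao_mmHg,
                             band = c(85, 110)) {
  vals <- c(EF_pct, t_ej_ms, t_ivr_ms, PP_ao_mmHg)
  if (any(!is.finite(vals)) || any(vals <= 0))
    abort("all clinical targets must be positive finite numbers")
  if (band[1] >= band[2]) abort("pressure band must have low < high")
  structure(list(EF_pct = EF_pct, t_ej_ms = t_ej_ms, t_ivr_ms = t_ivr_ms,
                 PP_ao_mmHg = PP_ao_mmHg, band = band),
            class = "clinical_targets")
}

inverse_param_names <- c("tau2", "Sa", "R2", "R3", "Cwk", "Cat")

#' Default inverse-problem parameter bounds
#'
#' Bounds bracketing the training hemodynamics and physiological ranges:
#' tau2 in ms, Sa in kPa, resistances in kPa ml^-1 s, capacitances in
#' ml/kPa.
#'
#' @param cell Baseline [cell_params()]; the Sa bounds scale its value by
#'   0.2x-2x.
#' @return Named list of `c(lower, upper)` bounds.
#' @export
inverse_bounds <- function(cell = cell_params()) {
  list(tau2 = c(75, 400), Sa = cell$Sa * c(0.2, 2.0), R2 = c(0, 0.05),
       R3 = c(0.02, 0.4), Cwk = c(2, 20), Cat = c(5, 100))
}

apply_inverse_params <- function(par, cell, circ) {
  cell$tau2 <- par[["tau2"]]
  cell$Sa <- par[["Sa"]]
  circ$R2 <- par[["R2"]]
  circ$R3 <- par[["R3"]]
  circ$Cwk <- par[["Cwk"]]
  circ$Cat <- par[["Cat"]]
  circ$atrium_mode <- "capacitor"
  circ$R1 <- 0.0015  # held fixed, as during congruency training
  list(cell = cell, circ = circ)
}

simulate_candidate <- function(par, lo, cell, circ, solver) {
  mod <- apply_inverse_params(par, cell, circ)
  simulate_beats(lo, mod$cell, mod$circ, solver)
}

#' Inverse-problem objective: mismatch to clinical indices
#'
#' Simulates a candidate parameter set `{tau2, Sa, R2, R3, Cwk, Cat}` to
#' steady state (capacitor atrium, R1 fixed at 0.0015 kPa ml^-1 s) and
#' scores the mean of squared relative errors on the four targets plus a
#' hinge penalty on the beat's aortic pressure extremes outside the
#' admissible band:
#' `w_pen * (max(0, (Pao_max - hi)/hi)^2 + max(0, (lo - Pao_min)/lo)^2)`.
#' Diastolic filling metrics are excluded by construction. A failed
#' simulation returns a large finite sentinel so derivative-free optimizers
#' can continue.
#'
#' @param par Named vector with `tau2`, `Sa`, `R2`, `R3`, `Cwk`, `Cat`.
#' @param targets A [clinical_targets()] object.
#' @param lo An [lo_params()] object (trained coefficients, held fixed).
#' @param cell Baseline [cell_params()].
#' @param circ Baseline [circ_params()].
#' @param w_pen Penalty weight (default 10).
#' @param solver A [solver_settings()] object.
#' @return Scalar objective (>= 0).
#' @export
clinical_objective <- function(par, targets, lo, cell, circ, w_pen = 10,
                               solver = solver_settings()) {
  stopifnot(inherits(targets, "clinical_targets"))
  tr <- tryCatch(simulate_candidate(par, lo, cell, circ, solver),
                 error = function(e) NULL)
  if (is.null(tr)) return(1e6)
  m <- tryCatch(beat_metrics(tr), error = function(e) NULL)
  if (is.null(m)) return(1e6)
  mism <- target_mismatches(m, targets)
  pen <- aortic_band_penalty(tr, targets$band, w_pen)
  mean(mism^2) + pen
}

target_mismatches <- function(m, targets) {
  c(EF = (m$EF_pct - targets$EF_pct) / targets$EF_pct,
    t_ej = (m$t_ej_ms - targets$t_ej_ms) / targets$t_ej_ms,
    t_ivr = (m$t_ivr_ms - targets$t_ivr_ms) / targets$t_ivr_ms,
    PP_ao = (m$PP_ao_mmHg - targets$PP_ao_mmHg) / targets$PP_ao_mmHg)
}

aortic_band_penalty <- function(trace, band, w_pen) {
  pao <- kpa_to_mmhg(trace$Pao_kPa)
  over <- max(0, (max(pao) - band[2]) / band[2])
  under <- max(0, (band[1] - min(pao)) / band[1])
  w_pen * (over^2 + under^2)
}

#' Fit cell and hemodynamic parameters to clinical indices
#'
#' Derivative-free minimization of [clinical_objective()] over
#' `{tau2, Sa, R2, R3, Cwk, Cat}` via [mads_minimize()].
#'
#' @param targets A [clinical_targets()] object.
#' @param lo Trained [lo_params()].
#' @param cell Baseline [cell_params()].
#' @param circ Baseline [circ_params()].
#' @param bounds Named list of bounds as from [inverse_bounds()].
#' @param seed Integer seed.
#' @param budget Evaluation budget (>= 50).
#' @param w_pen Aortic-band penalty weight.
#' @param solver A [solver_settings()] object.
#' @param x0 Optional named start point.
#' @return A list of class `lv_inverse_fit` with `par`, `mismatches`
#'   (per-target relative errors), `avg_mismatch_pct`, `achieved_3pct`,
#'   `penalty`, `metrics`, `trace` (best beat) and `optimizer` diagnostics.
#' @export
fit_clinical <- function(targets, lo, cell, circ,
                         bounds = inverse_bounds(cell), seed = 1L,
                         budget = 300, w_pen = 10,
                         solver = solver_settings(), x0 = NULL) {
  if (budget < 50) abort("budget must be at least 50 evaluations")
  lower <- vapply(inverse_param_names, function(f) bounds[[f]][1], 1)
  upper <- vapply(inverse_param_names, function(f) bounds[[f]][2], 1)
  obj <- function(x) {
    clinical_objective(setNames(x, inverse_param_names), targets, lo, cell,
                       circ, w_pen, solver)
  }
  opt <- mads_minimize(obj, lower, upper, seed = seed, budget = budget,
                       x0 = if (is.null(x0)) NULL else x0[inverse_param_names])
  par <- setNames(opt$par, inverse_param_names)
  tr <- simulate_candidate(par, lo, cell, circ, solver)
  m <- beat_metrics(tr)
  mism <- abs(target_mismatches(m, targets))
  structure(list(
    par = par, mismatches = mism,
    avg_mismatch_pct = 100 * mean(mism),
    achieved_3pct = mean(mism) <= 0.03,
    penalty = aortic_band_penalty(tr, targets$band, w_pen),
    objective = opt$value, metrics = m, trace = tr,
    optimizer = list(evaluations = opt$evaluations,
                     converged = opt$converged, seed = opt$seed,
                     history = opt$history)), class = "lv_inverse_fit")
}
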
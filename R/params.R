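#' Myofilament cell-unit parameters
#'
#' Parameters of the default biophysical cell unit: a biexponential calcium
#' transient drives a Hill-type activation gate, which in turn recruits
#' crossbridges whose bound fraction sets active tension through a linear
#' length-dependence factor. All rates are per second, times in ms,
#' concentrations in micromolar, tension scale in kPa.
#'
#' @param fXB Crossbridge attachment rate (1/s).
#' @param gXB Crossbridge detachment rate (1/s).
#' @param n0 Minimum stretch for active force generation (dimensionless,
#'   0 < n0 < 1).
#' @param nA Hill cooperativity coefficient of the calcium-activation curve
#'   (dimensionless, >= 1).
#' @param Sa Contraction-efficiency scale: tension (kPa) per unit bound
#'   crossbridge fraction at unit length factor.
#' @param tau1 Calcium rise time constant (ms).
#' @param tau2 Calcium decay time constant (ms); must exceed `tau1`.
#' @param Ca_d Diastolic calcium (uM).
#' @param Ca_amp Calcium transient amplitude above diastolic (uM).
#' @param Ca50 Half-activation calcium (uM).
#' @param k_on,k_off Activation gate on/off rates (1/s).
#' @param t_act Activation onset time within the beat (ms).
#' @param model Provenance of the rate laws; `"default"` is the documented
#'   built-in cell unit.
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(fXB = 25, gXB = 15, n0 = 0.6, nA = 5, Sa = 95,
                        tau1 = 30, tau2 = 150, Ca_d = 0.1, Ca_amp = 1.0,
                        Ca50 = 0.5, k_on = 40, k_off = 20, t_act = 0,
                        model = "default") {
  p <- list(fXB = fXB, gXB = gXB, n0 = n0, nA = nA, Sa = Sa, tau1 = tau1,
            tau2 = tau2, Ca_d = Ca_d, Ca_amp = Ca_amp, Ca50 = Ca50,
            k_on = k_on, k_off = k_off, t_act = t_act, model = model)
  validate_cell_params(p)
  structure(p, class = "cell_params")
}

validate_cell_params <- function(p) {
  num <- c("fXB", "gXB", "n0", "nA", "Sa", "tau1", "tau2", "Ca_d", "Ca_amp",
           "Ca50", "k_on", "k_off", "t_act")
  for (f in num) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]))
      abort(sprintf("cell parameter '%s' must be a finite number", f))
  }
  for (f in c("fXB", "gXB", "tau1", "tau2", "Ca50", "k_on", "k_off"))
    if (p[[f]] <= 0) abort(sprintf("cell parameter '%s' must be positive", f))
  if (p$tau2 <= p$tau1)
    abort("invalid calcium time constants: tau2 must exceed tau1")
  if (p$n0 <= 0 || p$n0 >= 1)
    abort("n0 must lie strictly between 0 and 1")
  if (p$nA < 1) abort("nA must be >= 1")
  if (p$Sa < 0) abort("Sa must be >= 0")
  if (p$Ca_d < 0 || p$Ca_amp < 0) abort("calcium levels must be >= 0")
  invisible(p)
}

#' Scale the maximum shortening velocity of the cell unit
#'
#' Vmax is represented implicitly through the crossbridge cycling rates:
#' scaling `fXB` and `gXB` together by `sv` speeds up (sv > 1) or slows down
#' (sv < 1) contraction while leaving the isometric steady tension unchanged
#' (it depends on the fXB/gXB ratio only).
#'
#' @param p A [cell_params()] object.
#' @param sv Positive scaling factor.
#' @return A `cell_params` object with scaled rates.
#' @export
scale_vmax <- function(p, sv) {
  stopifnot(inherits(p, "cell_params"))
  if (!is.numeric(sv) || length(sv) != 1 || !is.finite(sv) || sv <= 0)
    abort("sv must be a positive finite scalar")
  p$fXB <- p$fXB * sv
  p$gXB <- p$gXB * sv
  p
}

#' Lumped circulation parameters
#'
#' Atrium (constant pressure or discharging capacitor), mitral and aortic
#' valves as ideal diodes with series resistances, and a 3-element Windkessel
#' afterload (proximal resistance R2, capacitance Cwk, distal resistance R3).
#'
#' @param Pat0 Atrial pressure (kPa); in capacitor mode, the value the atrium
#'   is recharged to at each cycle start.
#' @param atrium_mode `"constant"` or `"capacitor"`.
#' @param Cat Atrial capacitance (ml/kPa), used in capacitor mode.
#' @param Rmv Mitral valve resistance (kPa ml^-1 s).
#' @param R1 Aortic valve resistance (kPa ml^-1 s).
#' @param R2 Proximal aortic resistance (kPa ml^-1 s); may be 0.
#' @param R3 Distal arterial resistance (kPa ml^-1 s).
#' @param Cwk Windkessel capacitance (ml/kPa).
#' @return An object of class `circ_params`.
#' @export
circ_params <- function(Pat0 = 0.66, atrium_mode = c("constant", "capacitor"),
                        Cat = 25, Rmv = 0.0015, R1 = 0.0015, R2 = 0,
                        R3 = 0.20, Cwk = 8.0) {
  atrium_mode <- match.arg(atrium_mode)
  p <- list(Pat0 = Pat0, atrium_mode = atrium_mode, Cat = Cat, Rmv = Rmv,
            R1 = R1, R2 = R2, R3 = R3, Cwk = Cwk)
  for (f in c("Pat0", "Cat", "Rmv", "R1", "R2", "R3", "Cwk"))
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]))
      abort(sprintf("circulation parameter '%s' must be a finite number", f))
  if (p$R1 <= 0 || p$R3 <= 0) abort("R1 and R3 must be positive")
  if (p$Rmv <= 0) abort("Rmv must be positive")
  if (p$R2 < 0) abort("R2 must be >= 0")
  if (p$Cwk <= 0) abort("Cwk must be positive")
  if (atrium_mode == "capacitor" && p$Cat <= 0)
    abort("Cat must be positive in capacitor mode")
  structure(p, class = "circ_params")
}

#' Named circulation presets for training simulations
#'
#' The three active training conditions ("A1", "A2", "A3") pair a common
#' aortic-valve resistance with different atrial pressures and distal
#' resistances (kPa-ml-s units): A1 (Pat 0.33, R3 0.20, C 8.0),
#' A2 (Pat 0.66, R3 0.05, C 8.0), A3 (Pat 1.5, R3 0.20, C 8.0).
#' The passive preset "P" is a quasi-static inflation over 0-4 kPa and has no
#' hemodynamic parameters; requesting it returns the inflation pressure grid.
#'
#' @param name One of `"P"`, `"A1"`, `"A2"`, `"A3"`.
#' @param Pat Optional override of the atrial pressure (kPa), used e.g. when
#'   re-training against multi-element references at atrial pressures
#'   0.3 / 0.6 / 1.0 kPa.
#' @return A [circ_params()] object, or for `"P"` a numeric vector of
#'   inflation pressures (kPa).
#' @export
circ_preset <- function(name = c("A1", "A2", "A3", "P"), Pat = NULL) {
  name <- match.arg(name)
  if (name == "P") return(seq(0, 4, by = 0.25))
  p <- switch(name,
    A1 = circ_params(Pat0 = 0.33, R1 = 0.0015, R2 = 0, R3 = 0.20, Cwk = 8.0),
    A2 = circ_params(Pat0 = 0.66, R1 = 0.0015, R2 = 0, R3 = 0.05, Cwk = 8.0),
    A3 = circ_params(Pat0 = 1.5,  R1 = 0.0015, R2 = 0, R3 = 0.20, Cwk = 8.0))
  if (!is.null(Pat)) p$Pat0 <- Pat
  p
}

#' Low-order ventricle parameters
#'
#' The 8 trained coefficients of the low-order ventricle plus the unloaded
#' cavity volume V0. `mu1` maps relative volume to myofilament stretch,
#' `mu2` maps active tension to pressure; `alpha`, `beta`, `gamma` shape the
#' exponential compression branch of the passive law and `a`, `b`, `c` its
#' cubic tension branch.
#'
#' @param mu1 Volume-to-stretch scale (dimensionless, > 0; 0 accepted as the
#'   degenerate decoupled case).
#' @param mu2 Tension-to-pressure scale (dimensionless, > 0).
#' @param gamma Compression-branch shape factor (accepted range (0, 20]).
#' @param alpha Compression-branch pressure scale (kPa, > 0).
#' @param beta Compression-branch exponent factor (dimensionless, > 0).
#' @param a,b,c Tension-branch cubic coefficients (kPa); `c > 0` so the
#'   passive curve has positive slope at V0.
#' @param V0 Unloaded cavity volume (ml, > 0).
#' @return An object of class `lo_params`.
#' @export
lo_params <- function(mu1 = 0.191, mu2 = 0.183, gamma = 4.97, alpha = 0.640,
                      beta = 1.39, a = 1.70, b = -1.41, c = 1.64, V0 = 100) {
  p <- list(mu1 = mu1, mu2 = mu2, gamma = gamma, alpha = alpha, beta = beta,
            a = a, b = b, c = c, V0 = V0)
  for (f in names(p))
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]))
      abort(sprintf("low-order parameter '%s' must be a finite number", f))
  if (p$V0 <= 0) abort("V0 must be positive")
  if (p$mu1 < 0) abort("mu1 must be >= 0")
  if (p$mu2 <= 0) abort("mu2 must be positive")
  if (p$gamma <= 0 || p$gamma > 20)
    abort("gamma must lie in (0, 20]")
  if (p$alpha <= 0 || p$beta <= 0) abort("alpha and beta must be positive")
  if (p$c <= 0) abort("c must be positive")
  structure(p, class = "lo_params")
}

#' Trained coefficient sets shipped with the package
#'
#' Best-fit low-order coefficients for the two reference ventricular
#' geometries (a normal and a heart-failure case), used throughout the
#' package as realistic defaults and as the base parameters of the
#' multi-element reference generator.
#'
#' @param V0 Unloaded cavity volume (ml); not part of the trained set, so it
#'   must be supplied (default 100 ml, a physiological normal value).
#' @return An [lo_params()] object.
#' @export
lo_params_normal <- function(V0 = 100) {
  lo_params(mu1 = 0.191, mu2 = 0.183, gamma = 4.97, alpha = 0.640,
            beta = 1.39, a = 1.70, b = -1.41, c = 1.64, V0 = V0)
}

#' @rdname lo_params_normal
#' @export
lo_params_failing <- function(V0 = 120) {
  lo_params(mu1 = 0.190, mu2 = 0.173, gamma = 5.17, alpha = 0.571,
            beta = 1.47, a = 1.77, b = -1.47, c = 1.61, V0 = V0)
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params> (", x$model, " myofilament unit)\n", sep = "")
  flds <- setdiff(names(x), "model")
  cat(paste0("  ", flds, " = ", vapply(flds, function(f) format(x[[f]]), "")),
      sep = "\n")
  invisible(x)
}

#' @export
print.lo_params <- function(x, ...) {
  cat("<lo_params>\n")
  cat(paste0("  ", names(x), " = ", vapply(names(x), function(f)
    format(x[[f]]), "")), sep = "\n")
  invisible(x)
}

#' @export
print.circ_params <- function(x, ...) {
  cat("<circ_params> (", x$atrium_mode, " atrium)\n", sep = "")
  flds <- setdiff(names(x), "atrium_mode")
  cat(paste0("  ", flds, " = ", vapply(flds, function(f) format(x[[f]]), "")),
      sep = "\n")
  invisible(x)
}
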
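#' Passive pressure-volume law
#'
#' Two-branch empirical law about the unloaded volume V0, continuous (value 0)
#' at the junction. With x = V/V0 - 1:
#' compression (V <= V0): `P = alpha * (1 - exp(-beta * gamma * x))`;
#' tension (V > V0): `P = a x^3 + b x^2 + c x`.
#'
#' @param V Cavity volume (ml, > 0); vectorized.
#' @param lp An [lo_params()] object.
#' @param gamma Optional override of the compression shape factor (the
#'   passive fit holds it at 1).
#' @return Passive pressure (kPa).
#' @export
passive_pressure <- function(V, lp, gamma = NULL) {
  stopifnot(inherits(lp, "lo_params"))
  if (any(!is.finite(V)) || any(V <= 0)) abort("volume must be positive")
  g <- if (is.null(gamma)) lp$gamma else gamma
  x <- V / lp$V0 - 1
  ifelse(x <= 0,
         lp$alpha * (1 - exp(-lp$beta * g * x)),
         ((lp$a * x + lp$b) * x + lp$c) * x)
}

#' Invert the passive law: volume at a given passive pressure
#'
#' The compression branch inverts in closed form; the tension branch is
#' solved by safeguarded root finding on the cubic (unique root for the
#' fitted, monotone parameter sets).
#'
#' @param p Passive pressure (kPa); vectorized.
#' @param lp An [lo_params()] object.
#' @param gamma Optional override of the compression shape factor.
#' @return Cavity volume (ml).
#' @export
passive_volume <- function(p, lp, gamma = NULL) {
  stopifnot(inherits(lp, "lo_params"))
  g <- if (is.null(gamma)) lp$gamma else gamma
  vapply(p, function(pi) {
    if (pi == 0) return(lp$V0)
    if (pi < 0) {
      x <- -log(1 - pi / lp$alpha) / (lp$beta * g)
      return(lp$V0 * (1 + x))
    }
    f <- function(x) ((lp$a * x + lp$b) * x + lp$c) * x - pi
    hi <- 1
    guard <- 0
    while (f(hi) < 0 && guard < 60) { hi <- hi * 1.5; guard <- guard + 1 }
    if (f(hi) < 0) abort("passive law cannot reach the requested pressure")
    x <- uniroot(f, c(0, hi), tol = 1e-13)$root
    lp$V0 * (1 + x)
  }, numeric(1))
}

#' Stretch from volume (cell-to-organ strain transform)
#'
#' `lambda = mu1 * (V/V0 - 1) + 1`; strictly increasing in V for mu1 > 0 and
#' identically 1 in the degenerate decoupled case mu1 = 0.
#'
#' @param V Cavity volume (ml, > 0); vectorized.
#' @param lp An [lo_params()] object.
#' @return Myofilament stretch (dimensionless).
#' @export
stretch_from_volume <- function(V, lp) {
  stopifnot(inherits(lp, "lo_params"))
  if (any(!is.finite(V)) || any(V <= 0)) abort("volume must be positive")
  lp$mu1 * (V / lp$V0 - 1) + 1
}

#' Ventricular pressure from active tension and volume
#'
#' `P = mu2 * Ta + Ppass(V)` (tension-to-pressure transform plus the passive
#' law).
#'
#' @param Ta Active tension (kPa, >= 0); vectorized.
#' @param V Cavity volume (ml, > 0).
#' @param lp An [lo_params()] object.
#' @return Left-ventricular pressure (kPa).
#' @export
ventricular_pressure <- function(Ta, V, lp) {
  stopifnot(inherits(lp, "lo_params"))
  if (any(Ta < 0)) abort("active tension must be >= 0")
  lp$mu2 * Ta + passive_pressure(V, lp)
}

#' Quasi-static passive inflation curve
#'
#' Generates the passive pressure-volume relation of a single-element or
#' multi-element model over a pressure grid (the passive training protocol).
#' For the series configuration each subunit's weighted law is inverted and
#' the subunit volumes averaged; parallel subunits share the passive law of
#' the base parameters.
#'
#' @param x An [lo_params()] or [multi_config()] object.
#' @param pressures Pressure grid (kPa); the default extends slightly below
#'   zero so the compression branch is exercised.
#' @return A tibble with `p_kPa` and `V_ml`.
#' @export
passive_inflation <- function(x, pressures = seq(-0.5, 4, by = 0.25)) {
  if (inherits(x, "lo_params")) {
    return(tibble(p_kPa = pressures, V_ml = passive_volume(pressures, x)))
  }
  stopifnot(inherits(x, "multi_config"))
  lp <- x$base
  if (x$mode == "parallel") {
    return(tibble(p_kPa = pressures, V_ml = passive_volume(pressures, lp)))
  }
  w <- subunit_grid(x)
  V <- vapply(pressures, function(p) {
    vi <- vapply(w, function(wi) {
      lpw <- lp
      lpw$alpha <- lp$alpha * wi
      lpw$a <- lp$a * wi
      lpw$b <- lp$b * wi
      lpw$c <- lp$c * wi
      if (isTRUE(x$weight_beta)) lpw$beta <- lp$beta * wi
      passive_volume(p, lpw)
    }, numeric(1))
    mean(vi)
  }, numeric(1))
  tibble(p_kPa = pressures, V_ml = V)
}
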
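#' Congruency error between reference and low-order traces
#'
#' Normalized L2 mismatch of volume and pressure traces over one beat:
#' for each training protocol i,
#' `Vterm_i = int (V_ref - V_lo)^2 dt / int V_ref^2 dt` and analogously
#' `Pterm_i`; the congruency error is
#' `C = sqrt(mean_i (Vterm_i + Pterm_i))` with trapezoidal quadrature.
#' Traces must already share a common uniform time grid (no silent
#' resampling); normalization is by the reference only, so the functional is
#' asymmetric in its arguments.
#'
#' @param ref_traces,lo_traces A single trace or a list of paired traces,
#'   each a tibble with `t_ms`, `P_kPa`, `V_ml`.
#' @param detail If TRUE, also return the per-protocol term decomposition.
#' @return The scalar congruency error C (>= 0), or, with `detail = TRUE`, a
#'   list with `C` and a tibble of per-protocol `V_term` / `P_term` values
#'   (the terms sum to `n_protocols * C^2`).
#' @export
congruency_error <- function(ref_traces, lo_traces, detail = FALSE) {
  as_list <- function(x) if (is.data.frame(x)) list(x) else x
  ref_traces <- as_list(ref_traces)
  lo_traces <- as_list(lo_traces)
  if (length(ref_traces) != length(lo_traces))
    abort("reference and low-order trace lists differ in length")
  trapz <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
  terms <- purrr::map2(ref_traces, lo_traces, function(r, l) {
    if (nrow(r) != nrow(l) || any(r$t_ms != l$t_ms))
      abort("traces are not on a common time grid; resample before comparing")
    c(V_term = trapz(r$t_ms, (r$V_ml - l$V_ml)^2) / trapz(r$t_ms, r$V_ml^2),
      P_term = trapz(r$t_ms, (r$P_kPa - l$P_kPa)^2) / trapz(r$t_ms, r$P_kPa^2))
  })
  tt <- do.call(rbind, terms)
  C <- sqrt(mean(tt[, "V_term"] + tt[, "P_term"]))
  if (!detail) return(C)
  list(C = C,
       terms = tibble(protocol = seq_len(nrow(tt)),
                      V_term = tt[, "V_term"], P_term = tt[, "P_term"]))
}

#' Fit the passive coefficients to a reference inflation curve
#'
#' Stage one of congruency training: finds `{alpha, beta, a, b, c}`
#' minimizing the sum of squared relative volume errors
#' `sum_p ((V_ref(p) - V_lo(p)) / V_ref(p))^2`, where `V_lo(p)` inverts the
#' passive law with the compression shape factor held at gamma = 1 (gamma is
#' identified later, from active beats that actually compress the cavity).
#' Bounded Levenberg-Marquardt least squares (alpha, beta, c > 0). If the
#' reference never enters compression (all volumes above V0), `alpha` and
#' `beta` are unconstrained by the data: they are returned at their initial
#' values with a warning and flagged in the result.
#'
#' @param reference A data frame with columns `p_kPa` and `V_ml`.
#' @param V0 Unloaded volume (ml) of the low-order model being trained.
#' @param init Named initial guess for `alpha`, `beta`, `a`, `b`, `c`.
#' @return A list of class `lv_passive_fit` with elements `coefficients`
#'   (named vector), `residual` (objective value at the optimum), `fitted`
#'   (tibble of reference vs fitted volumes), `unconstrained_compression`,
#'   and `n_obs`.
#' @export
fit_passive <- function(reference, V0,
                        init = c(alpha = 0.5, beta = 1.5, a = 1.5, b = -1.0,
                                 c = 1.5)) {
  if (!all(c("p_kPa", "V_ml") %in% names(reference)))
    abort("reference must have columns p_kPa and V_ml")
  p <- reference$p_kPa
  V <- reference$V_ml
  if (any(V <= 0)) abort("reference volumes must be positive")
  if (length(unique(V)) < 2)
    abort("degenerate reference: all volumes identical")
  if (length(p) < 5) abort("need at least 5 passive samples")
  has_compression <- any(V <= V0 & p <= 0)

  vol_model <- function(theta, pp) {
    lp <- lo_params(mu1 = 0.1, mu2 = 0.1, gamma = 1, alpha = theta[["alpha"]],
                    beta = theta[["beta"]], a = theta[["a"]], b = theta[["b"]],
                    c = theta[["c"]], V0 = V0)
    passive_volume(pp, lp, gamma = 1)
  }

  safe_resid <- function(expr) {
    tryCatch(expr, error = function(e) rep(1e3, length(p)))
  }
  if (has_compression) {
    resid_fn <- function(theta) {
      th <- setNames(theta, c("alpha", "beta", "a", "b", "c"))
      safe_resid((V - vol_model(th, p)) / V)
    }
    fit <- minpack.lm::nls.lm(
      par = init[c("alpha", "beta", "a", "b", "c")], fn = resid_fn,
      lower = c(1e-6, 1e-6, -Inf, -Inf, 1e-6),
      upper = rep(Inf, 5),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14))
    coefs <- setNames(fit$par, c("alpha", "beta", "a", "b", "c"))
  } else {
    keep <- V > V0
    resid_fn <- function(theta) {
      th <- c(init[c("alpha", "beta")],
              setNames(theta, c("a", "b", "c")))
      tryCatch((V[keep] - vol_model(th, p[keep])) / V[keep],
               error = function(e) rep(1e3, sum(keep)))
    }
    fit <- minpack.lm::nls.lm(
      par = init[c("a", "b", "c")], fn = resid_fn,
      lower = c(-Inf, -Inf, 1e-6), upper = rep(Inf, 3),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14))
    coefs <- c(init[c("alpha", "beta")], setNames(fit$par, c("a", "b", "c")))
    warn(paste("reference has no compression samples: alpha and beta are",
               "unconstrained and returned at their initial values"))
  }
  V_fit <- vol_model(coefs, p)
  structure(list(
    coefficients = coefs,
    residual = sum(((V - V_fit) / V)^2),
    fitted = tibble(p_kPa = p, V_ref_ml = V, V_fit_ml = V_fit),
    unconstrained_compression = !has_compression,
    n_obs = length(p)), class = "lv_passive_fit")
}

#' Fit the active trained coefficients by congruency minimization
#'
#' Stage two of congruency training: with the passive coefficients fixed,
#' minimizes the congruency error C over `{mu1, mu2, gamma}` by
#' mesh-adaptive direct search ([mads_minimize()]). Each objective
#' evaluation simulates the single-element model to steady state under every
#' training circulation and compares the final beats to the references.
#'
#' @param ref_traces List of reference beat traces (one per training
#'   circulation), on the solver's output grid.
#' @param circs List of [circ_params()] objects matching `ref_traces`.
#' @param passive Named vector or list with `alpha`, `beta`, `a`, `b`, `c`
#'   (typically `coefficients` of a [fit_passive()] result).
#' @param V0 Unloaded volume (ml).
#' @param cell A [cell_params()] object (the shared biophysical unit).
#' @param bounds Named list of `[lower, upper]` for `mu1`, `mu2`, `gamma`.
#' @param x0 Optional start point `c(mu1, mu2, gamma)`, e.g. a homogenized
#'   guess for a heterogeneous reference; the simplex refinement is run from
#'   both the direct-search incumbent and `x0`, keeping the better optimum.
#' @param seed Seed for the direct search.
#' @param budget Objective-evaluation budget for the direct search.
#' @param polish Maximum simplex iterations of the deterministic
#'   Nelder-Mead refinement started from the direct-search incumbent
#'   (0 disables it); the search phase locates the basin, the simplex
#'   descends the narrow valley the trained coefficients live in.
#' @param solver A [solver_settings()] object used for the candidate runs.
#' @return A list of class `lv_active_fit` with `lo` (the trained
#'   [lo_params()]), `C`, `terms` (per-protocol decomposition), and
#'   `optimizer` diagnostics.
#' @export
fit_active <- function(ref_traces, circs, passive, V0, cell,
                       bounds = list(mu1 = c(0.01, 1), mu2 = c(0.01, 1),
                                     gamma = c(0.5, 20)),
                       seed = 1L, budget = 200, polish = 200, x0 = NULL,
                       solver = solver_settings()) {
  stopifnot(inherits(cell, "cell_params"))
  if (length(ref_traces) != length(circs))
    abort("need one circulation per reference trace")
  pc <- as.list(passive)
  make_lo <- function(x) {
    lo_params(mu1 = x[1], mu2 = x[2], gamma = x[3], alpha = pc$alpha,
              beta = pc$beta, a = pc$a, b = pc$b, c = pc$c, V0 = V0)
  }
  n_fail <- 0L
  objective <- function(x) {
    lp <- make_lo(x)
    tr <- tryCatch(
      purrr::map(circs, function(hp) simulate_beats(lp, cell, hp, solver)),
      error = function(e) NULL)
    if (is.null(tr)) {
      n_fail <<- n_fail + 1L
      return(1e6)
    }
    congruency_error(ref_traces, tr)
  }
  lower <- c(bounds$mu1[1], bounds$mu2[1], bounds$gamma[1])
  upper <- c(bounds$mu1[2], bounds$mu2[2], bounds$gamma[2])
  opt <- mads_minimize(objective, lower, upper, seed = seed, budget = budget,
                       x0 = x0)
  if (n_fail >= opt$evaluations)
    abort("all candidate simulations failed during active training")
  best <- opt$par
  best_val <- opt$value
  n_polish <- 0L
  if (polish > 0) {
    span <- upper - lower
    obj_u <- function(u) objective(pmin(pmax(u, 0), 1) * span + lower)
    starts <- list(best)
    if (!is.null(x0)) starts <- c(starts, list(pmin(pmax(x0, lower), upper)))
    for (st in starts) {
      nm <- optim((st - lower) / span, obj_u, method = "Nelder-Mead",
                  control = list(maxit = polish, reltol = 1e-12))
      n_polish <- n_polish + unname(nm$counts[1])
      if (is.finite(nm$value) && nm$value < best_val) {
        best <- pmin(pmax(nm$par, 0), 1) * span + lower
        best_val <- nm$value
      }
    }
  }
  lo <- make_lo(best)
  lo_traces <- purrr::map(circs, function(hp)
    simulate_beats(lo, cell, hp, solver))
  det <- congruency_error(ref_traces, lo_traces, detail = TRUE)
  structure(list(
    lo = lo, C = det$C, terms = det$terms,
    mu = setNames(best, c("mu1", "mu2", "gamma")),
    optimizer = list(evaluations = opt$evaluations,
                     polish_evaluations = n_polish,
                     converged = opt$converged, seed = opt$seed,
                     history = opt$history, failures = n_fail)),
    class = "lv_active_fit")
}
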
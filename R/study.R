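#' Single-element approximation error of multi-element references
#'
#' Reproduces the single- vs multi-element error study: a heterogeneous
#' multi-element reference (parallel: mu1 varying linearly over
#' `mu1_range`; series: weights over `w_range`) is simulated under three
#' active training circulations (the named presets' resistances and
#' capacitance with atrial pressures 0.3 / 0.6 / 1.0 kPa), a single-element
#' model is congruency-trained against it (passive inflation fit followed by
#' the active fit of the congruency error), and the trained model is then
#' re-evaluated — without further tuning — across a sweep of a shared
#' biophysical parameter: the maximum shortening velocity (`sweep = "vmax"`,
#' scaling fXB and gXB together) or the calcium decay time
#' (`sweep = "tau2"`).
#'
#' @param mode `"parallel"` or `"series"`.
#' @param sweep `"vmax"` or `"tau2"`.
#' @param factors Sweep grid; defaults to the study grids (Vmax scale
#'   factors 4.0 down to 0.25, tau2 scale factors 1.1-2.0).
#' @param base Base [lo_params()] of the reference (default: the trained
#'   normal-geometry set).
#' @param cell Shared [cell_params()].
#' @param n_sub Subunits in the reference (default 256).
#' @param mu1_range,w_range Heterogeneity ranges.
#' @param pat Atrial pressures (kPa) of the three training circulations.
#' @param seed Seed for the active-fit direct search.
#' @param budget,polish Active-fit search budget and simplex refinement.
#' @param solver A [solver_settings()] object.
#' @return A list of class `lv_error_study`: `errors` (tibble of sweep
#'   `factor` and congruency error `C` and `C_x100`), `fit` (the
#'   [fit_active()] result at baseline), `mode`, `sweep`.
#' @export
multi_element_error_study <- function(
    mode = c("parallel", "series"), sweep = c("vmax", "tau2"),
    factors = NULL, base = lo_params_normal(), cell = cell_params(),
    n_sub = 256, mu1_range = c(0.01, 0.179), w_range = c(0.6, 1.0),
    pat = c(0.3, 0.6, 1.0), seed = 1L, budget = 400, polish = 200,
    solver = solver_settings()) {
  mode <- match.arg(mode)
  sweep <- match.arg(sweep)
  if (is.null(factors)) {
    factors <- if (sweep == "vmax")
      c(1.00, 1.75, 2.50, 3.25, 4.00, 0.62, 0.45, 0.36, 0.29, 0.25)
    else seq(1.1, 2.0, by = 0.1)
  }
  presets <- c("A1", "A2", "A3")
  circs <- purrr::map2(presets, pat, function(nm, p) circ_preset(nm, Pat = p))
  cfg <- multi_config(mode, n_sub = n_sub, mu1_range = mu1_range,
                      w_range = w_range, base = base, cell = cell)
  refs <- purrr::map(circs, function(hp) simulate_multi(cfg, hp, solver))
  pfit <- fit_passive(passive_inflation(cfg), base$V0)
  # homogenized start: subunit-mean transforms, and the compression shape
  # that preserves the generator's beta*gamma product through the fitted beta
  x0 <- if (mode == "parallel") {
    c(mean(mu1_range), base$mu2,
      base$beta * base$gamma / pfit$coefficients[["beta"]])
  } else {
    c(base$mu1, mean(w_range) * base$mu2,
      base$beta * base$gamma / pfit$coefficients[["beta"]])
  }
  afit <- fit_active(refs, circs, pfit$coefficients, base$V0, cell,
                     seed = seed, budget = budget, polish = polish, x0 = x0,
                     solver = solver)
  vary_cell <- function(f) {
    if (sweep == "vmax") return(scale_vmax(cell, f))
    cs <- cell
    cs$tau2 <- cell$tau2 * f
    cs
  }
  errs <- purrr::map_dbl(factors, function(f) {
    cs <- vary_cell(f)
    cfg_s <- cfg
    cfg_s$cell <- cs
    r <- purrr::map(circs, function(hp) simulate_multi(cfg_s, hp, solver))
    l <- purrr::map(circs, function(hp) simulate_beats(afit$lo, cs, hp,
                                                       solver))
    congruency_error(r, l)
  })
  structure(list(
    errors = tibble(factor = factors, C = errs, C_x100 = 100 * errs),
    fit = afit, passive_fit = pfit, mode = mode, sweep = sweep,
    seed = seed), class = "lv_error_study")
}

#' @export
tidy.lv_error_study <- function(x, ...) x$errors

#' @export
glance.lv_error_study <- function(x, ...) {
  tibble(mode = x$mode, sweep = x$sweep, max_C_x100 = max(x$errors$C_x100),
         baseline_C_x100 = 100 * x$fit$C, seed = x$seed)
}
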
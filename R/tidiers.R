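#' @export
tidy.lv_passive_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @export
glance.lv_passive_fit <- function(x, ...) {
  tibble(residual = x$residual, n_obs = x$n_obs,
         unconstrained_compression = x$unconstrained_compression)
}

#' @export
tidy.lv_active_fit <- function(x, ...) {
  tibble(term = names(x$mu), estimate = unname(x$mu))
}

#' @export
glance.lv_active_fit <- function(x, ...) {
  tibble(C = x$C, C_x100 = 100 * x$C,
         evaluations = x$optimizer$evaluations,
         converged = x$optimizer$converged, seed = x$optimizer$seed)
}

#' @export
tidy.lv_inverse_fit <- function(x, ...) {
  bind_rows(
    tibble(term = names(x$par), estimate = unname(x$par),
           kind = "parameter"),
    tibble(term = names(x$mismatches), estimate = unname(x$mismatches),
           kind = "relative_mismatch"))
}

#' @export
glance.lv_inverse_fit <- function(x, ...) {
  tibble(avg_mismatch_pct = x$avg_mismatch_pct,
         achieved_3pct = x$achieved_3pct, penalty = x$penalty,
         objective = x$objective,
         evaluations = x$optimizer$evaluations)
}

#' @export
tidy.lv_emulator <- function(x, ...) {
  bind_rows(purrr::imap(x$fits, function(f, nm) {
    if (isTRUE(f$constant)) {
      tibble(output = nm, signal_sd = 0, noise_sd = 0)
    } else {
      tibble(output = nm, signal_sd = f$y_scl * sqrt(f$sf2),
             noise_sd = f$y_scl * sqrt(f$sn2))
    }
  }))
}

#' Plot a pressure-volume loop
#'
#' @param object An `lv_trace` tibble.
#' @param ... Unused.
#' @return A ggplot object: the PV loop colored by beat phase.
#' @export
autoplot.lv_trace <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$V_ml, y = .data$P_kPa,
                               color = .data$phase)) +
    ggplot2::geom_path(ggplot2::aes(group = 1)) +
    ggplot2::labs(x = "LV volume (ml)", y = "LV pressure (kPa)",
                  color = "phase") +
    ggplot2::theme_minimal()
}

#' Plot pressure and volume traces over the beat
#'
#' @param trace An `lv_trace` tibble.
#' @return A ggplot object with pressure and volume panels.
#' @export
plot_beat <- function(trace) {
  long <- dplyr::bind_rows(
    tibble(t_ms = trace$t_ms, value = trace$P_kPa, series = "LV pressure (kPa)"),
    tibble(t_ms = trace$t_ms, value = trace$Pao_kPa, series = "Aortic pressure (kPa)"),
    tibble(t_ms = trace$t_ms, value = trace$V_ml, series = "LV volume (ml)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_ms, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}
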
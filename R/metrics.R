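# Phase detection from flow signs with a deadband; the valve flags are
# derived post hoc from the clamped flows (open iff flow above deadband).
# Isovolumic samples are labelled by the next flow phase within the cyclic
# beat: before ejection -> isovolumic contraction, before filling ->
# isovolumic relaxation. Ties at transitions resolve toward the later phase.

#' Classify beat phases from valve flows
#'
#' @param Qmv,Qao Mitral and aortic flows (ml/s).
#' @param deadband Flow deadband (ml/s) below which a valve counts as closed.
#' @return A factor with levels `filling`, `isovolumic_contraction`,
#'   `ejection`, `isovolumic_relaxation`.
#' @export
lv_phases <- function(Qmv, Qao, deadband = 1e-9) {
  n <- length(Qmv)
  mv <- Qmv > deadband
  ao <- Qao > deadband
  ph <- character(n)
  ph[ao] <- "ejection"
  ph[!ao & mv] <- "filling"
  iso <- !ao & !mv
  if (any(iso)) {
    # cyclic scan backwards from each flow phase
    nxt <- character(n)
    nxt[ao] <- "ejection"
    nxt[!ao & mv] <- "filling"
    lab <- rep(NA_character_, n)
    if (any(nzchar(nxt))) {
      idx <- which(nzchar(nxt))
      for (i in which(iso)) {
        after <- idx[idx > i]
        j <- if (length(after)) after[1] else idx[1]
        lab[i] <- if (nxt[j] == "ejection") "isovolumic_contraction"
                  else "isovolumic_relaxation"
      }
      ph[iso] <- lab[iso]
    } else {
      ph[iso] <- "isovolumic_contraction"
    }
  }
  factor(ph, levels = c("filling", "isovolumic_contraction", "ejection",
                        "isovolumic_relaxation"))
}

# first index (cyclically) where flag switches from TRUE to FALSE / FALSE to
# TRUE; returns times of events. `flag` must contain both states.
cyclic_transition <- function(t, flag, from, to) {
  n <- length(flag)
  prev <- c(flag[n], flag[-n])
  hit <- which(prev == from & flag == to)
  if (!length(hit)) return(NA_real_)
  t[hit[1]]
}

#' Beat-level contraction metrics
#'
#' Extracts end-diastolic and end-systolic volumes (at mitral and aortic
#' closure), ejection fraction, ejection time (aortic-open duration),
#' isovolumic relaxation time (aortic closure to mitral opening), peak
#' systolic pressure and aortic pulse pressure from a converged single-beat
#' trace. Valve event times are the first sample of the new valve state;
#' durations are differences of event times modulo the pacing period.
#' Pressures are reported in mmHg.
#'
#' @param trace An `lv_trace` tibble covering exactly one beat.
#' @param deadband Flow deadband (ml/s) for valve-state detection.
#' @return A one-row tibble with `EDV_ml`, `ESV_ml`, `SV_ml`, `EF_pct`,
#'   `t_ej_ms`, `t_ivr_ms`, `P_sys_peak_mmHg`, `PP_ao_mmHg`.
#' @export
beat_metrics <- function(trace, deadband = 1e-9) {
  req <- c("t_ms", "P_kPa", "V_ml", "Pao_kPa", "Qmv_ml_s", "Qao_ml_s")
  if (!all(req %in% names(trace)))
    abort("trace must carry time, pressures, volume and both valve flows")
  period <- attr(trace, "period_ms")
  if (is.null(period)) period <- max(trace$t_ms)
  # drop a duplicated cycle-end sample for cyclic bookkeeping
  tr <- trace[trace$t_ms < period, ]
  t <- tr$t_ms
  mv <- tr$Qmv_ml_s > deadband
  ao <- tr$Qao_ml_s > deadband
  if (!any(ao))
    abort("no ejection detected: beat metrics are undefined")
  if (!any(mv))
    abort("no filling detected: beat metrics are undefined")
  t_mv_close <- cyclic_transition(t, mv, TRUE, FALSE)
  t_mv_open <- cyclic_transition(t, mv, FALSE, TRUE)
  t_ao_open <- cyclic_transition(t, ao, FALSE, TRUE)
  t_ao_close <- cyclic_transition(t, ao, TRUE, FALSE)
  lag <- function(t1, t0) (t1 - t0) %% period
  EDV <- tr$V_ml[match(t_mv_close, t)]
  ESV <- tr$V_ml[match(t_ao_close, t)]
  if (!(ESV < EDV)) abort("no net ejection: beat metrics are undefined")
  tibble(
    EDV_ml = EDV, ESV_ml = ESV, SV_ml = EDV - ESV,
    EF_pct = 100 * (EDV - ESV) / EDV,
    t_ej_ms = lag(t_ao_close, t_ao_open),
    t_ivr_ms = lag(t_mv_open, t_ao_close),
    P_sys_peak_mmHg = kpa_to_mmhg(max(tr$P_kPa)),
    PP_ao_mmHg = kpa_to_mmhg(max(tr$Pao_kPa) - min(tr$Pao_kPa)))
}
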
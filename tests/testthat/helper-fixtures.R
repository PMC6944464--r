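# Shared fixtures: the trained coefficient sets, default cell unit, and the
# three active training circulations. Reference traces used by several files
# are cached per session to keep the suite fast.

fix_lo <- lo_params_normal()
fix_cell <- cell_params()
fix_circs <- lapply(c("A1", "A2", "A3"), circ_preset)

# single-element steady-state traces under the three presets (memoised)
fix_ref_traces <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- lapply(fix_circs, function(hp)
        simulate_beats(fix_lo, fix_cell, hp))
    }
    cache
  }
})

# construct a synthetic one-beat trace with prescribed valve-event times
# (ms): mitral closes at mv_close, aortic open on [ao_open, ao_close),
# mitral reopens at mv_open. Volumes/pressures are simple ramps; flows are
# set directly so phase and metric extraction can be checked independently
# of any simulation.
synthetic_trace <- function(mv_close = 50, ao_open = 60, ao_close = 310,
                            mv_open = 450, period = 1000, EDV = 120,
                            ESV = 48) {
  t <- seq(0, period - 1)
  mv <- (t < mv_close) | (t >= mv_open)
  ao <- (t >= ao_open) & (t < ao_close)
  V <- numeric(length(t))
  V[t < mv_close] <- EDV
  V[t >= mv_close & t < ao_open] <- EDV
  ej <- t >= ao_open & t < ao_close
  V[ej] <- EDV + (ESV - EDV) * (t[ej] - ao_open) / (ao_close - ao_open)
  V[t >= ao_close & t < mv_open] <- ESV
  fill <- t >= mv_open
  V[fill] <- ESV + (EDV - ESV) * (t[fill] - mv_open) / (period - mv_open)
  P <- 1 + 9 * ao
  tr <- tibble::tibble(
    t_ms = t, P_kPa = P, V_ml = V, Pao_kPa = 10 + 2 * ao,
    Qmv_ml_s = ifelse(mv, 50, 0), Qao_ml_s = ifelse(ao, 80, 0),
    lambda = 1, Pat_kPa = 1, Pwk_kPa = 10)
  tr$phase <- lv_phases(tr$Qmv_ml_s, tr$Qao_ml_s)
  attr(tr, "period_ms") <- period
  class(tr) <- c("lv_trace", class(tr))
  tr
}
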
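test_that("passive law is continuous at V0 and matches hand evaluations", {
  lp <- fix_lo
  eps <- 1e-9
  expect_equal(passive_pressure(lp$V0, lp), 0)
  expect_lt(abs(passive_pressure(lp$V0 - eps, lp) -
                  passive_pressure(lp$V0 + eps, lp)), 1e-10)
  # cubic branch at V = 1.5 V0: 1.70/8 - 1.41/4 + 1.64/2
  expect_equal(passive_pressure(1.5 * lp$V0, lp),
               1.70 * 0.125 - 1.41 * 0.25 + 1.64 * 0.5)
  # exponential branch at V = 0.9 V0: 0.640 (1 - e^{0.1 * 1.39 * 4.97})
  expect_equal(passive_pressure(0.9 * lp$V0, lp),
               0.640 * (1 - exp(0.1 * 1.39 * 4.97)))
  expect_equal(0.640 * (1 - exp(0.1 * 1.39 * 4.97)), -0.637,
               tolerance = 1e-3)
  expect_error(passive_pressure(-1, lp), "positive")
})

test_that("passive curve is monotone over the fitted range for both sets", {
  for (lp in list(lo_params_normal(), lo_params_failing())) {
    V <- seq(lp$V0, 2 * lp$V0, length.out = 400)
    expect_true(all(diff(passive_pressure(V, lp)) > 0))
  }
})

test_that("passive inversion round-trips both branches", {
  lp <- fix_lo
  p <- c(-0.45, -0.1, 0, 0.3, 1.2, 4)
  V <- passive_volume(p, lp)
  expect_equal(passive_pressure(V, lp), p, tolerance = 1e-10)
})

test_that("volume-to-stretch transform is linear with the documented values", {
  lp <- fix_lo
  expect_equal(stretch_from_volume(lp$V0, lp), 1)
  expect_equal(stretch_from_volume(1.5 * lp$V0, lp), 1 + 0.191 * 0.5)
  expect_equal(1 + 0.191 * 0.5, 1.0955)
  # degenerate decoupled case handled, not rejected
  lp0 <- lo_params(mu1 = 0)
  expect_equal(stretch_from_volume(c(50, 100, 180), lp0), rep(1, 3))
})

test_that("ventricular pressure adds the scaled active tension", {
  lp <- fix_lo
  expect_equal(ventricular_pressure(40, lp$V0, lp), 0.183 * 40)
  expect_equal(0.183 * 40, 7.32)
  expect_equal(ventricular_pressure(0, 130, lp), passive_pressure(130, lp))
  # additivity in Ta
  d <- ventricular_pressure(30, 130, lp) - ventricular_pressure(10, 130, lp)
  expect_equal(d, lp$mu2 * 20)
})

test_that("pressure unit conversion matches the standard atmosphere", {
  expect_equal(kpa_to_mmhg(101.325), 760, tolerance = 1e-6)
  expect_equal(kpa_to_mmhg(13.3), 99.8, tolerance = 1e-3)
  expect_equal(mmhg_to_kpa(kpa_to_mmhg(7.5)), 7.5)
})

test_that("with no active tension the volume settles at the passive root", {
  lp <- fix_lo
  cp <- cell_params(Sa = 0)
  # aortic path blocked so the passive balloon equilibrates against the
  # atrium alone
  hp <- circ_params(Pat0 = 1, R1 = 1e9, R3 = 0.2, Cwk = 8)
  tr <- simulate_beats(lp, cp, hp, solver_settings(n_beats = 20))
  # independent 1-D root of Ppass(V) = 1 kPa
  V_root <- uniroot(function(V) passive_pressure(V, lp) - 1,
                    c(lp$V0, 3 * lp$V0), tol = 1e-12)$root
  expect_equal(V_root / lp$V0, 1.68, tolerance = 0.005)
  expect_equal(tail(tr$V_ml, 1), V_root, tolerance = 1e-3)
})

test_that("blocked valves freeze the cavity volume", {
  lp <- fix_lo
  hp <- circ_params(Rmv = 1e9, R1 = 1e9, R3 = 0.2, Cwk = 8)
  tr <- simulate_beats(lp, fix_cell, hp, solver_settings(n_beats = 3))
  expect_lt(diff(range(tr$V_ml)), 1e-6)
})

test_that("traces are bitwise deterministic and refine with the step", {
  lp <- fix_lo
  hp <- circ_preset("A1")
  t1 <- simulate_beats(lp, fix_cell, hp)
  t2 <- simulate_beats(lp, fix_cell, hp)
  expect_identical(t1$P_kPa, t2$P_kPa)
  expect_identical(t1$V_ml, t2$V_ml)
  ef <- function(dt) beat_metrics(simulate_beats(
    lp, fix_cell, hp, solver_settings(dt = dt)))$EF_pct
  expect_lt(abs(ef(0.1) - ef(0.05)), 0.1)
})

test_that("beat metrics extract the constructed valve events", {
  tr <- synthetic_trace(mv_close = 50, ao_open = 60, ao_close = 310,
                        mv_open = 450, EDV = 120, ESV = 48)
  m <- beat_metrics(tr)
  expect_equal(m$t_ej_ms, 250)
  expect_equal(m$t_ivr_ms, 140)
  expect_equal(m$EDV_ml, 120)
  expect_equal(m$ESV_ml, 48)
  expect_equal(m$EF_pct, 60)
  # phases form the expected contiguous blocks
  expect_equal(as.character(tr$phase[tr$t_ms == 55]),
               "isovolumic_contraction")
  expect_equal(as.character(tr$phase[tr$t_ms == 400]),
               "isovolumic_relaxation")
  expect_equal(as.character(tr$phase[tr$t_ms == 100]), "ejection")
  expect_equal(as.character(tr$phase[tr$t_ms == 500]), "filling")
})

test_that("metrics are undefined without ejection", {
  tr <- synthetic_trace()
  tr$Qao_ml_s <- 0
  expect_error(beat_metrics(tr), "no ejection")
})

test_that("non-default cell units are rejected by the compiled core", {
  cp <- cell_params(model = "alternative")
  expect_error(simulate_beats(fix_lo, cp, circ_preset("A1")),
               "no compiled integrator")
})

test_that("simulation failure is reported when the state degenerates", {
  lp <- fix_lo
  # a calcium amplitude at the double-precision ceiling overflows the Hill
  # activation; the integrator must report the failure, not return garbage
  cp <- cell_params(Ca_amp = 1e300)
  expect_error(simulate_beats(lp, cp, circ_preset("A1")),
               "simulation failure")
})
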
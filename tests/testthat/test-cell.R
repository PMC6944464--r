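test_that("calcium transient has the documented shape", {
  p <- cell_params(tau1 = 30, tau2 = 150)
  # at onset both exponentials cancel: diastolic level
  expect_equal(calcium_transient(0, p), p$Ca_d)
  # peak equals Ca_d + Ca_amp at the closed-form extremum of the
  # biexponential, s* = tau1 tau2 / (tau2 - tau1) * log(tau2/tau1)
  s_star <- 30 * 150 / (150 - 30) * log(150 / 30)
  expect_equal(s_star, 37.5 * log(5))
  grid <- seq(0, 600, by = 0.01)
  ca <- calcium_transient(grid, p)
  expect_equal(grid[which.max(ca)], s_star, tolerance = 1e-4)
  expect_equal(max(ca), p$Ca_d + p$Ca_amp, tolerance = 1e-6)
  expect_equal(calcium_transient(p$t_act + s_star, p), p$Ca_d + p$Ca_amp)
  # zero amplitude: flat at the diastolic level
  p0 <- cell_params(Ca_amp = 0)
  expect_true(all(calcium_transient(grid, p0) == p0$Ca_d))
  # invalid time constants rejected
  expect_error(cell_params(tau1 = 150, tau2 = 150), "tau2 must exceed")
  expect_error(cell_params(tau1 = -5), "positive")
})

test_that("state derivative has the documented fixed points and limits", {
  p <- cell_params()
  s0 <- cell_state(A = 0, F = 0)
  d0 <- cell_derivative(s0, lam = 1, ca = 0, p)
  expect_equal(d0$A, 0)
  expect_equal(d0$F, 0)
  # gate saturation: dA/dt -> -k_off at A = 1, ca -> infinity
  d1 <- cell_derivative(cell_state(A = 1, F = 0), lam = 1, ca = 1e9, p)
  expect_equal(d1$A, -p$k_off, tolerance = 1e-6)
  expect_error(cell_derivative(s0, lam = 1, ca = -1, p), "calcium")
  expect_error(cell_derivative(s0, lam = -1, ca = 1, p), "stretch")
})

test_that("closed-form steady state matches long-time integration", {
  p <- cell_params()
  ca <- 0.8
  ss <- cell_steady_state(ca, p, lam = 1.1)
  tw <- simulate_twitch(p, lam = 1.1, t_end = 3000, dt = 0.1, ca = ca)
  n <- nrow(tw)
  expect_equal(tw$A[n], ss$A, tolerance = 1e-6)
  expect_equal(tw$F[n], ss$F, tolerance = 1e-6)
  expect_equal(tw$Ta_kPa[n], ss$Ta, tolerance = 1e-6)
})

test_that("states stay in [0,1] and tension nonnegative along trajectories", {
  set.seed(4021)
  for (i in 1:8) {
    p <- cell_params(fXB = runif(1, 5, 60), gXB = runif(1, 5, 60),
                     k_on = runif(1, 10, 80), k_off = runif(1, 10, 80),
                     nA = runif(1, 1, 8), tau1 = runif(1, 10, 60),
                     tau2 = runif(1, 80, 400), Ca_amp = runif(1, 0.2, 2))
    tw <- simulate_twitch(p, lam = runif(1, 0.8, 1.3), t_end = 1500)
    expect_true(all(tw$A >= 0 & tw$A <= 1))
    expect_true(all(tw$F >= 0 & tw$F <= 1))
    expect_true(all(tw$Ta_kPa >= 0))
  }
})

test_that("active tension respects its endpoints and linearity", {
  p <- cell_params()
  expect_equal(active_tension(cell_state(A = 1, F = 0), 1.1, p), 0)
  s <- cell_state(A = 0.5, F = 0.4)
  expect_equal(active_tension(s, p$n0, p), 0)
  expect_equal(active_tension(s, 1, p), p$Sa * 0.4)
  p2 <- p
  p2$Sa <- 2 * p$Sa
  expect_equal(active_tension(s, 1.07, p2), 2 * active_tension(s, 1.07, p))
  # no force below the minimum stretch
  expect_equal(active_tension(s, 0.5 * p$n0, p), 0)
})

test_that("steady tension is monotone in calcium and steeper with nA", {
  p <- cell_params()
  ca_grid <- seq(0.05, 3, by = 0.05)
  ta <- cell_steady_state(ca_grid, p, lam = 1.1)$Ta
  expect_true(all(diff(ta) >= -1e-12))
  slope_at_ca50 <- function(nA) {
    pp <- cell_params(nA = nA)
    h <- 1e-4
    (cell_steady_state(pp$Ca50 + h, pp, 1.1)$Ta -
        cell_steady_state(pp$Ca50 - h, pp, 1.1)$Ta) / (2 * h)
  }
  expect_gt(slope_at_ca50(6), slope_at_ca50(3))
})

test_that("scale_vmax scales both rates and keeps isometric tension", {
  p <- cell_params()
  expect_identical(scale_vmax(p, 1), p)
  q <- scale_vmax(p, 0.25)
  expect_equal(q$fXB, p$fXB / 4)
  expect_equal(q$gXB, p$gXB / 4)
  expect_identical(q$Sa, p$Sa)
  # isometric steady tension depends on fXB/gXB ratio only
  expect_equal(cell_steady_state(0.9, q, 1.1)$Ta,
               cell_steady_state(0.9, p, 1.1)$Ta)
  expect_error(scale_vmax(p, 0), "positive")
  expect_error(scale_vmax(p, -2), "positive")
})
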
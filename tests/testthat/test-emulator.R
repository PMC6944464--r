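test_that("latin hypercube designs are stratified and reproducible", {
  g1 <- sample_anatomies(150, seed = 9)
  g2 <- sample_anatomies(150, seed = 9)
  expect_identical(g1, g2)
  rng <- default_geometry_ranges()
  for (f in names(rng)) {
    u <- (g1[[f]] - rng[[f]][1]) / diff(rng[[f]])
    # exactly one sample in each of the n equal bins
    expect_equal(sort(unique(floor(u * 150))), 0:149)
  }
  g3 <- sample_anatomies(150, seed = 10)
  expect_false(identical(g1, g3))
  # degenerate design: midpoint
  g0 <- sample_anatomies(1)
  expect_equal(g0$Rb_mm, mean(rng$Rb_mm))
  expect_error(sample_anatomies(5, ranges = list(Rb_mm = c(2, 1))),
               "range|dimensions")
})

test_that("cavity volume scales dimensionally and matches the spheroid", {
  g <- tibble::tibble(Rb_mm = 35, L_mm = 9.6, Z_mm = 54, H_mm = 12,
                      e = 0.70, Psi0_deg = -53)
  v1 <- cavity_volume(g)
  g2 <- g
  g2$Rb_mm <- 2 * g$Rb_mm
  g2$L_mm <- 2 * g$L_mm
  g2$Z_mm <- 2 * g$Z_mm
  g2$H_mm <- 2 * g$H_mm
  expect_equal(cavity_volume(g2), 8 * v1, tolerance = 1e-8)
  # full prolate spheroid limit: e = 1, truncation at the far pole, H = L
  gs <- tibble::tibble(Rb_mm = 35, L_mm = 9.6, Z_mm = 54, H_mm = 9.6,
                       e = 1, Psi0_deg = -90)
  Ri <- 35 - 9.6
  Zi <- 54 - 9.6
  expect_equal(cavity_volume(gs), 4 / 3 * pi * Ri^2 * Zi / 1000,
               tolerance = 1e-6)
  # reference unloaded normal anatomy lands in a physiological band
  expect_gt(v1, 40)
  expect_lt(v1, 200)
  expect_error(cavity_volume(tibble::tibble(
    Rb_mm = 10, L_mm = 12, Z_mm = 54, H_mm = 12, e = 0.7, Psi0_deg = -53)),
    "inner radius")
})

test_that("the admissibility filter applies the 85% rule inclusively", {
  mk <- function(minV) {
    tibble::tibble(t_ms = 0:10, V_ml = seq(100, minV, length.out = 11))
  }
  expect_true(is_admissible(mk(80), 100))
  expect_false(is_admissible(mk(90), 100))
  expect_true(is_admissible(mk(85), 100)) # boundary inclusive
})

test_that("the emulator learns a smooth noiseless map", {
  set.seed(11)
  X <- sample_anatomies(80, seed = 11)
  Y <- synthetic_coefficient_map(X)
  cv <- cross_validate(X, Y, k = 5, seed = 2)
  expect_equal(nrow(cv), 8)
  expect_true(all(cv$r_squared > 0.9))
  # seeded fold assignment is reproducible
  cv2 <- cross_validate(X, Y, k = 5, seed = 2)
  expect_identical(cv$r_squared, cv2$r_squared)
  em <- fit_emulator(X, Y, seed = 2)
  pr <- predict(em, X[1:5, ])
  expect_equal(names(pr), names(Y))
  # sign constraints of the physical coefficients on a test grid
  Xg <- sample_anatomies(40, seed = 33)
  pg <- predict(em, Xg)
  expect_true(all(pg$mu1 > 0))
  expect_true(all(pg$mu2 > 0))
  expect_true(all(pg$alpha > 0))
  expect_true(all(pg$c > 0))
})

test_that("noise-free GPs interpolate and constants are preserved", {
  set.seed(5)
  X <- matrix(runif(60), 20, 3)
  y <- sin(2 * X[, 1]) + X[, 2]^2
  fit <- gp_fit(X, y, seed = 1, noise = FALSE)
  pr <- gp_predict(fit, X)
  expect_lt(max(abs(pr$mean - y) / (abs(y) + 1)), 0.01)
  # constant outputs: constant prediction, near-zero spread
  fit0 <- gp_fit(X, rep(3.2, 20), seed = 1)
  pr0 <- gp_predict(fit0, matrix(runif(9), 3, 3))
  expect_equal(pr0$mean, rep(3.2, 3))
  expect_equal(pr0$sd, rep(0, 3))
  expect_error(gp_fit(cbind(X[, 1], X[, 1], X[, 1]), y), "rank")
})

test_that("cross-validation separates signal from noise", {
  set.seed(21)
  X <- matrix(runif(200), 50, 4)
  y_lin <- 2 * X[, 1] - 3 * X[, 3] + 0.5
  cv_lin <- cross_validate(as.data.frame(X), data.frame(y = y_lin), k = 5,
                           seed = 1)
  expect_gt(cv_lin$r_squared, 0.99)
  y_noise <- rnorm(50)
  cv_noise <- cross_validate(as.data.frame(X), data.frame(y = y_noise),
                             k = 5, seed = 1)
  expect_lt(cv_noise$r_squared, 0.1)
  expect_error(cross_validate(as.data.frame(X), data.frame(y = y_lin),
                              k = 60, seed = 1), "exceed")
})

test_that("the cohort loop reports its admissibility bookkeeping", {
  res <- train_cohort(n = 30, seed = 3, budget = 40, polish = 40,
                      solver = solver_settings(n_beats = 12), k = 3)
  expect_equal(res$n_admissible + res$n_excluded, 30)
  expect_gte(res$n_admissible, 10) # enough cases to regress
  expect_equal(nrow(res$coefficients), res$n_admissible)
  expect_s3_class(res$emulator, "lv_emulator")
  expect_equal(nrow(res$cv), 8)
})
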
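test_that("congruency error matches closed-form cases", {
  tr <- fix_ref_traces()[[1]]
  expect_equal(congruency_error(tr, tr), 0)
  # uniform 1% pressure scaling: P-term = 1e-4, C = 0.01 (1.0 on the x100
  # scale)
  tr2 <- tr
  tr2$P_kPa <- tr$P_kPa * 1.01
  expect_equal(congruency_error(tr, tr2), 0.01, tolerance = 1e-12)
  # normalization is by the reference only: the functional is asymmetric
  expect_false(isTRUE(all.equal(congruency_error(tr, tr2),
                                congruency_error(tr2, tr))))
  # multi-protocol form averages per-protocol terms
  C3 <- congruency_error(list(tr, tr, tr), list(tr2, tr, tr))
  expect_equal(C3, sqrt(1e-4 / 3), tolerance = 1e-12)
  det <- congruency_error(list(tr, tr2), list(tr2, tr), detail = TRUE)
  expect_equal(sum(det$terms$V_term + det$terms$P_term), 2 * det$C^2)
  # mismatched grids are an error, never silently resampled
  tr3 <- tr[-2, ]
  expect_error(congruency_error(tr, tr3), "common time grid")
})

test_that("congruency error is stable under output-grid refinement", {
  lp <- fix_lo
  hp <- circ_preset("A1")
  lo2 <- lp
  lo2$mu2 <- lp$mu2 * 1.03
  C_at <- function(dt_out) {
    s <- solver_settings(dt = 0.1, dt_out = dt_out)
    congruency_error(simulate_beats(lp, fix_cell, hp, s),
                     simulate_beats(lo2, fix_cell, hp, s))
  }
  expect_lt(abs(C_at(1) - C_at(0.5)), 1e-6)
})

test_that("passive fit recovers generating coefficients", {
  lp <- fix_lo
  ref <- passive_inflation(lp) # includes compression samples
  fit <- fit_passive(ref, lp$V0)
  expect_s3_class(fit, "lv_passive_fit")
  expect_lt(abs(fit$coefficients[["a"]] / lp$a - 1), 0.01)
  expect_lt(abs(fit$coefficients[["b"]] / lp$b - 1), 0.01)
  expect_lt(abs(fit$coefficients[["c"]] / lp$c - 1), 0.01)
  expect_lt(fit$residual, 1e-8)
  # with gamma pinned at 1 the compression exponent absorbs the product
  # beta * gamma of the generator
  expect_equal(fit$coefficients[["beta"]], lp$beta * lp$gamma,
               tolerance = 1e-3)
  expect_false(fit$unconstrained_compression)
  # objective at the generating point is a local optimum: perturbations of
  # the identifiable cubic coefficients never improve it
  obj <- function(th) {
    lpx <- lo_params(gamma = 1, alpha = th[["alpha"]], beta = th[["beta"]],
                     a = th[["a"]], b = th[["b"]], c = th[["c"]], V0 = lp$V0)
    sum(((ref$V_ml - passive_volume(ref$p_kPa, lpx)) / ref$V_ml)^2)
  }
  th0 <- fit$coefficients
  f0 <- obj(th0)
  for (nm in c("a", "b", "c")) {
    for (fac in c(0.97, 1.03)) {
      th <- th0
      th[[nm]] <- th[[nm]] * fac
      expect_gte(obj(th), f0)
    }
  }
})

test_that("tension-only reference leaves the compression branch flagged", {
  lp <- fix_lo
  ref <- passive_inflation(lp, pressures = seq(0.25, 4, by = 0.25))
  expect_warning(fit <- fit_passive(ref, lp$V0), "no compression")
  init <- c(alpha = 0.5, beta = 1.5, a = 1.5, b = -1.0, c = 1.5)
  expect_equal(fit$coefficients[["alpha"]], init[["alpha"]])
  expect_equal(fit$coefficients[["beta"]], init[["beta"]])
  expect_true(fit$unconstrained_compression)
  expect_lt(abs(fit$coefficients[["a"]] / lp$a - 1), 0.01)
})

test_that("degenerate passive references are rejected", {
  expect_error(fit_passive(tibble::tibble(p_kPa = 1:6, V_ml = rep(100, 6)),
                           100), "degenerate")
  expect_error(fit_passive(tibble::tibble(p_kPa = 1:3, V_ml = c(100, 110, 120)),
                           100), "at least 5")
})

test_that("direct search satisfies its contract", {
  f <- function(x) sum((x - c(0.3, -0.2, 0.7))^2)
  opt <- mads_minimize(f, lower = rep(-1, 3), upper = rep(1, 3), seed = 5,
                       budget = 200)
  expect_lt(sqrt(sum((opt$par - c(0.3, -0.2, 0.7))^2)), 1e-3)
  # incumbent monotonicity
  expect_true(all(diff(opt$history) <= 0))
  # seeded determinism: identical evaluation sequences
  opt2 <- mads_minimize(f, lower = rep(-1, 3), upper = rep(1, 3), seed = 5,
                        budget = 200)
  expect_identical(opt$par, opt2$par)
  expect_identical(opt$history, opt2$history)
  # budget exhaustion returns the incumbent unconverged
  opt3 <- mads_minimize(f, lower = rep(-1, 3), upper = rep(1, 3), seed = 5,
                        budget = 10)
  expect_false(opt3$converged)
  expect_equal(opt3$evaluations, 10)
  # collapsed bounds: no search, the point is returned
  opt4 <- mads_minimize(f, lower = c(0.1, 0.1, 0.1), upper = c(0.1, 0.1, 0.1),
                        seed = 1, budget = 50)
  expect_equal(opt4$par, c(0.1, 0.1, 0.1))
  expect_equal(opt4$evaluations, 1)
  expect_error(mads_minimize(f, rep(-1, 3), rep(1, 3), budget = 2),
               "at least")
  expect_error(mads_minimize(function(x) NaN, rep(-1, 3), rep(1, 3)),
               "not finite")
})

test_that("active training recovers the generating transforms", {
  lp <- fix_lo
  refs <- fix_ref_traces()
  passive_true <- c(alpha = lp$alpha, beta = lp$beta, a = lp$a, b = lp$b,
                    c = lp$c)
  fit <- fit_active(refs, fix_circs, passive_true, lp$V0, fix_cell,
                    seed = 7, budget = 400)
  expect_lt(abs(fit$mu[["mu1"]] / lp$mu1 - 1), 0.02)
  expect_lt(abs(fit$mu[["mu2"]] / lp$mu2 - 1), 0.02)
  expect_lt(abs(fit$mu[["gamma"]] / lp$gamma - 1), 0.10)
  expect_lt(fit$C, 1e-3)
  expect_true(all(diff(fit$optimizer$history) <= 0))
  td <- tidy(fit)
  expect_equal(td$term, c("mu1", "mu2", "gamma"))
  expect_equal(glance(fit)$C, fit$C)
})
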
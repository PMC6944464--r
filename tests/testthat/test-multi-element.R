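test_that("homogeneous parallel and series models collapse to one element", {
  hp <- circ_preset("A1")
  single <- fix_ref_traces()[[1]]
  cfgp <- multi_config("parallel", n_sub = 64,
                       mu1_range = c(fix_lo$mu1, fix_lo$mu1),
                       base = fix_lo, cell = fix_cell)
  trp <- simulate_multi(cfgp, hp)
  relP <- max(abs(trp$P_kPa - single$P_kPa)) / max(abs(single$P_kPa))
  relV <- max(abs(trp$V_ml - single$V_ml)) / max(single$V_ml)
  expect_lt(relP, 1e-4)
  expect_lt(relV, 1e-4)
  cfgs <- multi_config("series", n_sub = 64, w_range = c(1, 1),
                       base = fix_lo, cell = fix_cell)
  trs <- simulate_multi(cfgs, hp)
  expect_lt(max(abs(trs$P_kPa - single$P_kPa)) / max(abs(single$P_kPa)), 1e-4)
  expect_lt(max(abs(trs$V_ml - single$V_ml)) / max(single$V_ml), 1e-4)
})

test_that("parallel stretch heterogeneity spreads linearly with volume", {
  cfg <- multi_config("parallel", n_sub = 8, mu1_range = c(0.01, 0.179),
                      base = fix_lo, cell = fix_cell)
  grid <- lvreduce:::subunit_grid(cfg)
  # midpoint grid spans the interior of the imposed linear range
  expect_equal(length(grid), 8)
  expect_equal(grid[1], 0.01 + (0.179 - 0.01) / 16)
  v <- 1.4 # V/V0 at end diastole
  lam <- grid * (v - 1) + 1
  expect_equal(max(lam) - min(lam), (v - 1) * (max(grid) - min(grid)))
})

test_that("parallel quadrature is converged at the working subunit count", {
  hp <- circ_preset("A1")
  ef <- function(n) {
    cfg <- multi_config("parallel", n_sub = n, mu1_range = c(0.01, 0.179),
                        base = fix_lo, cell = fix_cell)
    beat_metrics(simulate_multi(cfg, hp))$EF_pct
  }
  expect_lt(abs(ef(128) - ef(256)), 0.05)
})

test_that("series partition conserves volume and equalizes pressure", {
  cfg <- multi_config("series", n_sub = 32, w_range = c(0.6, 1.0),
                      base = fix_lo, cell = fix_cell)
  hp <- circ_preset("A1")
  tr <- simulate_multi(cfg, hp, return_subunits = TRUE)
  vs <- attr(tr, "V_sub")
  expect_lt(max(abs(rowMeans(vs) - tr$V_ml)), 1e-9)
  expect_lt(attr(tr, "partition_residual"), 1e-9)
  # compliance ordering: the softest (w = 0.6) subunit holds the largest
  # volume subportion, the stiffest (w = 1.0) the smallest, at every sample
  expect_true(all(vs[, 1] >= vs[, ncol(vs)]))
  expect_true(all(vs[, 1] == t(apply(vs, 1, max))))
})

test_that("partition_volumes agrees with an independent scalar solver", {
  cfg <- multi_config("series", n_sub = 4, w_range = c(0.6, 1.0),
                      base = fix_lo, cell = fix_cell)
  w <- lvreduce:::subunit_grid(cfg)
  F_sub <- c(0.1, 0.2, 0.3, 0.4)
  V_tot <- 120
  res <- partition_volumes(V_tot, F_sub, cfg)
  # oracle: per-subunit pressure maps built from the exported primitives,
  # outer bisection on the common pressure
  subP <- function(Vi, i) {
    lpw <- fix_lo
    lpw$alpha <- fix_lo$alpha * w[i]
    lpw$a <- fix_lo$a * w[i]
    lpw$b <- fix_lo$b * w[i]
    lpw$c <- fix_lo$c * w[i]
    lam <- stretch_from_volume(Vi, fix_lo)
    passive_pressure(Vi, lpw) +
      fix_lo$mu2 * w[i] * active_tension(cell_state(0, F_sub[i]), lam,
                                         fix_cell)
  }
  g <- function(P) mean(vapply(seq_along(w), function(i)
    uniroot(function(Vi) subP(Vi, i) - P, c(10, 600), tol = 1e-12)$root,
    numeric(1))) - V_tot
  P_star <- uniroot(g, c(-2, 30), tol = 1e-12)$root
  expect_equal(res$P, P_star, tolerance = 1e-8)
  V_star <- vapply(seq_along(w), function(i)
    uniroot(function(Vi) subP(Vi, i) - P_star, c(10, 600),
            tol = 1e-12)$root, numeric(1))
  expect_equal(res$V_sub, V_star, tolerance = 1e-7)
  # softening one subunit increases its share at the same total volume
  F2 <- F_sub
  cfg2 <- cfg
  cfg2$w_range <- c(0.5, 1.0)
  res2 <- partition_volumes(V_tot, F2, cfg2)
  expect_gt(res2$V_sub[1], res$V_sub[1])
})

test_that("beta is not weighted in the series model unless asked", {
  # with weights acting on {alpha, a, b, c, mu2} only, two configurations
  # that differ solely in beta weighting must disagree under compression
  cfg <- multi_config("series", n_sub = 4, w_range = c(0.6, 1.0),
                      base = fix_lo, cell = fix_cell)
  cfg_wb <- cfg
  cfg_wb$weight_beta <- TRUE
  V_tot <- 0.9 * fix_lo$V0
  r1 <- partition_volumes(V_tot, 0, cfg)
  r2 <- partition_volumes(V_tot, 0, cfg_wb)
  expect_false(isTRUE(all.equal(r1$V_sub, r2$V_sub)))
  # unweighted beta: subunit compression pressures follow alpha_i with the
  # SHARED exponent beta*gamma — check against the closed form
  w <- lvreduce:::subunit_grid(cfg)
  x <- r1$V_sub / fix_lo$V0 - 1
  p_cmp <- ifelse(x <= 0,
                  w * fix_lo$alpha *
                    (1 - exp(-fix_lo$beta * fix_lo$gamma * x)),
                  w * (fix_lo$a * x^3 + fix_lo$b * x^2 + fix_lo$c * x))
  expect_equal(p_cmp, rep(r1$P, 4), tolerance = 1e-8)
})

test_that("series passive inflation averages the weighted inverses", {
  cfg <- multi_config("series", n_sub = 8, w_range = c(0.6, 1.0),
                      base = fix_lo, cell = fix_cell)
  inf <- passive_inflation(cfg, pressures = c(-0.3, 0, 0.5, 2))
  w <- lvreduce:::subunit_grid(cfg)
  V_hand <- vapply(c(-0.3, 0, 0.5, 2), function(p) {
    mean(vapply(w, function(wi) {
      lpw <- fix_lo
      lpw$alpha <- fix_lo$alpha * wi
      lpw$a <- fix_lo$a * wi
      lpw$b <- fix_lo$b * wi
      lpw$c <- fix_lo$c * wi
      passive_volume(p, lpw)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(inf$V_ml, V_hand, tolerance = 1e-10)
  expect_equal(inf$V_ml[2], fix_lo$V0)
})
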
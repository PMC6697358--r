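planar_residual <- function(unit, shared, exc, inh, V, h) {
  pf <- respcpg:::planar_field(unit, shared, exc, inh)
  c(pf$F(V, h), pf$G(V, h))
}

test_that("fixed points satisfy the equilibrium equations to tight tolerance", {
  u <- pre_I_unit(); s <- shared_params()
  for (cc in c(-0.10, -0.03, 0.01)) {
    fp <- find_fixed_points(u, s, exc_sum = cc + 0.095)
    for (r in seq_len(nrow(fp))) {
      res <- planar_residual(u, s, cc + 0.095, 0, fp$V[r], fp$h[r])
      expect_lt(max(abs(res)), 1e-10)
    }
  }
})

test_that("fixed-point structure across drives matches the bifurcation narrative", {
  u <- pre_I_unit(); s <- shared_params()
  lo <- find_fixed_points(u, s, exc_sum = -0.10 + 0.095)   # well below interval
  expect_equal(nrow(lo), 1)
  expect_true(lo$stable)
  expect_identical(lo$branch, "left")
  hi <- find_fixed_points(u, s, exc_sum = 0.01 + 0.095)    # tonic tuning
  expect_true(any(hi$stable & hi$V > -45))                 # depolarized FP
  mid <- find_fixed_points(u, s, exc_sum = -0.03 + 0.095)  # oscillatory tuning
  expect_false(any(mid$stable))
})

test_that("Hopf points satisfy their defining conditions and bracket the oscillatory interval", {
  u <- pre_I_unit()
  h_lo <- hopf_point(u, bracket = c(-0.07, -0.05))
  h_hi <- hopf_point(u, bracket = c(-0.02, 0.0))
  expect_lt(abs(attr(h_lo, "trace")), 1e-9)
  expect_lt(abs(attr(h_hi, "trace")), 1e-9)
  expect_gt(attr(h_lo, "det"), 0)   # rules out saddle-node misdetection
  expect_gt(attr(h_hi, "det"), 0)
  b <- osc_boundaries()
  expect_lt(abs(h_lo - b[1]), 0.002)   # canard explosion: near-coincidence
  expect_lt(abs(h_hi - b[2]), 0.002)
  expect_error(hopf_point(u, bracket = c(-0.2, -0.15)), "sign")
})

test_that("simulation-detected boundaries bracket exactly the rhythmic sub-grid", {
  b <- osc_boundaries()
  reg <- attr(b, "regimes")
  cc <- as.numeric(names(reg))
  inside <- cc > b[1] & cc < b[2]
  expect_true(all(reg[inside] == "rhythmic"))
  expect_true(all(reg[!inside] != "rhythmic"))
})

test_that("without persistent sodium there is no oscillatory interval", {
  b <- oscillation_boundaries(pre_I_unit(), g_NaP = 0,
                              scan = seq(-0.06, 0.02, by = 0.01))
  expect_true(all(is.na(b)))
  expect_identical(attr(b, "reason"), "no oscillatory interval")
})

test_that("the period drops sharply just inside the lower boundary, then decays gradually", {
  u <- pre_I_unit()
  per <- function(c11) {
    cfg <- isolated_config(exc_sum = c11 + 0.095)
    compute_metrics(find_attractor(cfg, solver_options(window = 80e3)))$T
  }
  b <- osc_boundaries()
  p_onset <- per(b[1] + 0.0005)
  p_mid1 <- per(-0.045)
  p_mid2 <- per(-0.03)
  p_hi <- per(-0.015)
  expect_gt(p_onset - p_mid1, p_mid1 - p_mid2)   # abrupt drop at onset
  expect_gt(p_mid1, p_mid2)                      # then gradual decay
  expect_gt(p_mid2, p_hi)
})

test_that("stability from eigenvalues agrees with simulation from perturbed starts", {
  u0 <- pre_I_unit(); s <- shared_params()
  set.seed(7)
  n_checked <- 0
  for (k in 1:50) {
    u <- u0
    u$g_NaP <- runif(1, 2.5, 5.5)
    exc <- runif(1, 0.0, 0.12)
    inh <- runif(1, 0, 0.04)
    fp <- find_fixed_points(u, s, exc_sum = exc, inh_sum = inh)
    if (nrow(fp) != 1) next
    if (max(abs(c(fp$re1, fp$re2))) < 1e-4) next   # near-marginal: skip
    cfg <- isolated_config(u, s, exc_sum = exc, inh_sum = inh)
    y0 <- pack_state(cfg, V = fp$V + 1, h = min(1, max(0, fp$h + 0.02)))
    tr <- cpg_integrate(cfg, y0, duration = 2000,
                        opts = solver_options(transient = 38e3))
    settled <- unname(abs(tr$V[nrow(tr$V), 1] - fp$V) < 0.1)
    expect_identical(settled, fp$stable)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 25)
})

test_that("transition curve is consistent across methods, warm starts, and regime labels", {
  u <- pre_I_unit()
  g <- c(5, 4.5, 4)
  tc_sim <- continue_transition_curve(u, g_NaP = g)
  tc_hopf <- continue_transition_curve(u, g_NaP = g, method = "linear-hopf")
  expect_equal(tc_sim$g_NaP, g)
  expect_lt(max(abs(tc_sim$c11 - tc_hopf$c11)), 0.002)
  # passes through the boundary from oscillation_boundaries at g = 4.5
  b <- osc_boundaries()
  expect_lt(abs(tc_sim$c11[tc_sim$g_NaP == 4.5] - b[2]), 2e-4)
  # warm-started continuation equals cold pointwise re-solving
  cold <- vapply(g, function(gg) {
    tt <- respcpg:::tracked_trace({u2 <- u; u2$g_NaP <- gg; u2},
                                  shared_params(), 0, 0.095)
    stats::uniroot(function(cc) tt(cc)$tr, c(-0.04, 0.01), tol = 1e-10)$root
  }, numeric(1))
  expect_lt(max(abs(tc_hopf$c11 - cold)), 1e-6)
  # the curve separates cells whose isolated regimes differ
  c_star <- tc_sim$c11[tc_sim$g_NaP == 4.5]
  r_below <- respcpg:::isolated_regime(u, shared_params(), c_star - 0.003)
  r_above <- respcpg:::isolated_regime(u, shared_params(), c_star + 0.003)
  expect_identical(r_below, "rhythmic")
  expect_identical(r_above, "tonic")
  # truncation where the oscillatory interval closes at small g_NaP
  tc_tr <- continue_transition_curve(u, g_NaP = c(4, 3))
  expect_identical(attr(tc_tr, "truncated"), 3)
  expect_equal(tc_tr$g_NaP, 4)
})
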
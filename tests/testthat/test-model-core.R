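test_that("gating sigmoids hit their midpoints and slopes have the right sign", {
  s <- shared_params()
  expect_equal(gating("h_inf", -48, s), 0.5)
  expect_equal(gating("tau_h", -48, s), 4000)
  expect_equal(gating("m_inf", -37, s), 0.5)
  expect_equal(gating("n_inf", -29, s), 0.5)
  V <- seq(-90, 10, by = 0.5)
  expect_true(all(diff(gating("h_inf", V, s)) < 0))   # inactivation
  expect_true(all(diff(gating("m_inf", V, s)) > 0))
  expect_true(all(diff(gating("n_inf", V, s)) > 0))
  expect_true(all(gating("tau_h", V, s) > 0 & gating("tau_h", V, s) <= 4000))
})

test_that("output sigmoids are 0.5 at their half-activation voltages and increase with V", {
  cfg <- preset("baseline5_pico")
  expect_equal(f_out(cfg$units[[1]], -32), 0.5)   # pre-I
  expect_equal(f_out(cfg$units[[3]], -30), 0.5)   # post-I (inhibitory)
  expect_equal(f_out(cfg$units[[5]], -20), 0.5)   # PiCo
  V <- seq(-80, 10, by = 1)
  for (u in cfg$units) expect_true(all(diff(f_out(u, V)) > 0))
})

test_that("intrinsic currents vanish at their reversal potentials and match a hand computation", {
  cfg <- preset("baseline4")
  s <- cfg$shared
  u1 <- cfg$units[[1]]
  expect_equal(intrinsic_currents(u1, V = -65, h = 0.5, shared = s)[["I_L"]], 0)
  expect_equal(intrinsic_currents(u1, V = 50, h = 0.5, shared = s)[["I_NaP"]], 0)
  # hand-computed product of the three I_NaP factors at V = -50, h = 0.6
  m <- 1 / (1 + exp((-50 + 37) / -6))
  expect_equal(intrinsic_currents(u1, V = -50, h = 0.6, shared = s)[["I_NaP"]],
               4.5 * m * 0.6 * (-50 - 50), tolerance = 1e-12)
  # inhibitory unit uses p, not n_inf^4
  u3 <- cfg$units[[3]]
  ic <- intrinsic_currents(u3, V = -40, h = 0.2, p = 0.3, shared = s)
  expect_equal(ic[["I_K"]], 10 * 0.3 * (-40 + 85), tolerance = 1e-12)
})

test_that("synaptic sums reduce to the tonic drive when presynaptic units are silent", {
  cfg <- preset("oscillatory")
  st <- pack_state(cfg, V = rep(-100, 4), h = 0.5, p = 0.1)
  sy <- synaptic_inputs(cfg, st, "pre-I")
  expect_lt(sy$inh_sum, 1e-6)
  expect_equal(sy$exc_sum, -0.03 + 0.095, tolerance = 1e-6)
  expect_error(synaptic_inputs(cfg, st, "PiCo"), "unknown unit")
})

# independent transcription of the model equations, coded directly from
# the current-balance and gating formulas, sharing nothing with the
# package implementation
oracle_rhs <- function(cfg, y) {
  s <- cfg$shared
  n <- length(cfg$units)
  exc <- vapply(cfg$units, `[[`, logical(1), "excitatory")
  V <- y[seq_len(n)]
  has_h <- exc | cfg$h_mode == "dynamic"
  h <- 1 / (1 + exp((V - s$theta_h) / s$sigma_h))
  h[has_h] <- y[n + seq_len(sum(has_h))]
  p <- rep(NA_real_, n)
  p[!exc] <- y[n + sum(has_h) + seq_len(sum(!exc))]
  fo <- vapply(seq_len(n), function(i) {
    u <- cfg$units[[i]]
    1 / (1 + exp((V[i] - u$theta_out) / u$sigma_out))
  }, numeric(1))
  dV <- numeric(n)
  for (i in seq_len(n)) {
    u <- cfg$units[[i]]
    m <- 1 / (1 + exp((V[i] - s$theta_m) / s$sigma_m))
    INaP <- u$g_NaP * m * h[i] * (V[i] - s$E_Na)
    IK <- if (exc[i]) {
      nn <- 1 / (1 + exp((V[i] - s$theta_n) / s$sigma_n))
      u$g_K * nn^4 * (V[i] - s$E_K)
    } else u$g_K * p[i] * (V[i] - s$E_K)
    IL <- u$g_L * (V[i] - u$E_L)
    IsynI <- s$g_synI * (V[i] - s$E_synI) *
      (u$inh0 + sum(cfg$b[!exc, i] * fo[!exc]))
    IsynE <- s$g_synE * (V[i] - s$E_synE) *
      (sum(cfg$a[exc, i] * fo[exc]) + cfg$c1[i] + cfg$c2[i])
    dV[i] <- -(INaP + IK + IL + IsynI + IsynE) / s$C
  }
  dh <- ((1 / (1 + exp((V - s$theta_h) / s$sigma_h))) - h) /
    (s$epsilon / cosh((V - s$theta_h) / (2 * s$sigma_h)))
  dp <- vapply(which(!exc), function(i)
    (cfg$units[[i]]$d_adapt * fo[i] - p[i]) / cfg$units[[i]]$tau_p,
    numeric(1))
  c(dV, dh[has_h], dp)
}

test_that("rhs agrees with an independently coded duplicate at random states", {
  set.seed(42)
  for (cfg in list(preset("oscillatory"), preset("baseline5_pico"))) {
    lay <- state_layout(cfg)
    for (k in 1:50) {
      y <- pack_state(cfg,
                      V = runif(length(lay$V), -80, 0),
                      h = runif(length(lay$h), 0, 1),
                      p = runif(length(lay$p), 0, 1))
      expected <- oracle_rhs(cfg, as.numeric(y))
      got_r <- cpg_rhs(cfg, y)
      got_c <- cpg_rhs_compiled(cfg, y)$ydot
      expect_equal(unname(got_r), expected, tolerance = 1e-12)
      expect_equal(unname(got_c), expected, tolerance = 1e-12)
    }
  }
})

test_that("rhs is autonomous", {
  cfg <- preset("oscillatory")
  y <- default_initial_state(cfg)
  expect_identical(cpg_rhs(cfg, y, t = 0), cpg_rhs(cfg, y, t = 1e6))
})

test_that("with coupling and drives removed each unit follows its isolated dynamics", {
  cfg <- preset("oscillatory")
  cfg$a[] <- 0
  cfg$c1[] <- 0
  cfg$c2[] <- 0
  cfg$b[] <- 0
  y <- pack_state(cfg, V = c(-55, -45, -35, -60), h = 0.5, p = 0.2)
  d_net <- cpg_rhs(cfg, y)
  lay <- state_layout(cfg)
  st <- unpack_state(cfg, y)
  for (i in seq_along(cfg$units)) {
    iso <- isolated_config(cfg$units[[i]]$name, from = cfg,
                           exc_sum = 0, inh_sum = 0)
    yi <- if (cfg$units[[i]]$excitatory)
      pack_state(iso, V = st$V[i], h = st$h[i]) else
      pack_state(iso, V = st$V[i], h = st$h[i], p = st$p[i])
    d_iso <- cpg_rhs(iso, yi)
    expect_equal(unname(d_iso[1]), unname(d_net[lay$V[i]]),
                 tolerance = 1e-12)
  }
})

test_that("h and p derivatives point inward at their range boundaries", {
  cfg <- preset("oscillatory")
  cfg$h_mode <- "dynamic"
  lay <- state_layout(cfg)
  Vgrid <- seq(-90, 10, by = 10)
  for (V in Vgrid) {
    y0 <- pack_state(cfg, V = rep(V, 4), h = 0, p = 0)
    y1 <- pack_state(cfg, V = rep(V, 4), h = 1,
                     p = cfg$units[[2]]$d_adapt)
    d0 <- cpg_rhs(cfg, y0)
    d1 <- cpg_rhs(cfg, y1)
    expect_true(all(d0[lay$h] >= 0) && all(d0[lay$p] >= 0))
    expect_true(all(d1[lay$h] <= 0) && all(d1[lay$p] <= 0))
  }
})

test_that("state packing and unpacking round-trip", {
  cfg <- preset("baseline5_pico")
  y <- pack_state(cfg, V = c(-60, -50, -40, -30, -20),
                  h = c(0.1, 0.3, 0.4, 0.5, 0.9), p = c(0.2, 0.3, 0.4))
  st <- unpack_state(cfg, y)
  expect_equal(unname(st$V), c(-60, -50, -40, -30, -20))
  expect_equal(unname(st$h[c("pre-I", "PiCo")]), c(0.1, 0.9))
  expect_equal(unname(st$p[c("early-I", "post-I", "aug-E")]),
               c(0.2, 0.3, 0.4))
  expect_error(unpack_state(cfg, y[-1]), "length")
})
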
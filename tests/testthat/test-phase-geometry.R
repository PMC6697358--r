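test_that("every V-nullcline sample satisfies dV/dt = 0", {
  u <- pre_I_unit(); s <- shared_params()
  nc <- v_nullcline(u, s, exc_sum = 0.065, inh_sum = 0.01,
                    V = seq(-80, 0, by = 0.5))
  pf <- respcpg:::planar_field(u, s, 0.065, 0.01)
  keep <- !nc$clipped
  res <- mapply(pf$F, nc$V[keep], nc$h[keep])
  expect_lt(max(abs(res)), 1e-10)
  expect_error(v_nullcline(unit_params("x", TRUE, g_NaP = 0, g_K = 1,
                                       g_L = 3, E_L = -65, theta_out = -32,
                                       sigma_out = -8), s), "g_NaP")
})

test_that("nullcline shape is cubic for the oscillatory tuning and monotone for the tonic tuning", {
  u <- pre_I_unit(); s <- shared_params()
  expect_identical(attr(v_nullcline(u, s, exc_sum = -0.03 + 0.095), "shape"),
                   "cubic")
  expect_identical(attr(v_nullcline(u, s, exc_sum = 0.01 + 0.095), "shape"),
                   "monotone")
  # under sufficient inhibition the tonic tuning regains a cubic shape
  expect_identical(attr(v_nullcline(u, s, exc_sum = 0.105,
                                    inh_sum = 0.02), "shape"), "cubic")
})

test_that("knees satisfy the fold condition and the tonic knee curve terminates near 0.007", {
  kn <- tonic_knees()
  u <- pre_I_unit(); s <- shared_params()
  for (r in c(1, nrow(kn) %/% 2, nrow(kn))) {
    fns <- respcpg:::nullcline_funs(u, s, 0.105, kn$inh_sum[r])
    expect_lt(abs(fns$dh(kn$V[r])), 1e-8)
  }
  term <- attr(kn, "termination")
  expect_gt(term, 0.006)
  expect_lt(term, 0.008)
  # oscillatory tuning: cubic down to zero inhibition, no termination
  expect_true(is.na(attr(osc_knees(), "termination")))
  expect_equal(min(osc_knees()$inh_sum), 0)
})

test_that("shape switches exactly once along inhibition for the tonic tuning, never for the oscillatory", {
  u <- pre_I_unit(); s <- shared_params()
  shapes <- function(exc) vapply(seq(0, 0.15, by = 0.005), function(i)
    attr(v_nullcline(u, s, exc_sum = exc, inh_sum = i), "shape"),
    character(1))
  sh_t <- shapes(0.105)
  expect_equal(sum(sh_t[-1] != sh_t[-length(sh_t)]), 1)
  sh_o <- shapes(0.065)
  expect_equal(sum(sh_o[-1] != sh_o[-length(sh_o)]), 0)
})

test_that("the fixed-point curve agrees with direct fixed-point finding and shows stable quiescence under strong inhibition", {
  u <- pre_I_unit(); s <- shared_params()
  fc <- fp_curve(u, s, exc_sum = 0.065, inh = c(0, 0.05, 0.10))
  fp0 <- find_fixed_points(u, s, exc_sum = 0.065, inh_sum = 0)
  at0 <- fc[fc$inh_sum == 0, ]
  expect_equal(sort(at0$V), sort(fp0$V), tolerance = 1e-9)
  hi <- fc[fc$inh_sum == 0.10, ]
  expect_true(any(hi$stable & hi$h > 0.85 & hi$V < -60))
  # tonic tuning, no inhibition: single depolarized stable fixed point
  fp_t <- find_fixed_points(u, s, exc_sum = 0.105, inh_sum = 0)
  expect_equal(nrow(fp_t), 1)
  expect_true(fp_t$stable && fp_t$V > -45)
})

test_that("escape events exist each cycle and precede inspiratory onset", {
  tr <- osc_attractor()
  esc <- project_escape(tr, "pre-I", osc_knees())
  expect_gte(nrow(esc$events), 4)
  expect_lt(diff(range(esc$events$inh_sum)), 1e-4)   # cycle-to-cycle repeatability
  up <- threshold_crossings(tr, 1, "V", -35, "up")
  for (r in seq_len(nrow(esc$events))) {
    nxt <- up[up > esc$events$t[r] - 1][1]
    expect_lt(nxt - esc$events$t[r], 1500)   # escape shortly before onset
    expect_gt(nxt, esc$events$t[r] - 1)
  }
})

test_that("before escape the trajectory deinactivates toward the fixed-point curve", {
  tr <- osc_attractor()
  esc <- project_escape(tr, "pre-I", osc_knees())
  i <- 1
  t1 <- esc$events$t[2]
  t0 <- t1 - 1500                      # late expiration, pre-escape
  seg <- tr$t >= t0 & tr$t <= t1
  d <- diff(tr$h[seg, i])
  expect_true(all(d > -1e-5))          # h rising (to sample resolution)
  expect_gt(sum(d), 0.005)             # and by a meaningful amount
})

test_that("stronger post-I inhibition shifts the escape to larger inhibition and larger h", {
  base <- project_escape(osc_attractor(), "pre-I", osc_knees())
  trs <- cached("strong_b31", find_attractor(preset("strong_b31")))
  strong <- project_escape(trs, "pre-I", osc_knees())
  expect_gt(mean(strong$events$inh_sum), mean(base$events$inh_sum))
  expect_gt(mean(strong$events$h), mean(base$events$h))
})

test_that("an empty knee curve yields an explicit no-escape result", {
  kn <- knee_curve(pre_I_unit(), shared_params(), exc_sum = 0.105,
                   inh = seq(0, 0.004, by = 0.001))   # below termination
  expect_equal(nrow(kn), 0)
  esc <- project_escape(osc_attractor(), "pre-I", kn)
  expect_equal(nrow(esc$events), 0)
})
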
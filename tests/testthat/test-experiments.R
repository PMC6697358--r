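test_that("embedding masks the isolated oscillatory range", {
  ce <- cached("compare", compare_isolated_embedded(
    c11 = seq(-0.055, 0.01, by = 0.005)))
  lowend <- ce[ce$c11 <= -0.045, ]
  expect_true(all(lowend$isolated_regime == "rhythmic"))
  expect_true(all(lowend$embedded_regime != "rhythmic"))
  hi <- ce[ce$c11 >= 0, ]
  expect_true(all(hi$isolated_regime == "tonic"))
  expect_true(all(hi$embedded_regime == "rhythmic"))
  both <- ce[ce$c11 == -0.03, ]
  expect_equal(both$embedded_T, compute_metrics(osc_attractor())$T,
               tolerance = 1e-4)
  expect_equal(both$embedded_amp, compute_metrics(osc_attractor())$amplitude,
               tolerance = 1e-4)
  # the embedded unit runs slower and larger than in isolation here
  expect_gt(both$embedded_T, both$isolated_T)
  expect_gt(both$embedded_amp, both$isolated_amp)
})

test_that("block protocol with kappa = 1 reproduces the baseline exactly", {
  cfg <- preset("oscillatory")
  expect_identical(pack_parms(apply_block(cfg, "preBotC", 1)),
                   pack_parms(cfg))
  expect_identical(pack_parms(apply_block(cfg, "BotC", 1)), pack_parms(cfg))
  half <- apply_block(cfg, "BotC", 0.5)
  expect_equal(half$b["early-I", "post-I"], 0.3)   # b23 halved
  expect_equal(half$b["post-I", "pre-I"], 0.125)   # inputs to pre-I untouched
  expect_error(apply_block(cfg, "BotC", 0), "kappa")
})

test_that("block bisection boundary lies within one grid step of the first non-rhythmic cell", {
  bl <- cached("block_coarse", inhibition_block(
    preset("tonic"), "BotC", kappa = seq(1, 0.5, by = -0.1)))
  sweeprhy <- bl$sweep$regime == "rhythmic"
  first_lost <- bl$sweep$kappa[which(!sweeprhy)[1]]
  expect_lte(bl$kappa_star - first_lost, 0.1)
  expect_gte(bl$kappa_star, first_lost)
  expect_equal(bl$sweep$T_rel[1], 1)
  expect_equal(bl$sweep$amp_rel[1], 1)
})

test_that("drive to pre-I shortens the period through the expiratory phase", {
  sw <- cached("c11_sweep", drive_sweep("c11", seq(-0.035, 0.01, by = 0.005)))
  expect_true(all(diff(sw$T) < 0))
  expect_true(all(diff(sw$T_E) < 0))
  dTI <- abs(sw$T_I[nrow(sw)] - sw$T_I[1])
  expect_lt(dTI, 0.3 * abs(sw$T_E[nrow(sw)] - sw$T_E[1]))
})

test_that("raising post-I to pre-I inhibition lengthens the period mostly through T_E", {
  sw <- drive_sweep("b31", seq(0.105, 0.175, by = 0.014),
                    config = preset("oscillatory"))
  expect_true(all(diff(sw$T) > 0))
  expect_true(all(diff(sw$T_E) > 0))
  expect_true(all(diff(sw$T_I) > 0))                 # small accompanying increase
  expect_lt(max(diff(sw$T_I)), min(diff(sw$T_E)))
})

test_that("the period is more sensitive to aug-E drive than to post-I drive", {
  d13 <- drive_sweep("c13", 0.58 + c(-0.02, 0, 0.02))
  d14 <- drive_sweep("c14", 0.20 + c(-0.02, 0, 0.02))
  expect_true(all(diff(d13$T) > 0))   # both drives lengthen the period
  expect_true(all(diff(d14$T) > 0))
  # local sensitivity dT/dc over the same drive increment
  expect_gt(diff(range(d14$T)), diff(range(d13$T)))
  # and the change is carried by T_E in both cases
  expect_gt(diff(range(d14$T_E)), 0.8 * diff(range(d14$T)))
})

test_that("an output-disconnected PiCo leaves the core network attractor unchanged", {
  cfg5 <- preset("baseline5_pico")
  cfg5$a["PiCo", "post-I"] <- 0
  m5 <- network_metrics(cfg5)
  cfg4 <- preset("baseline4")
  cfg4$b["aug-E", "post-I"] <- 0.02    # the with-PiCo b43 value
  m4 <- network_metrics(cfg4)
  expect_equal(m5$T, m4$T, tolerance = 1e-6)
  expect_equal(m5$amplitude, m4$amplitude, tolerance = 1e-6)
})

test_that("the a53-induced period change is carried by the expiratory phase", {
  ps <- cached("pico_a53", pico_suite(a53 = seq(0, 0.4, by = 0.1),
                                      c15 = NULL, c13 = NULL))
  a <- ps$a53
  dT <- a$T[1] - a$T[nrow(a)]
  dTE <- a$T_E[1] - a$T_E[nrow(a)]
  expect_gt(dT, 0)                        # stronger PiCo drive shortens T
  expect_lt(abs(dT - dTE), 0.15 * dT)
  expect_true(all(a$three_phase_valid))   # PiCo leaves the order intact
})

test_that("PiCo co-activates with post-I and is suppressed during inspiration", {
  tr <- cached("pico_tr", find_attractor(preset("baseline5_pico")))
  i1 <- which(colnames(tr$f_out) == "pre-I")
  i3 <- which(colnames(tr$f_out) == "post-I")
  i5 <- which(colnames(tr$f_out) == "PiCo")
  insp <- tr$f_out[, i1] > 0.5
  expect_lt(max(tr$f_out[insp, i5]), 0.2)
  expect_gt(cor(tr$f_out[, i5], tr$f_out[, i3]), 0.7)
})

test_that("PiCo extends the rhythm-preserving post-I drive range to lower values", {
  grid <- seq(0.30, 0.46, by = 0.04)
  with5 <- cached("c13_with", drive_sweep("c13", grid,
                                          config = preset("baseline5_pico")))
  with4 <- cached("c13_without", drive_sweep("c13", grid))
  ok5 <- with5$regime == "rhythmic" & with5$three_phase_valid
  ok4 <- with4$regime == "rhythmic" & with4$three_phase_valid
  expect_lt(min(with5$c13[ok5]), min(with4$c13[ok4]))
})
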
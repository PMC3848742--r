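# Troponin binding, TnI phosphorylation, crossbridge rate scaling and the
# reduced cooperative force model.

test_that("troponin occupancies settle on the printed fixed points", {
  cfg <- model_config()
  # ca = 1 uM, TnIu = 1: h-site 22.22/(22.22+17.36), l-site 22.22/(22.22+173.61)
  h <- 0; l <- 0
  dt <- 1e-4
  for (i in 1:4000) {
    d <- troponin_rhs(1, h, l, 1, cfg)
    h <- h + dt * d[["d_ca_trop_h"]]
    l <- l + dt * d[["d_ca_trop_l"]]
  }
  expect_rel_equal(h, 22.22 / (22.22 + 17.36), 1e-5)
  expect_rel_equal(h, 0.5614, 1e-3)
  expect_rel_equal(l, 22.22 / (22.22 + 173.61), 1e-5)
  expect_rel_equal(l, 0.1135, 1e-3)
  # zero Ca: both occupancies decay to zero
  for (i in 1:20000) {
    d <- troponin_rhs(0, h, l, 1, cfg)
    h <- h + dt * d[["d_ca_trop_h"]]
    l <- l + dt * d[["d_ca_trop_l"]]
  }
  expect_lt(h, 1e-6)
  expect_lt(l, 1e-8)
  # halving TnIu halves the effective on-rate
  d1 <- troponin_rhs(1, 0.2, 0.05, 1, cfg)
  d2 <- troponin_rhs(1, 0.2, 0.05, 0.5, cfg)
  on1 <- d1[["d_ca_trop_h"]] + cfg$mechanics$koff_ht * 0.2
  on2 <- d2[["d_ca_trop_h"]] + cfg$mechanics$koff_ht * 0.2
  expect_rel_equal(on2 / on1, 0.5, 1e-12)
})

test_that("TnI phosphorylation fixed point follows the PKA law", {
  cfg <- model_config()
  # deltaPKA = 0.15 at camp = 12.1: steady tni_p = 104.80/(104.80+80)
  p <- 0
  for (i in 1:40000) p <- p + 1e-4 * tni_rhs(p, 12.1, cfg)
  expect_rel_equal(p, 698.69 * 0.15 / (698.69 * 0.15 + 80), 1e-6)
  expect_rel_equal(p, 0.5671, 1e-3)
  # camp = 0: decays to zero
  p <- 0.4
  for (i in 1:40000) p <- p + 1e-4 * tni_rhs(p, 0, cfg)
  expect_lt(p, 1e-6)
  expect_error(tni_rhs(1.2, 1, cfg), "\\[0, 1\\]")
})

test_that("crossbridge rates scale with the cAMP factor and Q10 temperature law", {
  cfg <- model_config()
  tref <- cfg$mechanics$t_ref
  # at T = t_ref and a cAMP giving F = 1, rates are unchanged
  camp_unit <- uniroot(function(c) f_camp_force(c) - 1, c(0, 10), tol = 1e-12)$root
  r <- xb_rate_scaling(camp_unit, tref, cfg)
  expect_rel_equal(r$fapp, cfg$mechanics$fapp, 1e-9)
  expect_rel_equal(r$hb, cfg$mechanics$hb, 1e-9)
  # +10 degC multiplies the four scaled rates by exactly Q10 = 2.25
  r10 <- xb_rate_scaling(camp_unit, tref + 10, cfg)
  for (nm in c("fapp", "hf", "hb", "gxb")) {
    expect_rel_equal(r10[[nm]] / r[[nm]], 2.25, 1e-9)
  }
  expect_equal(r10$gapp, r$gapp)  # reverse attachment not scaled
  # camp = 24.58 at t_ref scales by F = 1.8605
  r_camp <- xb_rate_scaling(24.58, tref, cfg)
  expect_rel_equal(r_camp$fapp / cfg$mechanics$fapp, 1.8605, 1e-3)
  expect_error(xb_rate_scaling(2.67, 50, cfg), "range")
})

test_that("steady-state force-Ca relation is sigmoidal with Hill coefficient above 1", {
  cfg <- model_config()
  ca <- seq(0.05, 6, by = 0.05)
  fc <- force_ca_curve(ca, 2.67, cfg)
  expect_true(all(diff(fc$force_norm) >= 0))
  # effective Hill coefficient from the 20-80% range
  f_norm <- fc$force_norm / max(fc$force_norm)
  ca20 <- ca[which.min(abs(f_norm - 0.2))]
  ca80 <- ca[which.min(abs(f_norm - 0.8))]
  n_h <- log(0.8 / 0.2 * (1 - 0.2) / (1 - 0.8)) / log(ca80 / ca20)
  expect_gt(n_h, 1)
  # raising TnI phosphorylation shifts the curve rightward without raising max
  hi_pka <- force_ca_curve(ca, 24.58, cfg)
  expect_lt(hi_pka$force_norm[40], fc$force_norm[40])
  expect_lte(max(hi_pka$force_norm), max(fc$force_norm) + 1e-9)
})

test_that("crossbridge cycle conserves fractions and relaxes to zero force without Ca", {
  cfg <- model_config()
  state <- c(ca_trop_h = 0.4, ca_trop_l = 0.1, tni_p = 0.32, perm = 0.5,
             xb_pre = 0.1, xb_post = 0.2, sl = 1.88)
  dt <- 2e-5
  worst_excess <- -Inf
  for (i in 1:50000) {
    out <- crossbridge_rhs(state, 0, 2.67, cfg)
    state <- state + dt * out$deriv
    worst_excess <- max(worst_excess, state[["xb_pre"]] + state[["xb_post"]] -
                          state[["perm"]])
  }
  # attached crossbridges never exceed the permissive fraction
  expect_lt(worst_excess, 1e-6)
  expect_lt(crossbridge_rhs(state, 0, 2.67, cfg)$force_norm, 1e-6)
  expect_rel_equal(state[["sl"]], cfg$mechanics$sl0, 1e-4)
})

test_that("full-activation crossbridge steady state solves the cycle equations", {
  r <- xb_rate_scaling(2.67, 22.5, model_config())
  ss <- xb_steady(r)
  n <- 1 - ss$pre - ss$post
  expect_rel_equal(r$fapp * n + r$hb * ss$post,
                   (r$gapp + r$hf) * ss$pre, 1e-9)
  expect_rel_equal(r$hf * ss$pre, (r$hb + r$gxb) * ss$post, 1e-9)
})
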
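# CaM cooperative binding, CaM buffering, CaMKII and CaN activation.

test_that("the zero-Ca equilibrium pool has zero derivatives", {
  # no ligand and no Ca-loaded species: the only remaining reactions are the
  # Ca-independent CaM-buffer and CaM-CaN exchanges, placed at equilibrium
  cfg <- model_config()
  pars <- cfg$signaling$myoplasm
  eq <- cam_equilibrium(0, pars)
  pool <- signaling_pool("myoplasm", pars, camb = eq$camb,
                         can_cam = eq$can_cam)
  d <- cam_rhs(pool, 0)
  expect_equal(unname(d), rep(0, 4), tolerance = 1e-10)
  expect_equal(camkii_rhs(pool), 0)
  dn <- can_rhs(pool)
  expect_equal(unname(dn), rep(0, 6), tolerance = 1e-10)
})

test_that("CaM derivatives conserve total CaM", {
  cfg <- model_config()
  for (cmp in c("dyad", "myoplasm")) {
    pars <- cfg$signaling[[if (cmp == "dyad") "dyad" else "myoplasm"]]
    pool <- signaling_pool(cmp, pars, ca2cam = 0.3, ca4cam = 0.1, camb = 1,
                          can_cam = 0.05, can_ca2 = 0.02, can_ca4 = 0.1)
    for (ca in c(0.1, 1, 30)) {
      d <- cam_rhs(pool, ca)
      expect_lt(abs(sum(d[c("d_cam_free", "d_ca2cam", "d_ca4cam", "d_camb")])),
                1e-10)
      dn <- can_rhs(pool)
      # complex formation balances CaM-species consumption exactly
      expect_lt(abs(dn[["d_can_cam"]] + dn[["d_cam_free"]]), 1e-12)
      expect_lt(abs(dn[["d_can_ca2"]] + dn[["d_ca2cam"]]), 1e-12)
      expect_lt(abs(dn[["d_can_ca4"]] + dn[["d_ca4cam"]]), 1e-12)
    }
  }
})

test_that("integrated pool equilibrium matches the algebraic mass-action oracle", {
  cfg <- model_config()
  pars <- cfg$signaling$myoplasm
  for (ca in c(0.1, 0.5, 2)) {
    eq <- cam_equilibrium(ca, pars)
    pool <- signaling_pool("myoplasm", pars)
    pool <- pool_integrate(pool, ca, t_end = 400, dt = 2e-3)
    # fast species equilibrate tightly; the slow CaN-Ca4CaM complex to ~1e-3
    expect_rel_equal(pool$state[["ca2cam"]], eq$ca2cam, 1e-4)
    expect_rel_equal(pool$state[["ca4cam"]], eq$ca4cam, 1e-4)
    expect_rel_equal(pool$state[["camb"]], eq$camb, 1e-4)
    if (eq$can_ca4 > 1e-8) {
      expect_rel_equal(pool$state[["can_ca4"]], eq$can_ca4, 5e-3)
    }
  }
})

test_that("dyadic buffering yields more free Ca4CaM than myoplasmic at matched conditions", {
  cfg <- model_config()
  dy <- cfg$signaling$dyad
  my <- cfg$signaling$myoplasm
  # put both pools at the same total CaM and the same local Ca; only the
  # compartment-specific buffer rate constants differ
  my_matched <- utils::modifyList(dy, my[c("kon_b", "koff_b")])
  ca <- 10
  eq_dyad <- cam_equilibrium(ca, dy)
  eq_myo <- cam_equilibrium(ca, my_matched)
  expect_gt(eq_dyad$ca4cam, eq_myo$ca4cam)
})

test_that("CaMKII steady state matches the fixed point of its rate law", {
  cfg <- model_config()
  pars <- cfg$signaling$dyad
  ca4 <- 5
  pool <- signaling_pool("dyad", pars, ca4cam = ca4)
  # hold ca4cam fixed and iterate the activation ODE only
  act <- 0
  dt <- 1e-3
  for (i in 1:40000) {
    act <- act + dt * (pars$camkii_ka * ca4 * (1 - act) - pars$camkii_kb * act)
  }
  fixed <- uniroot(function(a) pars$camkii_ka * ca4 * (1 - a) - pars$camkii_kb * a,
                   c(0, 1), tol = 1e-12)$root
  expect_rel_equal(act, fixed, 1e-6)
})

test_that("cycle averaging is exact for constant and square-wave signals", {
  t <- seq(0, 1000, by = 0.1)
  out <- active_levels(t, rep(3.5, length(t)), period_ms = 1000)
  expect_equal(out$average, 3.5)
  # square wave, 20% duty
  sig <- ifelse((t %% 1000) < 200, 1, 0)
  out <- active_levels(t, sig, period_ms = 1000)
  expect_rel_equal(out$average, 0.2, 1e-2)
  expect_error(active_levels(t[1:100], sig[1:100], 1000), "full cycle")
})

test_that("pool validation rejects invalid states", {
  expect_error(signaling_pool("dyad", ca2cam = -1), "negative")
  expect_error(signaling_pool("dyad", camkii = 1.5), "\\[0, 1\\]")
  cfg <- model_config()
  expect_error(signaling_pool("myoplasm", ca2cam = 2 * cfg$signaling$myoplasm$cam_tot),
               "exceed")
  pool <- signaling_pool("dyad")
  expect_error(cam_rhs(pool, -0.1), "non-negative")
})
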
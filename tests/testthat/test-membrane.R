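# Markov channel generators, CDI, facilitation, release flux, luminal
# sensor, NCX and PMCA.

null_space_occupancy <- function(Q) {
  # steady state of a frozen generator: null-space of Q with sum 1
  n <- nrow(Q)
  A <- rbind(Q, rep(1, n))
  b <- c(rep(0, n), 1)
  qr.solve(A, b)
}

test_that("xi facilitation reduces to 550 at zero signalling in both forms", {
  expect_equal(xi_facilitation(0, 0, "new"), 550)
  expect_equal(xi_facilitation(0, 0, "classic"), 550)
  expect_equal(xi_facilitation(10, 5, "classic"), 550 + 60 + 5)
  # the denominator clamp keeps xi finite near the singular activation level
  expect_true(is.finite(xi_facilitation(120, 0, "new")))
  expect_error(xi_facilitation(-1, 0), "non-negative")
})

test_that("LCC generator columns sum to zero and frozen steady state matches the null space", {
  cfg <- model_config()
  for (V in c(-40, 10)) {
    for (kii in c(0, 50, 90)) {
      Q <- lcc_generator(V, kii, 80, cfg)
      expect_lt(max(abs(colSums(Q))), 1e-10)
      expect_true(all(Q[row(Q) != col(Q)] >= 0))
      ss <- null_space_occupancy(Q)
      # integrate the master equation from a random start (implicit Euler,
      # unconditionally stable for the stiff gating rates)
      p <- c(0.4, 0.3, 0.1, 0.1, 0.05, 0.05)
      M <- solve(diag(6) - 5e-3 * Q)
      for (i in 1:8000) p <- as.numeric(M %*% p)
      expect_lt(max(abs(p - ss)), 1e-6)
      expect_rel_equal(sum(p), 1, 1e-9)
    }
  }
})

test_that("RyR generator obeys the generator convention and rest stability", {
  cfg <- model_config()
  Q <- ryr_generator(0.1, 0, 0, cfg)
  expect_lt(max(abs(colSums(Q))), 1e-10)
  ss <- null_space_occupancy(Q)
  expect_lt(ss[2], 1e-3)  # open probability at diastolic mouth Ca
  # frozen-generator steady state equals the null space across inputs
  for (ca in c(1, 50, 300)) {
    for (l in c(0, 0.4)) {
      Q <- ryr_generator(ca, 40, l, cfg)
      ss <- null_space_occupancy(Q)
      p <- c(1, 0, 0, 0)
      for (i in 1:40000) p <- p + 5e-4 * as.numeric(Q %*% p)
      expect_lt(max(abs(p - ss)), 1e-5)
    }
  }
  # opening accelerates with mouth Ca and CaMKII
  k1 <- ryr_generator(100, 0, 0, cfg)[2, 1]
  expect_gt(ryr_generator(200, 0, 0, cfg)[2, 1], k1)
  expect_gt(ryr_generator(100, 80, 0, cfg)[2, 1], k1)
  expect_error(ryr_generator(-1, 0, 0, cfg), "invalid")
})

test_that("CDI gate relaxes monoexponentially toward its Ca-dependent target", {
  cfg <- model_config()
  # no Ca: gate recovers to 1
  g <- 0.2
  for (i in 1:4000) g <- cdi_update(g, 0, 1e-3, cfg)
  expect_rel_equal(g, 1, 1e-6)
  # step in Ca: exact exponential with the configured time constant
  tau <- cfg$lcc$cdi_tau
  kca <- cfg$lcc$cdi_kca
  yinf <- 1 / (1 + (kca / kca)^cfg$lcc$cdi_hill)  # ca = kca -> 1/2
  g <- cdi_update(1, kca, tau, cfg)
  expect_rel_equal(g, yinf + (1 - yinf) * exp(-1), 1e-9)
  # higher Ca, deeper inactivation target
  g_hi <- 1
  g_lo <- 1
  for (i in 1:100) {
    g_hi <- cdi_update(g_hi, 200, 1e-3, cfg)
    g_lo <- cdi_update(g_lo, 20, 1e-3, cfg)
  }
  expect_lt(g_hi, g_lo)
})

test_that("L-type flux is zero with closed channels and scales with the cAMP factor", {
  cfg <- model_config()
  expect_equal(i_cal(10, 0, 1, 2.67, 0.1, cfg), 0)
  i1 <- i_cal(10, 0.5, 0.8, 2.67, 0.1, cfg)
  i2 <- i_cal(10, 0.5, 0.8, 24.58, 0.1, cfg)
  expect_lt(i1, 0)  # inward
  expect_rel_equal(i2 / i1, f_camp_ical(24.58) / f_camp_ical(2.67), 1e-10)
})

test_that("RyR flux is linear in the gradient and vanishes appropriately", {
  cfg <- model_config()
  expect_equal(ryr_flux(0, 1000, 10, cfg), 0)
  expect_equal(ryr_flux(0.5, 500, 500, cfg), 0)
  j1 <- ryr_flux(0.5, 1000, 500, cfg)
  j2 <- ryr_flux(0.5, 1500, 500, cfg)
  expect_rel_equal(j2 / j1, 2, 1e-12)
})

test_that("luminal sensor decays with a full store and rises after depletion", {
  cfg <- model_config()
  # full store: inhibition decays to ~0
  l <- 0.8
  for (i in 1:20000) l <- l + 1e-3 * luminal_sensor_rhs(l, 1600, cfg)
  expect_lt(l, 1e-3)
  # depleted store: inhibition rises with the configured on-rate
  l <- 0
  l2 <- l + 1e-3 * luminal_sensor_rhs(0, 300, cfg)
  on <- 1 / (1 + exp((300 - cfg$ryr$lum_th) / cfg$ryr$lum_w))
  expect_rel_equal(l2, 1e-3 * cfg$ryr$kl_on * on * 1, 1e-6)
  for (i in 1:20000) l <- l + 1e-3 * luminal_sensor_rhs(l, 300, cfg)
  expect_gt(l, 0.8)
})

test_that("NCX vanishes at its reversal potential and Na+ loading impedes extrusion", {
  cfg <- model_config()
  na <- 1e4; ca <- 0.5
  na_o <- cfg$cell$na_o; ca_o <- cfg$cell$ca_o
  v_rev <- 26.71 * (3 * log(na_o / na) - log(ca_o / ca))
  expect_lt(abs(ncx_flux(v_rev, na, ca, cfg = cfg)),
            1e-6 * abs(ncx_flux(v_rev - 30, na, ca, cfg = cfg)))
  # forward-mode extrusion decreases when myoplasmic Na+ rises by 30%
  j_lo <- ncx_flux(-40, na, ca, cfg = cfg)
  j_hi <- ncx_flux(-40, 1.3 * na, ca, cfg = cfg)
  expect_gt(j_lo, 0)
  expect_lt(j_hi, j_lo)
  # closed-form check on a grid of conditions
  p <- cfg$ncx
  for (V in c(-60, -20, 20)) {
    for (nai in c(8e3, 1.4e4)) {
      vhat <- V / 26.71
      num <- exp(p$eta * vhat) * nai^3 * ca_o -
        exp((p$eta - 1) * vhat) * na_o^3 * ca
      den <- (p$km_na^3 + na_o^3) * (p$km_ca + ca_o) *
        (1 + p$ksat * exp((p$eta - 1) * vhat))
      allo <- 1 / (1 + (p$km_act / ca)^p$act_hill)
      expect_rel_equal(ncx_flux(V, nai, ca, cfg = cfg),
                       -p$k_scale * allo * num / den, 1e-12)
    }
  }
})

test_that("PMCA is Hill-type with half-activation at km", {
  cfg <- model_config()
  expect_equal(pmca_flux(0, cfg), 0)
  expect_rel_equal(pmca_flux(cfg$pmca$km, cfg), cfg$pmca$vmax / 2, 1e-12)
  expect_true(all(diff(pmca_flux(seq(0, 5, 0.1), cfg)) > 0))
})

test_that("compiled generator matches the R-level LCC generator", {
  cfg <- config_fast_test()
  st <- initial_state(cfg)
  probe <- ffrcell:::cpp_rhs_probe(unname(st$y), as.numeric(st$grid_ca),
                                   as.numeric(st$grid_buf), unclass(cfg),
                                   2.67, 10)
  kii <- st$y[["dyad_camkii"]] * cfg$signaling$dyad$camkii_scale
  can <- st$y[["dyad_can_ca4"]] / cfg$signaling$dyad$can_tot *
    cfg$signaling$dyad$can_scale
  Q_r <- lcc_generator(10, kii, can, cfg)
  expect_equal(unname(probe$lcc_Q), unname(Q_r), tolerance = 1e-10)
})
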
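# Reaction-diffusion in the dyadic cleft: stability bound, conservation,
# point-source behaviour, and the superposition kernel.

test_that("explicit step refuses a stability-violating dt", {
  g <- dyad_grid(config_fast_test())
  bound <- dyad_stability_dt(g)
  expect_error(diffusion_step(g, dt = 2 * bound), "stability bound")
  expect_silent(diffusion_step(g, dt = 0.5 * bound))
})

test_that("a uniform field is unchanged by diffusion", {
  g <- dyad_grid(config_fast_test(), ca0 = 0.7)
  g2 <- diffusion_step(g, dt = 0.5 * dyad_stability_dt(g))
  expect_equal(g2$ca, g$ca, tolerance = 1e-12)
})

test_that("sealed grid conserves total Ca through point release and spreading", {
  g <- dyad_grid(config_fast_test(), ca0 = 0.1)
  dt <- 0.9 * dyad_stability_dt(g)
  m0 <- dyad_mass(g)
  g <- diffusion_step(g, dt, sources = list(list(node = c(3, 5), d_ca = 500)))
  m_add <- dyad_mass(g)
  for (i in 1:400) g <- diffusion_step(g, dt)
  expect_rel_equal(dyad_mass(g), m_add, 1e-8)
  expect_true(all(g$ca >= 0))
  # the deposit spread out: peak node no longer dominates
  expect_lt(max(g$ca) / mean(g$ca), 3)
})

test_that("compiled ADI and explicit updates agree and conserve mass", {
  cfg <- config_fast_test()
  set.seed(42)
  g0 <- matrix(runif(100, 0.1, 50), 10, 10)
  b0 <- matrix(5, 10, 10)
  m0 <- sum(ffrcell:::cpp_grid_mass(as.numeric(g0), as.numeric(b0),
                                    unclass(cfg)))
  adi <- list(grid_ca = as.numeric(g0), grid_buf = as.numeric(b0))
  expl <- adi
  for (i in 1:200) {
    adi <- ffrcell:::cpp_grid_step(adi$grid_ca, adi$grid_buf, unclass(cfg),
                                   1e-5, TRUE)
    expl <- ffrcell:::cpp_grid_step(expl$grid_ca, expl$grid_buf, unclass(cfg),
                                    1e-5, FALSE)
  }
  m_adi <- sum(ffrcell:::cpp_grid_mass(adi$grid_ca, adi$grid_buf, unclass(cfg)))
  m_exp <- sum(ffrcell:::cpp_grid_mass(expl$grid_ca, expl$grid_buf, unclass(cfg)))
  expect_rel_equal(m_adi, m0, 1e-8)
  expect_rel_equal(m_exp, m0, 1e-8)
  # both schemes relax toward the same equilibrium field
  expect_lt(max(abs(adi$grid_ca - expl$grid_ca)) / mean(expl$grid_ca), 0.05)
})

test_that("steady point-source profile matches the thin-slab analytic solution", {
  # continuous injection at the axis with an absorbing rim; at steady state
  # the stationary buffer is equilibrated, so the profile solves the pure
  # 2-D (slab-averaged) diffusion problem c(r) = Q ln(R/r) / (2 pi D H)
  cfg <- model_config()
  g <- dyad_grid(cfg, ca0 = 0)
  nr <- g$nr; nz <- g$nz
  gca <- as.numeric(g$ca); gbuf <- as.numeric(g$buf)
  dt <- 1e-6; d_ca <- 0.5
  for (i in 1:20000) {
    gca[1 + nr * (nz - 1)] <- gca[1 + nr * (nz - 1)] + d_ca
    res <- ffrcell:::cpp_grid_step(gca, gbuf, unclass(cfg), dt, TRUE)
    gca <- res$grid_ca; gbuf <- res$grid_buf
    gca[seq(nr, nr * nz, by = nr)] <- 0  # absorbing rim
  }
  vol_src <- 2 * pi * g$w_r[1] * g$dr * g$dz
  q <- d_ca * vol_src / dt
  r <- (seq_len(nr) - 1) * g$dr
  pred <- q / (2 * pi * g$d_eff * cfg$dyad$z_um) * log(max(r) / r)
  prof <- rowMeans(matrix(gca, nr, nz))
  for (i in 4:12) expect_rel_equal(prof[i], pred[i], 0.10)
  expect_true(all(diff(prof[2:nr]) < 0))
})

test_that("mouth superposition is additive and decays with distance", {
  g <- dyad_grid(config_fast_test(), ca0 = 0.25)
  expect_equal(local_ca_at(g, "ryr"), g$ca[1, 10])
  one <- local_ca_at(g, "ryr", list(list(location = "lcc", q = 100)))
  two <- local_ca_at(g, "ryr", list(list(location = "lcc", q = 100),
                                    list(location = "lcc", q = 100)))
  expect_equal(two - g$ca[1, 10], 2 * (one - g$ca[1, 10]), tolerance = 1e-12)
  # self increment (regularized at one axial step) exceeds the cross increment
  self <- local_ca_at(g, "lcc", list(list(location = "lcc", q = 100)))
  expect_gt(self - g$ca[1, 1], one - g$ca[1, 10])
  expect_error(local_ca_at(g, "mitochondrion"), "unknown")
})

test_that("grid refinement changes the release-phase mouth value only modestly", {
  base <- cached_run(1, "basal")
  fine <- run_to_steady_state(
    config_fast_test(list(dyad = list(nr = 20, nz = 20, lcc_node = c(1, 1),
                                      ryr_node = c(1, 20)))), 1, "basal")
  m1 <- max(base$traces$ca_ryr_mouth)
  m2 <- max(fine$traces$ca_ryr_mouth)
  expect_lt(abs(m2 - m1) / m1, 0.10)
})
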
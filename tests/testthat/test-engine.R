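# Protocol construction, integrator order, determinism, rest stability,
# self-convergence, and the whole-cell Ca2+ balance audit.

test_that("protocols translate frequency into period and reject bad pulses", {
  p <- build_protocol(5)
  expect_equal(p$period_ms, 200)
  expect_equal(p$pulse_ms, 50)
  expect_equal(p$v_hold, -40)
  expect_equal(p$v_step, 10)
  expect_equal(build_protocol(0.5)$period_ms, 2000)
  expect_error(build_protocol(5, list(pulse_ms = 250)), "shorter")
  expect_error(build_protocol(0.1), "\\[0.5, 12\\]")
  expect_error(build_protocol(5, list(nonsense = 1)), "unknown")
})

test_that("the fixed-step schemes integrate a linear system at order >= 4", {
  set.seed(7)
  A <- matrix(rnorm(16, sd = 2), 4, 4)
  A <- A - diag(5, 4)  # well-damped test system
  y0 <- rnorm(4)
  t_end <- 0.5
  exact <- as.numeric(as.matrix(Matrix::expm(A * t_end)) %*% y0)
  err <- function(dt, classic) {
    y <- ffrcell:::cpp_merson_linear(A, y0, dt, round(t_end / dt), classic)
    max(abs(y - exact))
  }
  for (classic in c(FALSE, TRUE)) {
    e1 <- err(1e-2, classic)
    e2 <- err(5e-3, classic)
    order <- log2(e1 / e2)
    expect_gt(order, 3.7)
  }
  # one Merson step matches the matrix exponential to O(dt^5)
  dt <- 1e-3
  y1 <- ffrcell:::cpp_merson_linear(A, y0, dt, 1, FALSE)
  expect_lt(max(abs(y1 - as.numeric(as.matrix(Matrix::expm(A * dt)) %*% y0))), 1e-9)
})

test_that("identical configurations give bitwise-identical cycle summaries", {
  cfg <- config_fast_test()
  st <- initial_state(cfg)
  pr <- build_protocol(4, cfg = cfg)
  a <- run_cycle(st, pr, cfg, 2.67, record = FALSE)
  b <- run_cycle(st, pr, cfg, 2.67, record = FALSE)
  expect_identical(a$summary, b$summary)
  expect_identical(a$state$y, b$state$y)
})

test_that("the solved quiescent state is a fixed point of the dynamics", {
  cfg <- config_fast_test()
  st <- resting_state(cfg)
  quiet <- build_protocol(1, list(v_step = -40), cfg)  # no pulses
  ref <- st$y[c("ca_myo", "na_myo", "ca_lsr", "ca_jsr")]
  out <- NULL
  for (i in 1:5) {
    out <- run_cycle(st, quiet, cfg, 2.67, record = FALSE)
    st <- out$state
  }
  drift <- abs(st$y[names(ref)] - ref) / abs(ref)
  expect_lt(max(drift), 1e-2)   # settle residual of the analytic solve
  # and all RyR openings stay negligible at rest
  expect_lt(out$summary[["peak_ryr_open"]], 1e-3)
})

test_that("halving the production step leaves the final-cycle peaks essentially unchanged", {
  # self-convergence at the production step (1 us) against its half
  cfg1 <- config_fast_test(list(engine = list(n_cycles = 3, dt = 1e-6)))
  cfg2 <- config_fast_test(list(engine = list(n_cycles = 3, dt = 5e-7)))
  r1 <- run_to_steady_state(cfg1, 4, "basal")
  r2 <- run_to_steady_state(cfg2, 4, "basal")
  expect_rel_equal(r1$summary[["peak_force"]], r2$summary[["peak_force"]], 0.005)
  expect_rel_equal(r1$summary[["peak_ca"]], r2$summary[["peak_ca"]], 0.005)
})

test_that("convergence stop reports its criterion and the cap is honoured", {
  cfg <- config_fast_test(list(engine = list(n_cycles = 3, convergence_tol = 0)))
  run <- run_to_steady_state(cfg, 4, "basal")
  expect_equal(run$n_cycles_run, 3)
  expect_equal(run$stop_reason, "cycle_cap")
  run2 <- cached_run(0.5, "basal")
  expect_true(run2$stop_reason %in% c("converged", "cycle_cap"))
  if (run2$converged) {
    cy <- run2$cycles
    n <- nrow(cy)
    expect_lt(abs(cy$peak_force[n] - cy$peak_force[n - 1]) /
                cy$peak_force[n], cfg$engine$convergence_tol + 5e-4 + 1e-9)
  }
})

test_that("whole-cell Ca balance closes on paced and sealed cycles", {
  run <- cached_run(1, "basal")
  bal <- ca_balance_audit(run)
  expect_true(attr(bal, "ok"))
  expect_lt(bal$residual_rel, 0.005)
  # sealed cell: no LCC flux, no NCX/PMCA -> total Ca exactly conserved
  sealed <- config_fast_test(list(
    lcc = list(g_flux = 1e-12), ncx = list(k_scale = 1e-12),
    pmca = list(vmax = 1e-12), engine = list(n_cycles = 2)))
  r <- run_to_steady_state(sealed, 4, "basal")
  a <- r$audit
  expect_lt(abs(a$total_ca_end - a$total_ca_start) / a$total_ca_start, 1e-8)
})

test_that("Markov occupancies stay on the simplex through pacing", {
  run <- cached_run(4, "basal")
  y <- run$state$y
  expect_rel_equal(sum(y[paste0("lcc", 0:5)]), 1, 1e-9)
  expect_rel_equal(sum(y[paste0("ryr", 0:3)]), 1, 1e-9)
  expect_true(all(y[paste0("lcc", 0:5)] >= -1e-12))
  expect_true(all(y[paste0("ryr", 0:3)] >= -1e-12))
})

test_that("steady-state periodicity holds at the stop point", {
  run <- cached_run(0.5, "basal")
  cy <- run$cycles
  n <- nrow(cy)
  expect_rel_equal(cy$peak_ca[n], cy$peak_ca[n - 1], 5e-3)
  expect_rel_equal(cy$pre_release_jsr[n], cy$pre_release_jsr[n - 1], 5e-3)
})

test_that("CaM mass is conserved through a full paced cycle", {
  cfg <- config_fast_test()
  run <- cached_run(1, "basal")
  y <- run$state$y
  for (cmp in c("dyad", "myo")) {
    pars <- cfg$signaling[[if (cmp == "dyad") "dyad" else "myoplasm"]]
    tot <- y[[paste0(cmp, "_ca2cam")]] + y[[paste0(cmp, "_ca4cam")]] +
      y[[paste0(cmp, "_camb")]] + y[[paste0(cmp, "_can_cam")]] +
      y[[paste0(cmp, "_can_ca2")]] + y[[paste0(cmp, "_can_ca4")]]
    expect_lt(tot, pars$cam_tot * (1 + 1e-8))
    expect_gt(tot, 0)
    # free CaM implied by conservation stays non-negative
    expect_gte(pars$cam_tot - tot, -1e-8 * pars$cam_tot)
  }
})
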
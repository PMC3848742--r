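# Metric extraction, FFR assembly, EC-coupling gain, phase loops, flux shares.

test_that("cycle metrics recover analytic extrema and slopes of a synthetic sine", {
  t_ms <- seq(0, 1000, by = 0.1)
  w <- 2 * pi * 2  # 2 Hz, amplitude 0.5, offset 1
  tr <- tibble::tibble(
    time_ms = t_ms,
    ca_myo = 1 + 0.5 * sin(w * t_ms / 1000),
    force_norm = 0.4 + 0.2 * sin(w * t_ms / 1000),
    sl = 1.9 - 0.05 * sin(w * t_ms / 1000),
    i_cal_pa = -100 * sin(w * t_ms / 1000)^2,
    ryr_open = 0.5 * abs(sin(w * t_ms / 1000)),
    j_ryr = 0 * t_ms, ca_jsr = 1000 + 100 * cos(w * t_ms / 1000))
  m <- cycle_metrics(tr)
  expect_rel_equal(m$peak_ca, 1.5, 1e-3)
  expect_rel_equal(m$min_ca, 0.5, 1e-3)
  expect_rel_equal(m$r_rise, 0.5 * w, 1e-3)
  expect_rel_equal(m$r_decay, 0.5 * w, 1e-3)
  expect_rel_equal(m$r_act, 0.2 * w, 1e-3)
  expect_rel_equal(m$peak_ical_pa, 100, 1e-3)
  # constant traces: peak equals min, zero rates
  flat <- dplyr::mutate(tr, ca_myo = 1, force_norm = 0.3)
  mf <- cycle_metrics(flat)
  expect_equal(mf$peak_ca, mf$min_ca)
  expect_equal(mf$r_rise, 0)
  expect_equal(mf$r_decay, 0)
})

test_that("metric extraction is pure", {
  run <- cached_run(1, "basal")
  expect_identical(cycle_metrics(run$traces), cycle_metrics(run$traces))
})

test_that("a single-frequency FFR table reports itself as the argmax", {
  run <- cached_run(1, "basal")  # warm the cache so this stays cheap
  tbl <- ffr_curve(1, "basal", config_fast_test())
  expect_equal(nrow(tbl), 1)
  expect_equal(attr(tbl, "argmax_force"), 1)
  expect_true(all(c("frequency", "beta_state", "peak_force", "camp") %in%
                    names(tbl)))
})

test_that("EC-coupling gain exceeds one with CICR and equals one when disabled in both runs", {
  g <- ec_gain(1, "basal", config_fast_test())
  expect_gt(g, 1.2)
  off <- config_fast_test(list(ryr = list(enabled = FALSE)))
  with_off <- run_to_steady_state(off, 1, "basal")
  denom <- run_to_steady_state(off, 1, "basal")
  expect_rel_equal(with_off$summary[["peak_ca"]] / denom$summary[["peak_ca"]],
                   1, 1e-9)
})

test_that("gain recomputed from exported traces equals the summary-based ratio", {
  cfg <- config_fast_test()
  on <- cached_run(2, "basal")
  off <- run_to_steady_state(config_fast_test(list(ryr = list(enabled = FALSE))),
                             2, "basal")
  g_traces <- max(on$traces$ca_myo) / max(off$traces$ca_myo)
  g_summary <- on$summary[["peak_ca"]] / off$summary[["peak_ca"]]
  expect_rel_equal(g_traces, g_summary, 1e-4)
})

test_that("phase loop is ordered, has consistent area, and degenerates for constant Ca", {
  run <- cached_run(1, "basal")
  pl <- phase_loop(run)
  expect_equal(nrow(pl$loop), nrow(run$traces))
  expect_gte(pl$area, 0)
  # shoelace area agrees with trapezoidal quadrature of F dCa around the loop
  ca <- pl$loop$ca; fo <- pl$loop$force
  quad <- abs(sum((c(ca[-1], ca[1]) - ca) * (fo + c(fo[-1], fo[1])) / 2))
  expect_rel_equal(pl$area, quad, 1e-6)
  # degenerate loop
  fake <- run
  fake$traces$ca_myo <- rep(1, nrow(fake$traces))
  pl0 <- phase_loop(fake)
  expect_lt(pl0$area, 1e-9)
})

test_that("SERCA share equals one when the competing pathways are disabled", {
  run <- cached_run(1, "basal")
  tweaked <- run
  tweaked$traces$j_ncx <- 0
  tweaked$traces$j_pmca <- 0
  expect_equal(serca_share(tweaked), 1)
  expect_lt(serca_share(run), 1)
})

test_that("tidy, glance and autoplot methods produce well-formed output", {
  run <- cached_run(1, "basal")
  td <- tidy(run)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("time_ms", "ca_myo", "frequency") %in% names(td)))
  gl <- glance(run)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("frequency", "peak_ca", "converged") %in% names(gl)))
  p1 <- ggplot2::autoplot(run)
  expect_s3_class(p1, "ggplot")
  tbl <- ffr_curve(1, "basal", config_fast_test())
  p2 <- ggplot2::autoplot(tbl)
  expect_s3_class(p2, "ggplot")
})
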
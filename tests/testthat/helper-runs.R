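# Cached steady-state pacing runs shared across test files.  Everything uses
# the fast-test configuration (10x10 cleft grid, 10 us step, convergence-stop
# pacing capped at 50 cycles).

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(frequency, beta_state = "basal", overlay = NULL) {
  key <- paste0(frequency, "_", beta_state, "_",
                paste(deparse(overlay), collapse = ""))
  if (is.null(.run_cache[[key]])) {
    cfg <- config_fast_test(overlay)
    .run_cache[[key]] <- run_to_steady_state(cfg, frequency, beta_state)
  }
  .run_cache[[key]]
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}

options(testthat.progress.max_fails = 1000)
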
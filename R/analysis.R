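# Post-processing: per-cycle transient and force metrics, force-frequency
# tables, EC-coupling gain, force-Ca phase loops, and flux-share analysis.
# All results are tibbles; derivative-based rates use centered differences
# on the saved sampling grid, decoupled from the integrator step.

#' Per-cycle transient and force metrics from traces
#'
#' Extrema and maximum first-derivative magnitudes of the myoplasmic Ca2+
#' transient and the normalized force, plus channel/SR summary values, on
#' one steady cycle.
#'
#' @param traces Steady-cycle trace tibble (from an `ffr_run`).
#' @return One-row tibble: `peak_ca`, `min_ca` (uM), `r_rise`, `r_decay`
#'   (uM/s), `peak_force`, `min_force`, `r_act`, `r_relax` (1/s), `min_sl`
#'   (um), `peak_ical_pa`, `peak_ryr_open`, `peak_j_ryr`, `pre_release_jsr`,
#'   `post_release_jsr`.
#' @export
cycle_metrics <- function(traces) {
  tr <- traces
  t_s <- tr$time_ms / 1000
  dmax <- function(x) {
    if (length(x) < 3) return(c(0, 0))
    d <- (x[-(1:2)] - x[1:(length(x) - 2)]) / (t_s[-(1:2)] - t_s[1:(length(t_s) - 2)])
    c(max(c(d, 0)), max(c(-d, 0)))
  }
  dca <- dmax(tr$ca_myo)
  dfo <- dmax(tr$force_norm)
  tibble::tibble(
    peak_ca = max(tr$ca_myo), min_ca = min(tr$ca_myo),
    r_rise = dca[1], r_decay = dca[2],
    peak_force = max(tr$force_norm), min_force = min(tr$force_norm),
    r_act = dfo[1], r_relax = dfo[2],
    min_sl = min(tr$sl),
    peak_ical_pa = max(abs(tr$i_cal_pa)),
    peak_ryr_open = max(tr$ryr_open),
    peak_j_ryr = max(tr$j_ryr),
    pre_release_jsr = max(tr$ca_jsr), post_release_jsr = min(tr$ca_jsr)
  )
}

#' Force-frequency response table
#'
#' Runs [run_to_steady_state()] at each frequency and assembles per-frequency
#' steady-cycle metrics.  The attribute `argmax_force` reports the frequency
#' of maximal peak force.
#'
#' @param frequencies Pacing frequencies (Hz), at least one.
#' @param beta_state `"basal"`, `"maximal"`, or `"both"`.
#' @param cfg Model configuration.
#' @param gain Also compute EC-coupling gain per frequency (two runs each).
#' @return An `ffr_table` tibble: one row per (frequency, beta_state) with
#'   the [cycle_metrics()] columns plus signalling averages and `camp`.
#' @export
ffr_curve <- function(frequencies, beta_state = "basal",
                      cfg = config_fast_test(), gain = FALSE) {
  stopifnot(length(frequencies) >= 1)
  states <- if (beta_state == "both") c("basal", "maximal") else beta_state
  rows <- purrr::map(states, function(bs) {
    purrr::map(sort(frequencies), function(f) {
      run <- run_to_steady_state(cfg, f, bs)
      m <- cycle_metrics(run$traces)
      m$frequency <- f
      m$beta_state <- bs
      m$camp <- run$camp
      m$avg_camkii_dyad <- run$summary[["avg_camkii_dyad"]]
      m$avg_can_dyad <- run$summary[["avg_can_dyad"]]
      m$avg_can_frac_dyad <- run$summary[["avg_can_frac_dyad"]]
      m$avg_camkii_myo <- run$summary[["avg_camkii_myo"]]
      m$avg_na <- run$summary[["avg_na"]]
      m$converged <- run$converged
      if (gain) m$gain <- ec_gain(f, bs, cfg)
      m
    })
  })
  tbl <- dplyr::bind_rows(purrr::flatten(rows))
  tbl <- dplyr::select(tbl, "frequency", "beta_state", dplyr::everything())
  attr(tbl, "argmax_force") <- tbl$frequency[which.max(tbl$peak_force)]
  class(tbl) <- c("ffr_table", class(tbl))
  tbl
}

#' EC-coupling gain at one frequency
#'
#' Ratio of the steady-state peak myoplasmic Ca2+ transient with CICR
#' enabled to the peak transient with RyR release disabled (trigger Ca2+
#' alone), everything else identical.
#'
#' @param frequency Pacing frequency (Hz).
#' @param beta_state Beta-adrenergic state.
#' @param cfg Model configuration.
#' @return Gain (>= 1 for a functioning release unit).
#' @export
ec_gain <- function(frequency, beta_state = "basal", cfg = config_fast_test()) {
  with_ryr <- run_to_steady_state(cfg, frequency, beta_state)
  cfg_off <- model_config(utils::modifyList(
    strip_overlay(cfg), list(ryr = list(enabled = FALSE))))
  without <- run_to_steady_state(cfg_off, frequency, beta_state)
  denom <- max(without$summary[["peak_ca"]], 1e-12)
  with_ryr$summary[["peak_ca"]] / denom
}

# reduce a full config back to an overlay list acceptable to model_config()
strip_overlay <- function(cfg) unclass(cfg)

#' Force-Ca phase loop and contraction-relaxation coupling point
#'
#' Orders the steady cycle as a (Ca, force) loop and locates the CRCP: the
#' point during relaxation where the trajectory crosses the steady-state
#' force-Ca curve.  Loop area is computed by the shoelace formula.
#'
#' @param run An `ffr_run`.
#' @return List: `loop` (tibble `ca`, `force`, `phase`), `crcp` (named
#'   vector `ca`, `force`, or `NA` if no crossing), `area`.
#' @export
phase_loop <- function(run) {
  tr <- run$traces
  ca <- tr$ca_myo; fo <- tr$force_norm
  ipk <- which.max(fo)
  phase <- rep("contraction", length(ca))
  if (ipk < length(ca)) phase[(ipk + 1):length(ca)] <- "relaxation"
  ss <- force_ca_curve(ca, run$camp, run$cfg)$force_norm
  diffs <- fo - ss
  crcp <- c(ca = NA_real_, force = NA_real_)
  if (ipk < length(ca)) {
    rel <- seq(ipk + 1, length(ca))
    sgn <- sign(diffs[rel])
    cross <- which(sgn[-1] != sgn[-length(sgn)])
    if (length(cross)) {
      i1 <- rel[cross[1]]; i2 <- i1 + 1
      w <- abs(diffs[i1]) / (abs(diffs[i1]) + abs(diffs[i2]))
      crcp <- c(ca = (1 - w) * ca[i1] + w * ca[i2],
                force = (1 - w) * fo[i1] + w * fo[i2])
    }
  }
  area <- abs(sum(ca * c(fo[-1], fo[1]) - c(ca[-1], ca[1]) * fo)) / 2
  list(loop = tibble::tibble(ca = ca, force = fo, phase = phase),
       crcp = crcp, area = area)
}

#' SERCA share of systolic Ca2+ removal
#'
#' Integrates the SERCA uptake flux, the NCX Ca2+ efflux (forward-mode part)
#' and the PMCA flux from the time of peak myoplasmic Ca2+ to the end of the
#' cycle, and returns the SERCA fraction.
#'
#' @param run An `ffr_run`.
#' @return Fraction in (0, 1).
#' @export
serca_share <- function(run) {
  tr <- run$traces
  ipk <- which.max(tr$ca_myo)
  win <- seq(ipk, nrow(tr))
  dt <- diff(tr$time_ms[win]) / 1000
  mid <- function(x) (x[-1] + x[-length(x)]) / 2
  s <- sum(mid(pmax(tr$j_serca[win], 0)) * dt)
  n <- sum(mid(pmax(tr$j_ncx[win], 0)) * dt)
  p <- sum(mid(pmax(tr$j_pmca[win], 0)) * dt)
  s / (s + n + p)
}

# ---- broom-style methods and plotting -----------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a steady-state run
#'
#' One row per recorded sample (the steady cycle), as a tibble.
#'
#' @param x An `ffr_run`.
#' @param ... Unused.
#' @return A tibble of traces.
#' @export
tidy.ffr_run <- function(x, ...) {
  dplyr::mutate(x$traces, frequency = x$frequency, beta_state = x$beta_state)
}

#' One-row summary of a steady-state run
#'
#' @param x An `ffr_run`.
#' @param ... Unused.
#' @return One-row tibble of steady-cycle metrics and run bookkeeping.
#' @export
glance.ffr_run <- function(x, ...) {
  m <- cycle_metrics(x$traces)
  dplyr::bind_cols(
    tibble::tibble(frequency = x$frequency, beta_state = x$beta_state,
                   camp = x$camp, converged = x$converged,
                   n_cycles_run = x$n_cycles_run),
    m)
}

#' Plot the steady-cycle traces of a run
#'
#' @param object An `ffr_run`.
#' @param signals Trace columns to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ffr_run <- function(object,
                             signals = c("ca_myo", "force_norm", "ca_jsr",
                                         "i_cal_pa"),
                             ...) {
  tr <- tidyr::pivot_longer(object$traces[, c("time_ms", signals)],
                            -"time_ms", names_to = "signal")
  ggplot2::ggplot(tr, ggplot2::aes(.data$time_ms, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  title = sprintf("%g Hz, %s", object$frequency,
                                  object$beta_state))
}

#' Plot a force-frequency table
#'
#' @param object An `ffr_table`.
#' @param metric Column to plot against frequency.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ffr_table <- function(object, metric = "peak_force", ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$frequency, .data[[metric]],
                                       colour = .data$beta_state)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "pacing frequency (Hz)", y = metric)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
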
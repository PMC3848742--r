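# Time integration of the full coupled system under voltage-clamp pacing.
#
# The compiled core advances one pacing cycle at a time with the fixed-step
# Merson Runge-Kutta scheme (classic RK4 optional); the R layer owns
# protocol construction, initial conditions, the steady-state pacing loop
# with its convergence stop, and the whole-cell Ca2+ balance audit.

state_names <- c(
  "ca_myo", "na_myo", "ca_lsr", "ca_jsr", "csq", "buf_myo",
  paste0("lcc", 0:5), "cdi", paste0("ryr", 0:3), "lum_inh",
  paste0("dyad_", c("ca2cam", "ca4cam", "camb", "can_cam", "can_ca2",
                    "can_ca4", "camkii")),
  paste0("myo_", c("ca2cam", "ca4cam", "camb", "can_cam", "can_ca2",
                   "can_ca4", "camkii")),
  "plb_dp", "tni_p", "ca_trop_h", "ca_trop_l", "perm", "xb_pre", "xb_post",
  "sl", "ncx_allo", "int_ncx", "int_pmca", "int_serca", "int_leak"
)

#' Voltage-clamp pacing protocol
#'
#' Square command pulses from the holding potential, one per cycle.
#'
#' @param frequency Pacing frequency (Hz), in `[0.5, 12]`.
#' @param overrides Named list: any of `v_hold` (mV), `v_step` (mV),
#'   `pulse_ms`, `n_cycles`, `convergence_tol`.
#' @param cfg Model configuration supplying defaults.
#' @return A `pacing_protocol` list with `frequency`, `period_ms`,
#'   `pulse_ms`, `v_hold`, `v_step`, `n_cycles`, `convergence_tol`.
#' @export
build_protocol <- function(frequency, overrides = NULL, cfg = model_config()) {
  if (!is.numeric(frequency) || frequency < 0.5 || frequency > 12) {
    stop("`frequency` must lie in [0.5, 12] Hz", call. = FALSE)
  }
  p <- list(frequency = frequency, period_ms = 1000 / frequency,
            pulse_ms = cfg$protocol$pulse_ms, v_hold = cfg$protocol$v_hold,
            v_step = cfg$protocol$v_step, n_cycles = cfg$engine$n_cycles,
            min_cycles = cfg$engine$min_cycles %||% 1,
            convergence_tol = cfg$engine$convergence_tol)
  for (nm in names(overrides %||% list())) {
    if (!nm %in% names(p)) stop("unknown protocol field: ", nm, call. = FALSE)
    p[[nm]] <- overrides[[nm]]
  }
  if (p$pulse_ms >= p$period_ms) {
    stop("pulse duration must be shorter than the cycle period", call. = FALSE)
  }
  structure(p, class = "pacing_protocol")
}

#' Resting initial state of the cell
#'
#' All pools at their algebraic equilibrium for the resting Ca2+ level, SR
#' loaded to its resting free level, channels closed and available.
#'
#' @param cfg Model configuration.
#' @param camp cAMP level (uM) used for PKA-dependent states.
#' @param ca_rest Resting myoplasmic / dyadic Ca2+ (uM).
#' @return List with `y` (named ODE state), `grid_ca`, `grid_buf` matrices.
#' @export
initial_state <- function(cfg = model_config(), camp = 2.67, ca_rest = 0.1) {
  m <- cfg$mechanics
  y <- stats::setNames(numeric(length(state_names)), state_names)
  y["ca_myo"] <- ca_rest
  y["na_myo"] <- 1e4
  y["ca_lsr"] <- 1450
  y["ca_jsr"] <- 1450
  y["csq"] <- csq_equilibrium(1450, cfg)
  y["buf_myo"] <- cfg$buffers$myo_tot * cfg$buffers$myo_kon * ca_rest /
    (cfg$buffers$myo_kon * ca_rest + cfg$buffers$myo_koff)
  y["lcc0"] <- 1
  y["cdi"] <- 1 / (1 + (ca_rest / cfg$lcc$cdi_kca)^cfg$lcc$cdi_hill)
  y["ryr0"] <- 1
  for (cmp in c("dyad", "myo")) {
    pars <- cfg$signaling[[if (cmp == "dyad") "dyad" else "myoplasm"]]
    eq <- cam_equilibrium(ca_rest, pars)
    y[paste0(cmp, "_ca2cam")] <- eq$ca2cam
    y[paste0(cmp, "_ca4cam")] <- eq$ca4cam
    y[paste0(cmp, "_camb")] <- eq$camb
    y[paste0(cmp, "_can_cam")] <- eq$can_cam
    y[paste0(cmp, "_can_ca2")] <- eq$can_ca2
    y[paste0(cmp, "_can_ca4")] <- eq$can_ca4
    act <- pars$camkii_ka * eq$ca4cam
    y[paste0(cmp, "_camkii")] <- act / (act + pars$camkii_kb)
  }
  can_m <- y["myo_can_ca4"] / cfg$signaling$myoplasm$can_tot *
    cfg$signaling$myoplasm$can_scale
  kii_m <- y["myo_camkii"] * cfg$signaling$myoplasm$camkii_scale
  y["plb_dp"] <- plb_steady(can_m, kii_m, camp, cfg)
  y["tni_p"] <- m$kon_ti * delta_pka(camp) /
    (m$kon_ti * delta_pka(camp) + m$koff_ti)
  on <- m$kon_t * (1 - y["tni_p"]) * ca_rest
  y["ca_trop_h"] <- on / (on + m$koff_ht)
  y["ca_trop_l"] <- on / (on + m$koff_lt)
  w <- perm_weight(y[["ca_trop_h"]], cfg)
  y["perm"] <- m$knp * w^2 / (m$knp * w^2 + m$kpn)
  y["sl"] <- m$sl0
  y["ncx_allo"] <- 1 / (1 + (cfg$ncx$km_act / ca_rest)^cfg$ncx$act_hill)
  g <- dyad_grid(cfg, ca0 = ca_rest)
  list(y = y, grid_ca = g$ca, grid_buf = g$buf)
}

#' Quiescent resting state solving the flux balance
#'
#' Solves the unstimulated fixed point of the cell at the holding potential:
#' myoplasmic Ca2+ where PMCA extrusion balances the L-type window entry and
#' the exchanger's net flux (with the channel at its frozen-generator steady
#' state and the allosteric gate at its own fixed point), the LSR level
#' where net SERCA uptake balances the constitutive leak, and Na+ where the
#' pump balances background entry plus exchanger stoichiometry.  All other
#' states take their algebraic equilibria at the solved Ca2+.
#'
#' @param cfg Model configuration.
#' @param camp cAMP level (uM).
#' @return List with `y`, `grid_ca`, `grid_buf`, as [initial_state()].
#' @export
resting_state <- function(cfg = model_config(), camp = 2.67) {
  v_hold <- cfg$protocol$v_hold
  # L-type window occupancy at the holding potential (zero-signalling rates)
  Q <- lcc_generator(v_hold, 0, 0, cfg)
  occ <- qr.solve(rbind(Q, rep(1, 6)), c(rep(0, 6), 1))
  o_rest <- max(occ[3], 0)
  v_dyad <- cfg$cell$n_dcu * 2 * pi *
    (cfg$dyad$r_um / (cfg$dyad$nr - 1)) * (cfg$dyad$z_um / (cfg$dyad$nz - 1)) *
    sum(dyad_grid(cfg)$w_r) * cfg$dyad$nz * 1e-3
  window_in <- function(ca) {
    cdi <- 1 / (1 + (ca / cfg$lcc$cdi_kca)^cfg$lcc$cdi_hill)
    flux <- -i_cal(v_hold, o_rest, cdi, camp, ca, cfg)  # uM/s dyad volume
    max(flux, 0) * v_dyad / cfg$cell$vol_myo            # uM/s myo volume
  }
  lsr_for <- function(ca) {
    f <- function(lsr) {
      serca_flux(ca, lsr, 1 - plb_steady(0, 0, camp, cfg), 0, camp, cfg) -
        cfg$sr$leak * (lsr - ca)
    }
    stats::uniroot(f, c(ca + 1, 1e4), tol = 1e-8)$root
  }
  na_for <- function(ca) {
    # Na+ where the pump balances background entry plus the exchanger's
    # stoichiometric import at this Ca2+ (coupled fixed point)
    f <- function(na) {
      nah <- na^3 / (na^3 + cfg$na$nak_km^3)
      cfg$na$bg + 3 * ncx_flux(v_hold, na, ca, cfg = cfg) -
        cfg$na$nak_vmax * nah
    }
    stats::uniroot(f, c(10, 5e5), tol = 1e-6)$root
  }
  net <- function(ca) {
    j_ncx <- ncx_flux(v_hold, na_for(ca), ca, cfg = cfg)
    window_in(ca) - j_ncx - pmca_flux(ca, cfg)
  }
  ca_rest <- stats::uniroot(net, c(0.02, 2), tol = 1e-9)$root
  lsr <- lsr_for(ca_rest)
  st <- initial_state(cfg, camp, ca_rest = ca_rest)
  st$y["ca_lsr"] <- lsr
  st$y["ca_jsr"] <- lsr  # transfer equilibrates exactly at rest
  st$y["csq"] <- csq_equilibrium(lsr, cfg)
  st$y["na_myo"] <- na_for(ca_rest)
  st$y[paste0("lcc", 0:5)] <- occ
  st
}

#' Run one pacing cycle
#'
#' Advances the cell through a single voltage-clamp cycle with the compiled
#' core.
#'
#' @param state List as returned by [initial_state()] (or a previous call).
#' @param protocol A `pacing_protocol`.
#' @param cfg Model configuration.
#' @param camp cAMP level (uM).
#' @param record Record traces at the output sampling interval.
#' @return List: updated `state`, `traces` (tibble if recorded), `audit`,
#'   `summary` (named per-cycle metrics).
#' @export
run_cycle <- function(state, protocol, cfg = model_config(), camp = 2.67,
                      record = FALSE) {
  res <- cpp_cycle_run(
    unname(state$y), as.numeric(state$grid_ca), as.numeric(state$grid_buf),
    strip_cfg(cfg), camp,
    protocol$period_ms / 1000, protocol$pulse_ms / 1000,
    protocol$v_hold, protocol$v_step,
    cfg$engine$dt, cfg$engine$output_dt, record,
    identical(cfg$engine$scheme, "rk4"))
  nr <- cfg$dyad$nr; nz <- cfg$dyad$nz
  st <- list(y = stats::setNames(res$y, state_names),
             grid_ca = matrix(res$grid_ca, nr, nz),
             grid_buf = matrix(res$grid_buf, nr, nz))
  traces <- if (record) tibble::as_tibble(as.data.frame(res$traces)) else NULL
  list(state = st, traces = traces, audit = res$audit, summary = res$summary)
}

strip_cfg <- function(cfg) unclass(cfg)

#' Pace the cell to steady state
#'
#' Runs voltage-clamp cycles at the given frequency until the peak
#' myoplasmic Ca2+ transient and peak force change by less than the
#' configured relative tolerance between consecutive cycles, or until
#' `n_cycles` is reached; then records one further cycle as the steady-state
#' cycle.  With `convergence_tol = 0` exactly `n_cycles` are run.
#'
#' @param cfg Model configuration.
#' @param frequency Pacing frequency (Hz).
#' @param beta_state `"basal"` or `"maximal"` beta-adrenergic stimulation
#'   (overridden by `cfg$neuro$beta_state` if `NULL`).
#' @param overrides Protocol overrides, see [build_protocol()].
#' @return An `ffr_run` object: `traces` (steady-cycle tibble), `cycles`
#'   (per-cycle summary tibble), `state`, `audit` of the recorded cycle,
#'   `frequency`, `beta_state`, `camp`, `converged`, `stop_reason`.
#' @export
run_to_steady_state <- function(cfg = config_fast_test(), frequency = 1,
                                beta_state = NULL, overrides = NULL) {
  beta_state <- beta_state %||% cfg$neuro$beta_state
  camp <- if (is.finite(cfg$neuro$camp_override %||% NA)) {
    cfg$neuro$camp_override
  } else {
    camp_level(frequency, beta_state, cfg$neuro$camp_method)
  }
  protocol <- build_protocol(frequency, overrides, cfg)
  state <- initial_state(cfg, camp)
  tol <- protocol$convergence_tol
  prev <- NULL
  cycles <- vector("list", protocol$n_cycles)
  converged <- FALSE
  n_run <- 0
  for (k in seq_len(protocol$n_cycles)) {
    out <- run_cycle(state, protocol, cfg, camp, record = FALSE)
    state <- out$state
    cycles[[k]] <- out$summary
    n_run <- k
    if (!is.null(prev) && tol > 0 && k >= protocol$min_cycles) {
      dca <- abs(out$summary[["peak_ca"]] - prev[["peak_ca"]]) /
        max(prev[["peak_ca"]], 1e-12)
      dfo <- abs(out$summary[["peak_force"]] - prev[["peak_force"]]) /
        max(prev[["peak_force"]], 1e-12)
      if (dca < tol && dfo < tol) {
        converged <- TRUE
        break
      }
    }
    prev <- out$summary
  }
  final <- run_cycle(state, protocol, cfg, camp, record = TRUE)
  cycles <- cycles[seq_len(n_run)]
  cyc_tbl <- tibble::as_tibble(do.call(rbind, cycles))
  cyc_tbl$cycle <- seq_len(nrow(cyc_tbl))
  res <- list(traces = final$traces, cycles = cyc_tbl, state = final$state,
              audit = final$audit, summary = final$summary,
              frequency = frequency, beta_state = beta_state, camp = camp,
              protocol = protocol, cfg = cfg,
              converged = converged,
              stop_reason = if (converged) "converged" else "cycle_cap",
              n_cycles_run = n_run)
  class(res) <- "ffr_run"
  res
}

#' @export
print.ffr_run <- function(x, ...) {
  cat(sprintf(
    "<ffr_run> %.3g Hz, %s beta-stimulation (cAMP %.3g uM)\n", x$frequency,
    x$beta_state, x$camp))
  cat(sprintf("  %d cycles run (%s); peak [Ca]myo %.3g uM, peak force %.3g\n",
              x$n_cycles_run, x$stop_reason, x$summary[["peak_ca"]],
              x$summary[["peak_force"]]))
  invisible(x)
}

#' Whole-cell Ca2+ balance audit
#'
#' Compares the change in total cellular Ca2+ (free + all buffers + SR +
#' cleft) over the recorded cycle against the net sarcolemmal flux integral
#' (L-type influx minus NCX and PMCA efflux).  At steady state both sides
#' are close to zero; on any cycle they must agree within the stated
#' tolerance.
#'
#' @param run An `ffr_run`.
#' @param tol Relative tolerance on the residual (default 0.005).
#' @return Tibble with the pathway integrals (uM pL), the residual and its
#'   relative size; attribute `ok` reports the tolerance check.
#' @export
ca_balance_audit <- function(run, tol = 0.005) {
  a <- run$audit
  delta <- a$total_ca_end - a$total_ca_start
  net <- a$influx_cal - a$efflux_ncx - a$efflux_pmca
  scale <- max(abs(a$influx_cal), abs(a$efflux_ncx) + abs(a$efflux_pmca),
               1e-12)
  resid <- delta - net
  out <- tibble::tibble(
    delta_total_ca = delta, influx_cal = a$influx_cal,
    efflux_ncx = a$efflux_ncx, efflux_pmca = a$efflux_pmca,
    uptake_serca = a$uptake_serca, net_sarcolemmal = net,
    residual = resid, residual_rel = abs(resid) / scale)
  attr(out, "ok") <- abs(resid) / scale <= tol
  out
}

#' Write run outputs to a directory
#'
#' `traces.csv` (one row per sample), `metrics.json` (per-cycle summary of
#' the steady cycle), `balance.json` (Ca audit), and `config.yaml` (the
#' configuration snapshot).  Field ordering is deterministic.
#'
#' @param run An `ffr_run`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_outputs <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(run$traces, file.path(dir, "traces.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(run$summary), file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(as.list(ca_balance_audit(run)),
                       file.path(dir, "balance.json"),
                       auto_unbox = TRUE, digits = NA)
  save_config(run$cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
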
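# Calmodulin-based frequency decoding.
#
# Each compartment (dyadic cleft, myoplasm) carries a pool of calmodulin that
# binds Ca2+ cooperatively in two sequential 2-Ca steps (C-lobe then N-lobe),
# a generic CaM buffer, CaMKII whose expected active-subunit fraction is
# driven by Ca4CaM, and calcineurin (CaN) which reversibly binds apo-CaM,
# Ca2CaM and Ca4CaM; the Ca4CaM-CaN complex is the active species and
# dissociates slowly, so CaN becomes near-constitutively active at high rates
# while CaMKII keeps grading with frequency.  The dyadic pool uses its own
# (weaker) CaM-buffer rate constants, producing the free-CaM enrichment that
# supports strong local CaMKII activation.
#
# Concentrations are in uM, time in seconds.  "Activation" state variables
# are fractions; the coupling variables CaMKIIact / CaNact used in rate laws
# elsewhere are fraction x compartment scale (see `camkii_scale`, `can_scale`
# in the `signaling` config block).

#' Construct a per-compartment signalling pool
#'
#' @param compartment `"dyad"` or `"myoplasm"`.
#' @param pars Named list of rate constants and totals for this compartment
#'   (defaults from [model_config()], block `signaling`).
#' @param ca2cam,ca4cam,camb Initial CaM species concentrations (uM):
#'   Ca2CaM (C-lobe loaded), Ca4CaM (fully loaded) and buffer-bound apo-CaM.
#' @param can_cam,can_ca2,can_ca4 Initial CaN complex concentrations (uM):
#'   CaN bound to apo-CaM, Ca2CaM and Ca4CaM (the last is the active complex).
#' @param camkii Initial active CaMKII fraction.
#' @return A `signaling_pool` list with state and parameters.
#' @export
signaling_pool <- function(compartment = c("dyad", "myoplasm"), pars = NULL,
                           ca2cam = 0, ca4cam = 0, camb = 0,
                           can_cam = 0, can_ca2 = 0, can_ca4 = 0, camkii = 0) {
  compartment <- match.arg(compartment)
  if (is.null(pars)) {
    cfg <- model_config()
    pars <- cfg$signaling[[compartment]]
  }
  state <- c(ca2cam = ca2cam, ca4cam = ca4cam, camb = camb,
             can_cam = can_cam, can_ca2 = can_ca2, can_ca4 = can_ca4,
             camkii = camkii)
  pool <- list(compartment = compartment, state = state, pars = pars)
  class(pool) <- "signaling_pool"
  validate_pool(pool)
  pool
}

validate_pool <- function(pool) {
  s <- pool$state; p <- pool$pars
  if (any(s[c("ca2cam", "ca4cam", "camb")] < 0) ||
      any(s[c("can_cam", "can_ca2", "can_ca4")] < 0)) {
    stop("negative species concentration in signalling pool", call. = FALSE)
  }
  if (s[["camkii"]] < 0 || s[["camkii"]] > 1) {
    stop("active CaMKII fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cam_free(pool) < -1e-9 * p$cam_tot) {
    stop("CaM species exceed total CaM", call. = FALSE)
  }
  if (can_free(pool) < -1e-9 * p$can_tot) {
    stop("CaN complexes exceed total CaN", call. = FALSE)
  }
  invisible(pool)
}

#' @rdname signaling_pool
#' @param pool A `signaling_pool`.
#' @export
cam_free <- function(pool) {
  s <- pool$state
  pool$pars$cam_tot - s[["ca2cam"]] - s[["ca4cam"]] - s[["camb"]] -
    s[["can_cam"]] - s[["can_ca2"]] - s[["can_ca4"]]
}

#' @rdname signaling_pool
#' @export
can_free <- function(pool) {
  s <- pool$state
  pool$pars$can_tot - s[["can_cam"]] - s[["can_ca2"]] - s[["can_ca4"]]
}

#' Time-derivatives of the CaM species and CaM buffer
#'
#' Two sequential cooperative 2-Ca binding steps (C-lobe, then N-lobe) plus
#' reversible binding of apo-CaM to a stationary buffer.  Returns derivatives
#' for the explicit species and for free CaM, which sum to zero (CaM mass
#' conservation); Ca bound in the lobes is accounted by the caller.
#'
#' @param pool A `signaling_pool`.
#' @param ca_local Free Ca2+ in the compartment (uM), non-negative.
#' @return Named numeric: `d_cam_free`, `d_ca2cam`, `d_ca4cam`, `d_camb` (uM/s).
#' @export
cam_rhs <- function(pool, ca_local) {
  if (!is.finite(ca_local) || ca_local < 0) {
    stop("`ca_local` must be a non-negative concentration", call. = FALSE)
  }
  p <- pool$pars; s <- pool$state
  cam <- cam_free(pool)
  jc <- p$kon_c * ca_local^2 * cam - p$koff_c * s[["ca2cam"]]
  jn <- p$kon_n * ca_local^2 * s[["ca2cam"]] - p$koff_n * s[["ca4cam"]]
  jb <- p$kon_b * cam * (p$buf_tot - s[["camb"]]) - p$koff_b * s[["camb"]]
  c(d_cam_free = -jc - jb, d_ca2cam = jc - jn, d_ca4cam = jn, d_camb = jb)
}

#' Time-derivative of the active CaMKII fraction
#'
#' Deterministic ODE for the expected active-subunit fraction: activation is
#' first-order in free Ca4CaM, deactivation first-order in the active
#' fraction.  The slow deactivation rate makes the cycle-averaged level an
#' integrator of pacing frequency.
#'
#' @param pool A `signaling_pool`.
#' @return d(active fraction)/dt in 1/s.
#' @export
camkii_rhs <- function(pool) {
  p <- pool$pars; s <- pool$state
  p$camkii_ka * s[["ca4cam"]] * (1 - s[["camkii"]]) - p$camkii_kb * s[["camkii"]]
}

#' Time-derivatives of the CaN-CaM complexes
#'
#' Mass-action reversible binding of apo-CaM, Ca2CaM and Ca4CaM to free CaN.
#' The Ca4CaM-CaN complex (the active species) dissociates slowly
#' (`koff_ca4` well below 1/s), which makes dyadic CaN near-constitutively
#' active above ~4 Hz.  Returns complex derivatives plus the matching
#' decrements of the CaM species so that combined CaM mass is conserved.
#'
#' @param pool A `signaling_pool`.
#' @return Named numeric: `d_can_cam`, `d_can_ca2`, `d_can_ca4` and the CaM
#'   species counterparts `d_cam_free`, `d_ca2cam`, `d_ca4cam` (uM/s).
#' @export
can_rhs <- function(pool) {
  p <- pool$pars; s <- pool$state
  can <- can_free(pool)
  j1 <- p$kon_cam * can * cam_free(pool) - p$koff_cam * s[["can_cam"]]
  j2 <- p$kon_ca2 * can * s[["ca2cam"]] - p$koff_ca2 * s[["can_ca2"]]
  j4 <- p$kon_ca4 * can * s[["ca4cam"]] - p$koff_ca4 * s[["can_ca4"]]
  c(d_can_cam = j1, d_can_ca2 = j2, d_can_ca4 = j4,
    d_cam_free = -j1, d_ca2cam = -j2, d_ca4cam = -j4)
}

#' Advance a signalling pool at fixed local Ca2+
#'
#' Forward-Euler sub-stepped integration of the combined pool ODEs, used for
#' equilibrium studies and as the reference path in tests.  The engine
#' integrates the same right-hand sides in compiled code.
#'
#' @param pool A `signaling_pool`.
#' @param ca_local Fixed free Ca2+ (uM).
#' @param t_end Integration horizon (s).
#' @param dt Step (s).
#' @return The advanced pool.
#' @export
pool_integrate <- function(pool, ca_local, t_end, dt = 1e-4) {
  n <- ceiling(t_end / dt)
  s <- pool$state
  for (i in seq_len(n)) {
    pool$state <- s
    dc <- cam_rhs(pool, ca_local)
    dn <- can_rhs(pool)
    dk <- camkii_rhs(pool)
    s[["ca2cam"]] <- s[["ca2cam"]] + dt * (dc[["d_ca2cam"]] + dn[["d_ca2cam"]])
    s[["ca4cam"]] <- s[["ca4cam"]] + dt * (dc[["d_ca4cam"]] + dn[["d_ca4cam"]])
    s[["camb"]]   <- s[["camb"]] + dt * dc[["d_camb"]]
    s[["can_cam"]] <- s[["can_cam"]] + dt * dn[["d_can_cam"]]
    s[["can_ca2"]] <- s[["can_ca2"]] + dt * dn[["d_can_ca2"]]
    s[["can_ca4"]] <- s[["can_ca4"]] + dt * dn[["d_can_ca4"]]
    s[["camkii"]]  <- s[["camkii"]] + dt * dk
  }
  pool$state <- s
  pool
}

#' Algebraic mass-action equilibrium of the CaM scheme
#'
#' Solves the equilibrium of the two-step Ca-CaM scheme plus CaM buffer (and
#' optionally the CaN complexes) at fixed Ca2+ by one-dimensional
#' root-finding on free CaM, independent of any ODE integration.
#'
#' @param ca Free Ca2+ (uM).
#' @param pars Compartment parameter list (as in [signaling_pool()]).
#' @param with_can Include CaN complex equilibria (default `TRUE`).
#' @return Named list of equilibrium species concentrations (uM).
#' @export
cam_equilibrium <- function(ca, pars, with_can = TRUE) {
  p <- pars
  r2 <- p$kon_c * ca^2 / p$koff_c          # ca2cam / cam_free
  r4 <- r2 * p$kon_n * ca^2 / p$koff_n     # ca4cam / cam_free
  # CaN complexes at equilibrium, given free CaN:
  q1 <- p$kon_cam / p$koff_cam
  q2 <- p$kon_ca2 / p$koff_ca2 * r2
  q4 <- p$kon_ca4 / p$koff_ca4 * r4
  total_err <- function(cam) {
    camb <- p$buf_tot * cam * p$kon_b / (p$kon_b * cam + p$koff_b)
    can_bound <- 0
    if (with_can && p$can_tot > 0) {
      canf <- p$can_tot / (1 + q1 * cam + q2 * cam + q4 * cam)
      can_bound <- canf * cam * (q1 + q2 + q4)
    }
    cam * (1 + r2 + r4) + camb + can_bound - p$cam_tot
  }
  cam <- stats::uniroot(total_err, c(0, p$cam_tot), tol = 1e-12)$root
  camb <- p$buf_tot * cam * p$kon_b / (p$kon_b * cam + p$koff_b)
  canf <- if (with_can && p$can_tot > 0) {
    p$can_tot / (1 + (q1 + q2 + q4) * cam)
  } else p$can_tot
  list(cam_free = cam, ca2cam = r2 * cam, ca4cam = r4 * cam, camb = camb,
       can_free = canf, can_cam = q1 * cam * canf, can_ca2 = q2 * cam * canf,
       can_ca4 = q4 * cam * canf)
}

#' Cycle-averaged activation levels from a trace
#'
#' Time-averages the named signal over exactly one steady-state cycle
#' (trapezoidal quadrature on the saved sampling grid) and also returns the
#' final instantaneous value for use in rate laws.
#'
#' @param time Time vector (ms), covering at least one full cycle.
#' @param signal Signal vector (same length).
#' @param period_ms Cycle period (ms).
#' @return List with `average` and `instantaneous`.
#' @export
active_levels <- function(time, signal, period_ms) {
  stopifnot(length(time) == length(signal))
  t_end <- time[length(time)]
  sel <- time >= t_end - period_ms - 1e-9
  if (sum(sel) < 3 || (t_end - time[sel][1]) < period_ms * (1 - 1e-6)) {
    stop("trace does not cover one full cycle", call. = FALSE)
  }
  tt <- time[sel]; ss <- signal[sel]
  avg <- sum(diff(tt) * (ss[-1] + ss[-length(ss)]) / 2) / (tt[length(tt)] - tt[1])
  list(average = avg, instantaneous = ss[length(ss)])
}
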
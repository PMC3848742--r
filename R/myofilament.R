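# Isometric force generation: regulatory Ca2+-troponin binding with
# PKA-mediated TnI desensitization, cooperative thin-filament activation, and
# a reduced three-state crossbridge cycle with cAMP- and temperature-scaled
# kinetics.  Fractions dimensionless, Ca uM, rates 1/s, sarcomere length um.

#' Regulatory Ca2+-troponin binding derivatives
#'
#' High- and low-affinity apparent regulatory site occupancies:
#' `d/dt = konT * TnIu * ca * (1 - occ) - koff * occ`, with the on-rate
#' scaled by the unphosphorylated TnI fraction (the PKA desensitization
#' mechanism).
#'
#' @param ca_myo Myoplasmic Ca2+ (uM).
#' @param ca_trop_h,ca_trop_l Site occupancies (fractions).
#' @param tni_u Unphosphorylated TnI fraction.
#' @param cfg Model configuration.
#' @return Named numeric `d_ca_trop_h`, `d_ca_trop_l` (1/s).
#' @export
troponin_rhs <- function(ca_myo, ca_trop_h, ca_trop_l, tni_u,
                         cfg = model_config()) {
  m <- cfg$mechanics
  on <- m$kon_t * tni_u * ca_myo
  c(d_ca_trop_h = on * (1 - ca_trop_h) - m$koff_ht * ca_trop_h,
    d_ca_trop_l = on * (1 - ca_trop_l) - m$koff_lt * ca_trop_l)
}

#' TnI phosphorylation derivative
#'
#' `d(TnIp)/dt = konTI * deltaPKA(camp) * (1 - TnIp) - koffTI * TnIp`;
#' `TnIu = 1 - TnIp` exactly.
#'
#' @param tni_p Phosphorylated TnI fraction.
#' @param camp cAMP (uM).
#' @param cfg Model configuration.
#' @return d(tni_p)/dt (1/s).
#' @export
tni_rhs <- function(tni_p, camp, cfg = model_config()) {
  if (tni_p < 0 || tni_p > 1) stop("tni_p must lie in [0, 1]", call. = FALSE)
  m <- cfg$mechanics
  m$kon_ti * delta_pka(camp) * (1 - tni_p) - m$koff_ti * tni_p
}

#' Crossbridge rate set scaled by cAMP and temperature
#'
#' The four crossbridge-cycle rates (attachment `fapp`, power-stroke forward
#' `hf` and reverse `hb`, detachment `gxb`) are scaled by the cAMP force
#' factor and by `q10^((T - t_ref)/10)`; the regulatory-unit switching rates
#' (500 / 50 1/s) and the reverse attachment `gapp` are not scaled.
#'
#' @param camp cAMP (uM).
#' @param temperature Bath temperature (degC), within 15-40.
#' @param cfg Model configuration.
#' @return Named list `fapp`, `gapp`, `hf`, `hb`, `gxb` (1/s).
#' @export
xb_rate_scaling <- function(camp, temperature = NULL, cfg = model_config()) {
  m <- cfg$mechanics
  temperature <- temperature %||% cfg$cell$temp
  if (temperature < 15 || temperature > 40) {
    stop("temperature outside the valid 15-40 degC range", call. = FALSE)
  }
  s <- f_camp_force(camp) * m$q10^((temperature - m$t_ref) / 10)
  list(fapp = m$fapp * s, gapp = m$gapp, hf = m$hf * s, hb = m$hb * s,
       gxb = m$gxb * s)
}

perm_weight <- function(reg, cfg) {
  m <- cfg$mechanics
  reg^m$perm_hill / (reg^m$perm_hill + m$perm50^m$perm_hill)
}

#' Crossbridge-cycle steady state at full activation
#'
#' Solves the three-state attachment cycle (non-attached, pre-rotation,
#' post-rotation) at permissive fraction 1; the post-rotation occupancy is
#' the normalization constant for `force_norm`.
#'
#' @param rates Output of [xb_rate_scaling()].
#' @return List `pre`, `post` at full activation.
#' @export
xb_steady <- function(rates) {
  r <- rates
  # 0 = fapp*(1 - pre - post) - (gapp + hf)*pre + hb*post
  # 0 = hf*pre - (hb + gxb)*post
  M <- matrix(c(r$fapp + r$gapp + r$hf, r$fapp - r$hb,
                -r$hf, r$hb + r$gxb), 2, 2, byrow = TRUE)
  x <- solve(M, c(r$fapp, 0))
  list(pre = x[1], post = x[2])
}

#' Full mechanics right-hand side
#'
#' Cooperative thin-filament activation (regulatory-unit permissive fraction
#' driven by high-affinity regulatory Ca binding with steep cooperativity)
#' and the three-state crossbridge cycle; isometric force is the post-stroke
#' occupancy normalized to maximal activation, and sarcomere length follows
#' internal shortening against a series elastance.
#'
#' @param state Named numeric with `ca_trop_h`, `ca_trop_l`, `tni_p`, `perm`,
#'   `xb_pre`, `xb_post`, `sl`.
#' @param ca_myo Myoplasmic Ca2+ (uM).
#' @param camp cAMP (uM).
#' @param cfg Model configuration.
#' @return List with `deriv` (named vector matching `state`), `force_norm`.
#' @export
crossbridge_rhs <- function(state, ca_myo, camp, cfg = model_config()) {
  m <- cfg$mechanics
  r <- xb_rate_scaling(camp, cfg$cell$temp, cfg)
  tr <- troponin_rhs(ca_myo, state[["ca_trop_h"]], state[["ca_trop_l"]],
                     1 - state[["tni_p"]], cfg)
  w <- perm_weight(state[["ca_trop_h"]], cfg)
  P <- state[["perm"]]
  d_perm <- m$knp * w^2 * (1 - P) - m$kpn * P
  n_avail <- max(P - state[["xb_pre"]] - state[["xb_post"]], 0)
  d_pre <- r$fapp * n_avail - (r$gapp + r$hf) * state[["xb_pre"]] +
    r$hb * state[["xb_post"]]
  d_post <- r$hf * state[["xb_pre"]] - (r$hb + r$gxb) * state[["xb_post"]]
  ss <- xb_steady(r)
  force <- state[["xb_post"]] / ss$post
  d_sl <- (m$sl0 - m$sl_gain * force - state[["sl"]]) / m$sl_tau
  list(deriv = c(ca_trop_h = unname(tr[1]), ca_trop_l = unname(tr[2]),
                 tni_p = tni_rhs(state[["tni_p"]], camp, cfg),
                 perm = d_perm, xb_pre = d_pre, xb_post = d_post, sl = d_sl),
       force_norm = force)
}

#' Steady-state force-Ca2+ relationship
#'
#' Algebraic fixed point of the mechanics at constant Ca2+: troponin
#' occupancy, permissive fraction and crossbridge cycle all at steady state.
#' Sigmoidal with Hill coefficient > 1; used for the phase-loop
#' contraction-relaxation coupling point.
#'
#' @param ca Myoplasmic Ca2+ (uM), vectorised.
#' @param camp cAMP (uM).
#' @param cfg Model configuration.
#' @return Tibble with `ca`, `force_norm`.
#' @export
force_ca_curve <- function(ca, camp = 2.67, cfg = model_config()) {
  m <- cfg$mechanics
  r <- xb_rate_scaling(camp, cfg$cell$temp, cfg)
  tni_p <- m$kon_ti * delta_pka(camp) /
    (m$kon_ti * delta_pka(camp) + m$koff_ti)
  on <- m$kon_t * (1 - tni_p) * ca
  trop_h <- on / (on + m$koff_ht)
  w <- perm_weight(trop_h, cfg)
  P <- m$knp * w^2 / (m$knp * w^2 + m$kpn)
  # at steady state the crossbridge occupancies are linear in the permissive
  # fraction, so normalized force equals P (rate scalings cancel)
  tibble::tibble(ca = ca, force_norm = P)
}
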
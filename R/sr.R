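# SR Ca2+ handling: SERCA with CaMKII/PLB/cAMP regulation, LSR -> jSR
# transfer, calsequestrin buffering in the jSR, and the phospholamban
# phosphorylation balance.

#' Phospholamban dephosphorylation balance
#'
#' `d(PLBdp)/dt = k12 * (1 + (CaNact*1e-4)^2) * PLBp
#'              - k21 * (1 + (CaMKIIact*1e5)^2 + F_cAMP,SERCA^2) * PLBdp`
#' with `PLBp = 1 - PLBdp` enforced algebraically.  CaN drives
#' dephosphorylation, CaMKII and cAMP drive phosphorylation.  Signalling
#' inputs are the myoplasmic activated levels in their compartment-scaled
#' units.
#'
#' @param plb_dp Dephosphorylated PLB fraction, in `[0, 1]`.
#' @param can_act Myoplasmic activated CaN (scaled units).
#' @param camkii_act Myoplasmic activated CaMKII (scaled units).
#' @param camp cAMP (uM).
#' @param cfg Model configuration.
#' @return d(plb_dp)/dt (1/s).
#' @export
plb_rhs <- function(plb_dp, can_act, camkii_act, camp, cfg = model_config()) {
  if (plb_dp < 0 || plb_dp > 1) {
    stop("plb_dp must lie in [0, 1]", call. = FALSE)
  }
  p <- cfg$sr
  f <- f_camp_serca(camp)
  k12 <- p$k12_plb * (1 + (can_act * 1e-4)^2)
  k21 <- p$k21_plb * (1 + (camkii_act * 1e5)^2 + f^2)
  k12 * (1 - plb_dp) - k21 * plb_dp
}

#' Algebraic steady state of the PLB balance
#'
#' Fixed point of [plb_rhs()] at constant inputs; the oracle the integrated
#' steady state must match.
#'
#' @inheritParams plb_rhs
#' @return Steady-state dephosphorylated fraction.
#' @export
plb_steady <- function(can_act, camkii_act, camp, cfg = model_config()) {
  p <- cfg$sr
  f <- f_camp_serca(camp)
  k12 <- p$k12_plb * (1 + (can_act * 1e-4)^2)
  k21 <- p$k21_plb * (1 + (camkii_act * 1e5)^2 + f^2)
  k12 / (k12 + k21)
}

#' Effective SERCA parameters under current regulation
#'
#' Maximal rate scales up with phosphorylated PLB (relief of inhibition) and
#' directly with myoplasmic CaMKII; the forward half-activation constant
#' decreases and the backward one increases with CaMKII (monotone laws).
#'
#' @param plb_p Phosphorylated PLB fraction.
#' @param camkii_act Myoplasmic activated CaMKII (scaled units).
#' @param camp cAMP (uM); the PKA-mediated enhancement scales the maximal
#'   rate through the cAMP-SERCA factor normalized to its basal value.
#' @param cfg Model configuration.
#' @return List `vmax_up`, `ec50_fwd`, `ec50_bwd`.
#' @export
serca_params <- function(plb_p, camkii_act, camp = 2.67, cfg = model_config()) {
  p <- cfg$sr
  ck <- camkii_act * 1e5
  camp_fac <- (f_camp_serca(camp) / f_camp_serca(2.67))^p$camp_vmax_exp
  list(
    vmax_up = p$vmax0 * (1 + p$a_plb * plb_p) * (1 + p$a_ck * ck / (1 + ck)) *
      camp_fac,
    ec50_fwd = p$kf0 / (1 + p$bf * ck / (1 + ck)),
    ec50_bwd = p$kr0 * (1 + p$br * ck / (1 + ck))
  )
}

#' Bidirectional SERCA flux (myoplasm -> LSR)
#'
#' Hill-type forward/backward competition:
#' `vmax * (hf - hb) / (1 + hf + hb)` with `hf = (ca_myo/ec50_fwd)^n`,
#' `hb = (ca_lsr/ec50_bwd)^n`.  Strictly increasing in phosphorylated PLB.
#'
#' @param ca_myo Myoplasmic Ca2+ (uM).
#' @param ca_lsr LSR free Ca2+ (uM).
#' @param plb_p Phosphorylated PLB fraction.
#' @param camkii_act Myoplasmic activated CaMKII (scaled units).
#' @param camp cAMP (uM) (enters only through PLB elsewhere; kept for the
#'   module surface).
#' @param cfg Model configuration.
#' @return Net uptake flux (uM/s, myoplasm volume).
#' @export
serca_flux <- function(ca_myo, ca_lsr, plb_p, camkii_act, camp = 2.67,
                       cfg = model_config()) {
  if (ca_myo < 0 || ca_lsr < 0) stop("concentrations must be non-negative", call. = FALSE)
  p <- cfg$sr
  sp <- serca_params(plb_p, camkii_act, camp, cfg)
  hf <- (ca_myo / sp$ec50_fwd)^p$hill
  hb <- (ca_lsr / sp$ec50_bwd)^p$hill
  sp$vmax_up * (hf - hb) / (1 + hf + hb)
}

#' LSR to jSR transfer flux
#'
#' First-order transfer along the intra-SR gradient; the time constant sets
#' the post-release jSR refilling delay.
#'
#' @param ca_lsr,ca_jsr Free Ca2+ (uM).
#' @param cfg Model configuration.
#' @return Flux (uM/s, jSR volume units).
#' @export
lsr_jsr_transfer <- function(ca_lsr, ca_jsr, cfg = model_config()) {
  if (ca_lsr < 0 || ca_jsr < 0) stop("concentrations must be non-negative", call. = FALSE)
  (ca_lsr - ca_jsr) / cfg$sr$tau_tr
}

#' Calsequestrin buffering reaction rate
#'
#' Kinetic binding of jSR free Ca2+ to calsequestrin; conserves total Ca by
#' construction (the same rate leaves the free pool and enters the bound
#' pool).
#'
#' @param ca_jsr jSR free Ca2+ (uM).
#' @param csq_bound Bound Ca2+ (uM).
#' @param cfg Model configuration.
#' @return d(csq_bound)/dt (uM/s); apply `-` to the free pool.
#' @export
csq_buffering <- function(ca_jsr, csq_bound, cfg = model_config()) {
  p <- cfg$sr
  p$csq_kon * ca_jsr * (p$csq_tot - csq_bound) - p$csq_koff * csq_bound
}

#' Calsequestrin equilibrium occupancy
#'
#' @param ca_jsr jSR free Ca2+ (uM).
#' @param cfg Model configuration.
#' @return Equilibrium bound Ca2+ (uM).
#' @export
csq_equilibrium <- function(ca_jsr, cfg = model_config()) {
  p <- cfg$sr
  kd <- p$csq_koff / p$csq_kon
  p$csq_tot * ca_jsr / (ca_jsr + kd)
}
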
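# Sarcolemmal and jSR-membrane Ca2+ transport.
#
# The L-type channel (LCC) is a 6-state Markov chain (two closed, one open,
# three progressively deeper inactivated states) with a separate 2-state
# Ca-dependent inactivation gate; CaMKII/CaN-dependent facilitation scales
# three named rates through the xi term, and cAMP scales the conductance.
# The RyR is a 4-state closed-open-inactivated-refractory ring whose opening
# is triggered by Ca at its dyadic mouth, boosted by CaMKII, and whose
# recovery is held back by a luminal (jSR Ca) sensor.  NCX and PMCA complete
# the sarcolemmal Ca2+ pathways.  Voltages mV, rates 1/s, Ca uM.

#' CaMKII/CaN facilitation term for the L-type channel
#'
#' The default (`form = "new"`) evaluates
#' `550 + A * (1.348 + A^3.22 / (3.135e6 - 0.755 * A^3.22)) + N`
#' with `A = CaMKIIact`, `N = CaNact` and the denominator clamped at a small
#' positive floor; `form = "classic"` evaluates `550 + 6.0 * A + N`.  Both
#' reduce to 550 at zero signalling.
#'
#' @param camkii_act Activated CaMKII level (compartment-scaled units), >= 0.
#' @param can_act Activated CaN level, >= 0.
#' @param form `"new"` or `"classic"`.
#' @return xi (dimensionless rate-scaling term).
#' @export
xi_facilitation <- function(camkii_act, can_act, form = c("new", "classic")) {
  form <- match.arg(form)
  if (any(camkii_act < 0) || any(can_act < 0)) {
    stop("signalling inputs must be non-negative", call. = FALSE)
  }
  if (form == "classic") {
    return(550 + 6.0 * camkii_act + can_act)
  }
  a <- camkii_act^3.22
  den <- pmax(3.135e6 - 0.755 * a, 1e3)
  550 + camkii_act * (1.348 + a / den) + can_act
}

lcc_rates <- function(V, p, scale = 1) {
  list(
    kact  = scale * p$kact / (1 + exp(-(V - p$kact_vh) / p$kact_k)),
    kdeact = p$kdeact * exp(-(V + 40) / p$kdeact_v),
    ko    = p$ko / (1 + exp(-(V - p$ko_vh) / p$ko_k)),
    kc    = p$kc * exp(-(V + 20) / p$kc_v),
    koi   = p$koi / (1 + exp(-(V - p$koi_vh) / p$koi_k)),
    ki12  = p$ki12, ki23 = p$ki23,
    kr1   = scale * p$kr1 * exp(-(V + 40) / p$krec_v),
    kr2   = scale * p$kr2 * exp(-(V + 40) / p$krec_v),
    kr3   = p$kr3 * exp(-(V + 40) / p$krec_v)
  )
}

#' Generator matrix of the 6-state L-type channel
#'
#' States (C0, C1, O, I1, I2, I3).  Activation C0->C1, opening C1->O,
#' voltage-dependent inactivation O->I1 and deepening I1->I2->I3, recovery
#' In->C0 at hyperpolarized potentials.  The activation and the two faster
#' recovery rates are scaled by `xi / xi_ref` (Ca-dependent facilitation).
#'
#' @param V Membrane potential (mV).
#' @param camkii_act,can_act Dyadic activated CaMKII / CaN levels (scaled units).
#' @param cfg Model configuration (blocks `lcc` used).
#' @return 6x6 generator matrix Q (columns sum to zero; `dp/dt = Q %*% p`).
#' @export
lcc_generator <- function(V, camkii_act, can_act, cfg = model_config()) {
  p <- cfg$lcc
  if (!is.finite(V)) stop("V must be finite", call. = FALSE)
  xi <- xi_facilitation(camkii_act, can_act, p$xi_form)
  sc <- xi / p$xi_ref
  r <- lcc_rates(V, p, sc)
  Q <- matrix(0, 6, 6)
  put <- function(from, to, rate) {
    Q[to, from] <<- Q[to, from] + rate
    Q[from, from] <<- Q[from, from] - rate
  }
  put(1, 2, r$kact); put(2, 1, r$kdeact)
  put(2, 3, r$ko);   put(3, 2, r$kc)
  put(3, 4, r$koi)
  put(4, 5, r$ki12); put(5, 6, r$ki23)
  put(4, 1, r$kr1);  put(5, 1, r$kr2); put(6, 1, r$kr3)
  Q
}

#' First-order Ca-dependent inactivation gate update
#'
#' The gate relaxes toward `1 / (1 + (ca / kca)^h)` with the configured time
#' constant: fully available at zero Ca, progressively inactivated as dyadic
#' Ca rises (within-beat kinetics).
#'
#' @param gate Current gate value in `[0, 1]`.
#' @param ca_dyad Ca2+ at the channel mouth (uM).
#' @param dt Step (s).
#' @param cfg Model configuration.
#' @return Updated gate value.
#' @export
cdi_update <- function(gate, ca_dyad, dt, cfg = model_config()) {
  p <- cfg$lcc
  yinf <- 1 / (1 + (ca_dyad / p$cdi_kca)^p$cdi_hill)
  yinf + (gate - yinf) * exp(-dt / p$cdi_tau)
}

ghk_term <- function(V, ca_in, ca_out) {
  vhat <- 2 * V / 26.71   # zFV/RT at 37C reference; mV
  if (abs(vhat) < 1e-6) return(ca_in - ca_out)
  vhat * (ca_in * exp(vhat) - ca_out) / (exp(vhat) - 1)
}

#' L-type Ca2+ flux / current
#'
#' Open occupancy x CDI gate x constant-field driving term x conductance x
#' cAMP factor.  Returned as a flux in uM/s into the dyad volume (negative =
#' inward Ca2+ current by the electrophysiological sign convention; the flux
#' into the cleft is `-i_cal`).
#'
#' @param V Membrane potential (mV).
#' @param open_occ Open-state occupancy (O of the 6-state chain).
#' @param cdi_gate CDI gate value.
#' @param camp cAMP (uM).
#' @param ca_dyad Ca2+ at the inner channel mouth (uM).
#' @param cfg Model configuration.
#' @return Signed flux (uM/s, dyad volume); inward (physiological) is negative.
#' @export
i_cal <- function(V, open_occ, cdi_gate, camp, ca_dyad, cfg = model_config()) {
  p <- cfg$lcc
  drv <- ghk_term(V, ca_dyad, cfg$cell$ca_o)
  p$g_flux * open_occ * cdi_gate * f_camp_ical(camp) * drv / cfg$cell$ca_o
}

#' Generator matrix of the 4-state RyR channel
#'
#' Ring C -> O -> I -> R -> C.  Opening is sigmoidal in mouth Ca2+ (CICR
#' trigger) and scaled up by CaMKII; inactivation O -> I accelerates with the
#' luminal-sensor inhibition; recovery R -> C is slowed by it and boosted by
#' CaMKII.
#'
#' @param ca_mouth Ca2+ at the RyR dyadic mouth (uM).
#' @param camkii_act Dyadic activated CaMKII (scaled units).
#' @param luminal_inhibition Sensor state in `[0, 1]`.
#' @param cfg Model configuration.
#' @return 4x4 generator matrix (columns sum to zero).
#' @export
ryr_generator <- function(ca_mouth, camkii_act, luminal_inhibition,
                          cfg = model_config()) {
  p <- cfg$ryr
  if (ca_mouth < 0 || camkii_act < 0 || luminal_inhibition < 0 ||
      luminal_inhibition > 1) {
    stop("invalid RyR generator inputs", call. = FALSE)
  }
  sck <- 1 + p$camkii_gain * camkii_act / 100
  h <- ca_mouth^p$kco_hill / (ca_mouth^p$kco_hill + p$kco_ca^p$kco_hill)
  kco <- p$kco_max * h * sck * (1 - luminal_inhibition)^p$gate_pow
  koi <- p$koi_base * (1 + p$koi_lum * luminal_inhibition)
  krc <- p$krc * (1 - luminal_inhibition) * sck /
    (1 + (ca_mouth / p$krec_ca)^2)
  Q <- matrix(0, 4, 4)
  put <- function(from, to, rate) {
    Q[to, from] <<- Q[to, from] + rate
    Q[from, from] <<- Q[from, from] - rate
  }
  put(1, 2, kco); put(2, 1, p$koc)
  put(2, 3, koi); put(3, 4, p$kir); put(4, 1, krc)
  Q
}

#' RyR release flux
#'
#' Permeability x open probability x concentration gradient across the
#' channel; uM/s in jSR-volume units.
#'
#' @param open_prob RyR open probability.
#' @param ca_jsr jSR free Ca2+ (uM).
#' @param ca_dyad_face Ca2+ at the jSR face of the cleft (uM).
#' @param cfg Model configuration.
#' @return Flux out of the jSR (uM/s); negative only if the gradient reverses.
#' @export
ryr_flux <- function(open_prob, ca_jsr, ca_dyad_face, cfg = model_config()) {
  if (ca_jsr < 0 || ca_dyad_face < 0) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  cfg$ryr$perm * open_prob * (ca_jsr - ca_dyad_face)
}

#' Luminal-sensor dynamics
#'
#' Inhibition rises (rate `kl_on`) while jSR Ca2+ sits below the sensor
#' threshold during release, and decays at a rate that grows with the jSR
#' refilling level, reproducing release refractoriness that relaxes as the SR
#' refills.
#'
#' @param luminal_inhibition Sensor state in `[0, 1]`.
#' @param ca_jsr jSR free Ca2+ (uM).
#' @param cfg Model configuration.
#' @return d(inhibition)/dt (1/s).
#' @export
luminal_sensor_rhs <- function(luminal_inhibition, ca_jsr, cfg = model_config()) {
  p <- cfg$ryr
  on <- 1 / (1 + exp((ca_jsr - p$lum_th) / p$lum_w))
  off <- p$kl_off * (ca_jsr / p$lum_th)^2
  p$kl_on * on * (1 - luminal_inhibition) - off * luminal_inhibition
}

#' Na+/Ca2+ exchanger flux
#'
#' Standard electrogenic 3:1 formulation (voltage- and gradient-dependent,
#' saturable) with a slow allosteric Ca2+ activation gate; no cAMP
#' dependence.  Positive = forward mode = Ca2+ extrusion.  `allo` defaults to
#' the steady-state gate at `ca_myo`; the engine integrates the gate as a
#' slow state.
#'
#' @param V Membrane potential (mV).
#' @param na_myo,ca_myo Intracellular Na+ / Ca2+ (uM).
#' @param na_o,ca_o Extracellular Na+ / Ca2+ (uM).
#' @param cfg Model configuration.
#' @return Ca2+ extrusion flux (uM/s, myoplasm volume).
#' @export
ncx_flux <- function(V, na_myo, ca_myo, na_o = NULL, ca_o = NULL,
                     allo = NULL, cfg = model_config()) {
  p <- cfg$ncx
  na_o <- na_o %||% cfg$cell$na_o
  ca_o <- ca_o %||% cfg$cell$ca_o
  if (any(c(na_myo, ca_myo, na_o, ca_o) <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  vhat <- V / 26.71
  num <- exp(p$eta * vhat) * na_myo^3 * ca_o -
    exp((p$eta - 1) * vhat) * na_o^3 * ca_myo
  den <- (p$km_na^3 + na_o^3) * (p$km_ca + ca_o) *
    (1 + p$ksat * exp((p$eta - 1) * vhat))
  if (is.null(allo)) {
    allo <- 1 / (1 + (p$km_act / ca_myo)^p$act_hill)  # gate steady state
  }
  -p$k_scale * allo * num / den
}

#' Plasma-membrane Ca2+-ATPase flux
#'
#' Hill-type saturating extrusion, half-maximal at `km`.
#'
#' @param ca_myo Myoplasmic Ca2+ (uM), >= 0.
#' @param cfg Model configuration.
#' @return Extrusion flux (uM/s, myoplasm volume).
#' @export
pmca_flux <- function(ca_myo, cfg = model_config()) {
  if (any(ca_myo < 0)) stop("ca_myo must be non-negative", call. = FALSE)
  p <- cfg$pmca
  p$vmax * ca_myo^p$hill / (ca_myo^p$hill + p$km^p$hill)
}
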
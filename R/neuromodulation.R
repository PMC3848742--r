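# cAMP-mediated beta-adrenergic modulation.
#
# Under maximal beta-adrenergic stimulation the intracellular cAMP level rises
# with pacing frequency; under basal conditions it stays at 2.67 uM.  Four
# closed-form factors translate [cAMP] into modulation of the L-type Ca2+
# conductance, SERCA/PLB phosphorylation, PKA-mediated TnI phosphorylation and
# crossbridge cycling rates.  cGMP is held constant and has no downstream
# coupling in this model.

# Anchor table: stimulation frequency (Hz) -> intracellular cAMP (uM) under
# maximal beta-adrenergic stimulation.  Flat at the basal level up to 1.67 Hz.
.camp_anchors <- data.frame(
  freq = c(0.50, 1.67, 2.50, 2.86, 3.33, 4.00, 5.00, 5.71, 6.67, 8.00, 10.00, 12.00),
  camp = c(2.67, 2.67, 3.00, 3.19, 3.45, 3.85, 4.67, 5.58, 18.06, 24.58, 27.03, 29.17)
)

#' Intracellular cAMP level as a function of pacing frequency
#'
#' Basal conditions give a frequency-independent 2.67 uM.  Under maximal
#' beta-adrenergic stimulation the level follows the anchor table (flat at
#' 2.67 uM up to 1.67 Hz, then rising to 29.17 uM at 12 Hz), interpolated
#' between anchors.
#'
#' @param frequency Pacing frequency in Hz, in `[0.5, 12]`.
#' @param beta_state `"basal"` or `"maximal"`.
#' @param method `"linear"` (default) interpolates linearly between anchors;
#'   `"step"` holds the last anchor value (left-continuous step function).
#' @return cAMP concentration in uM (vectorised over `frequency`).
#' @export
#' @examples
#' camp_level(5, "maximal")   # 4.67
#' camp_level(5, "basal")     # 2.67
camp_level <- function(frequency, beta_state = c("basal", "maximal"),
                       method = c("linear", "step")) {
  beta_state <- match.arg(beta_state)
  method <- match.arg(method)
  if (any(!is.finite(frequency)) || any(frequency < 0.5) || any(frequency > 12)) {
    stop("`frequency` must lie in [0.5, 12] Hz", call. = FALSE)
  }
  if (beta_state == "basal") {
    return(rep(2.67, length(frequency)))
  }
  if (method == "linear") {
    stats::approx(.camp_anchors$freq, .camp_anchors$camp, xout = frequency,
                  method = "linear", rule = 2)$y
  } else {
    stats::approx(.camp_anchors$freq, .camp_anchors$camp, xout = frequency,
                  method = "constant", rule = 2)$y
  }
}

.check_camp <- function(camp) {
  if (any(!is.finite(camp)) || any(camp < 0)) {
    stop("`camp` must be a non-negative finite concentration (uM)", call. = FALSE)
  }
  camp
}

#' cAMP modulation factor for the L-type Ca2+ conductance
#'
#' `1.094 - 0.163 * exp(-0.219 * camp)`; rises from 0.931 at zero cAMP to an
#' asymptote of 1.094, crossing ~1 at the basal level.
#'
#' @param camp cAMP concentration (uM), non-negative.
#' @return Dimensionless conductance factor.
#' @export
f_camp_ical <- function(camp) {
  .check_camp(camp)
  1.094 - 0.163 * exp(-0.219 * camp)
}

#' cAMP modulation factor for SERCA/PLB phosphorylation
#'
#' `0.1094 - 0.0163 * exp(-0.219 * camp)`.  Enters the phospholamban
#' phosphorylation balance (squared) on the kinase side.
#'
#' @inheritParams f_camp_ical
#' @return Dimensionless factor in (0.0931, 0.1094).
#' @export
f_camp_serca <- function(camp) {
  .check_camp(camp)
  0.1094 - 0.0163 * exp(-0.219 * camp)
}

#' PKA activation increment driving TnI phosphorylation
#'
#' Saturating `0.3 * camp / (camp + 12.1)`: 0 at zero cAMP, half of its 0.3
#' ceiling at 12.1 uM.
#'
#' @inheritParams f_camp_ical
#' @return Fraction in `[0, 0.3)`.
#' @export
delta_pka <- function(camp) {
  .check_camp(camp)
  0.3 * camp / (camp + 12.1)
}

#' cAMP modulation factor for crossbridge cycling rates
#'
#' `1.873 - 1.4 * exp(-0.192 * camp)`; scales the four crossbridge rate
#' constants, producing the cAMP-dependent speed-up of contraction and
#' relaxation.
#'
#' @inheritParams f_camp_ical
#' @return Dimensionless factor in (0.473, 1.873).
#' @export
f_camp_force <- function(camp) {
  .check_camp(camp)
  1.873 - 1.4 * exp(-0.192 * camp)
}
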
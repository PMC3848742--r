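# Model configuration.
#
# All parameters live in one nested list, organised by subsystem.  Units:
# time s (except protocol fields in ms), concentration uM (Na+ in uM, i.e.
# 10 mM = 1e4), length um, voltage mV, temperature degC.  Fluxes are uM/s in
# the volume of the compartment they enter.  `model_config()` returns the
# reference rat ventricular cell; overlays are merged and validated.

#' Reference model configuration
#'
#' Returns the full nested parameter list for the reference cell, optionally
#' modified by an overlay (a nested list of the same shape; unknown keys are
#' rejected).
#'
#' @param overlay Optional nested list of parameter overrides.
#' @return A validated `ffrcell_config` list.
#' @export
model_config <- function(overlay = NULL) {
  cfg <- list(
    metadata = list(
      name = "rat-ventricular-reference",
      version = "1.0",
      description = "Reference rat ventricular myocyte, voltage-clamp Ca2+ subsystem with coupled mechanics",
      seed = 0  # reserved; the model is fully deterministic
    ),
    cell = list(
      vol_myo = 20,       # pL, myoplasmic accessible volume
      vol_lsr = 1.4,      # pL, longitudinal SR
      vol_jsr = 0.3,      # pL, junctional SR
      n_dcu = 20000,      # dyadic coupling units represented by the one grid
      ca_o = 1800,        # uM extracellular Ca2+
      na_o = 140000,      # uM extracellular Na+
      temp = 22.5         # degC simulated bath temperature
    ),
    signaling = list(
      dyad = list(
        cam_tot = 400, buf_tot = 500,
        kon_c = 0.1, koff_c = 0.6,    # C-lobe 2-Ca step, /uM^2/s and /s
        kon_n = 0.02, koff_n = 5,     # N-lobe 2-Ca step
        kon_b = 0.1, koff_b = 10,     # dyad-modified CaM buffer rates
        camkii_ka = 0.05, camkii_kb = 0.5,
        camkii_scale = 100,           # CaMKIIact = fraction x scale
        can_tot = 1,
        kon_cam = 0.01, koff_cam = 1,
        kon_ca2 = 0.05, koff_ca2 = 0.5,
        kon_ca4 = 0.18, koff_ca4 = 0.02,
        can_scale = 100               # CaNact = fraction x scale
      ),
      myoplasm = list(
        cam_tot = 6, buf_tot = 50,
        kon_c = 10, koff_c = 60,
        kon_n = 2, koff_n = 500,
        kon_b = 1, koff_b = 1,
        camkii_ka = 0.05, camkii_kb = 0.5,
        camkii_scale = 0.3,
        can_tot = 1,
        kon_cam = 0.01, koff_cam = 1,
        kon_ca2 = 0.05, koff_ca2 = 0.5,
        kon_ca4 = 20, koff_ca4 = 0.02,
        can_scale = 1e6
      )
    ),
    neuro = list(
      beta_state = "basal",   # "basal" or "maximal"
      camp_override = NA,     # uM; set to force a fixed cAMP level
      camp_method = "linear", # anchor interpolation: "linear" or "step"
      cgmp = 2.0              # uM, held constant (no downstream coupling)
    ),
    dyad = list(
      nr = 20, nz = 20,
      r_um = 0.19,            # cleft radius (19 x 10 nm)
      z_um = 0.01444,         # cleft height (19 x 0.76 nm)
      d_eff = 50,             # um^2/s, barrier-reduced effective diffusivity
      buf_tot = 300, buf_kon = 100, buf_koff = 1500,  # stationary cleft buffer
      scheme = "adi",         # grid update inside the engine: "adi" or "explicit"
      mouth_r = 0.0015,       # um, self-increment regularization radius
      lcc_node = c(1, 1),     # (ir, iz) 1-based: axis, sarcolemmal face
      ryr_node = c(1, 20)     # axis, jSR face
    ),
    lcc = list(
      g_flux = 4.5e5,         # uM/s (dyad volume) flux scale
      kact = 800, kact_vh = -10, kact_k = 6,
      kdeact = 400, kdeact_v = 12,
      ko = 2500, ko_vh = -5, ko_k = 6,
      kc = 600, kc_v = 20,
      koi = 25, koi_vh = -15, koi_k = 8,
      ki12 = 3, ki23 = 0.5,
      kr1 = 40, kr2 = 40, kr3 = 22, krec_v = 15,
      cdi_kca = 60, cdi_hill = 2, cdi_tau = 0.015,
      xi_form = "new",        # "new" (default) or "classic"
      xi_ref = 650            # reference xi for rate scaling
    ),
    ryr = list(
      kco_max = 3000, kco_ca = 60, kco_hill = 4,
      koc = 500,
      koi_base = 120, koi_lum = 4,
      kir = 25,
      krc = 45,
      camkii_gain = 0.15,     # fractional rate boost per unit CaMKIIact/100
      perm = 500,             # /s release permeability (jSR volume units)
      lum_th = 700,           # uM jSR free Ca threshold for the luminal sensor
      lum_w = 80,             # uM sigmoid width
      kl_on = 120, kl_off = 15, gate_pow = 8,
      krec_ca = 3,            # uM mouth Ca blocking refractory recovery
      enabled = TRUE          # FALSE disables release (EC-gain denominator)
    ),
    ncx = list(
      k_scale = 3e5,          # uM/s (myo volume) flux scale
      km_na = 87500, km_ca = 1380, eta = 0.35, ksat = 0.1,
      km_act = 0.55,          # uM allosteric Ca2+ activation constant
      act_hill = 4,           # steepness of the allosteric activation
      act_tau = 1.5           # s, relaxation time of the allosteric gate
    ),
    pmca = list(vmax = 6, km = 0.5, hill = 2),
    na = list(
      bg = 105,               # uM/s background Na+ entry (myo volume)
      nak_vmax = 190,         # uM/s maximal Na+ pump rate
      nak_km = 9000,          # uM half-activation (Hill 3)
      vol_frac = 0.15         # effective (subsarcolemmal) Na+ volume fraction
    ),
    sr = list(
      k12_plb = 6800, k21_plb = 1000,
      vmax0 = 160,            # uM/s (myo volume) base maximal SERCA rate
      a_plb = 1.2,            # Vmax gain per unit phosphorylated PLB
      a_ck = 4.0,             # direct CaMKII phosphorylation gain on Vmax
      kf0 = 0.30, bf = 0.8,   # forward half-activation and its CaMKII law
      kr0 = 2600, br = 0.8,   # backward half-activation and its CaMKII law
      hill = 2,
      tau_tr = 0.025,         # s, LSR -> jSR transfer time constant
      csq_tot = 15000, csq_kon = 10, csq_koff = 8000,
      leak = 1e-3,            # /s constitutive SR leak (rest balance)
      camp_vmax_exp = 6       # cAMP (PKA/PLB-mediated) uptake enhancement exponent
    ),
    mechanics = list(
      kon_t = 22.22, koff_ht = 17.36, koff_lt = 173.61,  # /uM/s, /s, /s
      kon_ti = 698.69, koff_ti = 80.0,
      knp = 500, kpn = 50,    # regulatory-unit switching, /s (unscaled)
      fapp = 500, gapp = 70, hf = 2000, hb = 400, gxb = 70,
      q10 = 2.25, t_ref = 22.5,
      perm50 = 0.50, perm_hill = 7,
      trop_tot = 70,          # uM regulatory troponin sites (mass accounting)
      sl0 = 1.9, sl_gain = 0.13, sl_tau = 0.01
    ),
    buffers = list(
      myo_tot = 80, myo_kon = 100, myo_koff = 65
    ),
    engine = list(
      dt = 1e-6,              # s, global fixed step
      output_dt = 1e-4,       # s, trace sampling interval
      n_cycles = 150,
      min_cycles = 25,        # convergence stop armed only after this many
      convergence_tol = 0,    # relative beat-to-beat change for early stop
      scheme = "merson"       # "merson" (5-stage) or "rk4"
    ),
    protocol = list(
      v_hold = -40, v_step = 10, pulse_ms = 50
    )
  )
  if (!is.null(overlay)) cfg <- merge_config(cfg, overlay)
  validate_config(cfg)
  structure(cfg, class = c("ffrcell_config", "list"))
}

merge_config <- function(base, overlay, path = "") {
  for (nm in names(overlay)) {
    if (!nm %in% names(base)) {
      stop(sprintf("unknown configuration key: %s%s", path, nm), call. = FALSE)
    }
    if (is.list(base[[nm]]) && is.list(overlay[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], overlay[[nm]], paste0(path, nm, "$"))
    } else {
      base[[nm]] <- overlay[[nm]]
    }
  }
  base
}

#' Validate a model configuration
#'
#' Checks structural completeness, numeric types, and the bounds that matter
#' for well-posedness (positive volumes, rates and totals, q10 range, valid
#' grid nodes, stability of the explicit grid scheme when selected).
#'
#' @param cfg A configuration list.
#' @return The configuration, invisibly; errors list offending keys.
#' @export
validate_config <- function(cfg) {
  problems <- character()
  need_pos <- function(value, key) {
    if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0)) {
      problems <<- c(problems, key)
    }
  }
  for (blk in c("cell", "dyad", "lcc", "ryr", "ncx", "pmca", "na", "sr",
                "mechanics", "buffers")) {
    if (is.null(cfg[[blk]])) problems <- c(problems, blk)
  }
  need_pos(cfg$cell$vol_myo, "cell$vol_myo")
  need_pos(cfg$cell$vol_lsr, "cell$vol_lsr")
  need_pos(cfg$cell$vol_jsr, "cell$vol_jsr")
  need_pos(cfg$dyad$d_eff, "dyad$d_eff")
  need_pos(cfg$engine$dt, "engine$dt")
  for (cmp in c("dyad", "myoplasm")) {
    p <- cfg$signaling[[cmp]]
    for (k in c("cam_tot", "kon_c", "koff_c", "kon_n", "koff_n",
                "camkii_scale", "can_scale")) {
      need_pos(p[[k]], paste0("signaling$", cmp, "$", k))
    }
  }
  if (!is.numeric(cfg$mechanics$q10) || cfg$mechanics$q10 < 1 ||
      cfg$mechanics$q10 > 6.25) {
    problems <- c(problems, "mechanics$q10")
  }
  if (!cfg$neuro$beta_state %in% c("basal", "maximal")) {
    problems <- c(problems, "neuro$beta_state")
  }
  if (!cfg$lcc$xi_form %in% c("new", "classic")) {
    problems <- c(problems, "lcc$xi_form")
  }
  nd <- cfg$dyad
  if (any(nd$lcc_node < 1) || nd$lcc_node[1] > nd$nr || nd$lcc_node[2] > nd$nz ||
      any(nd$ryr_node < 1) || nd$ryr_node[1] > nd$nr || nd$ryr_node[2] > nd$nz) {
    problems <- c(problems, "dyad$lcc_node/ryr_node")
  }
  if (!is.numeric(cfg$cell$temp) || cfg$cell$temp < 15 || cfg$cell$temp > 40) {
    problems <- c(problems, "cell$temp")
  }
  if (length(problems)) {
    stop("invalid configuration key(s): ", paste(problems, collapse = ", "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Reference fixtures: full-resolution and fast-test configurations
#'
#' `config_full()` is the production cell: 20x20 dyadic grid, 1 us global
#' step, 150 pacing cycles.  `config_fast_test()` is the desk-scale variant
#' used throughout the test-suite and the acceptance experiments: 10x10 grid,
#' 10 us step, convergence-stop pacing capped at 50 cycles.
#'
#' @param overlay Optional further overrides.
#' @return A validated `ffrcell_config`.
#' @export
config_full <- function(overlay = NULL) {
  cfg <- model_config()
  if (!is.null(overlay)) cfg <- model_config(overlay)
  cfg
}

#' @rdname config_full
#' @export
config_fast_test <- function(overlay = NULL) {
  base <- list(
    dyad = list(nr = 10, nz = 10, lcc_node = c(1, 1), ryr_node = c(1, 10)),
    engine = list(dt = 1e-5, n_cycles = 50, convergence_tol = 5e-4)
  )
  if (!is.null(overlay)) base <- utils::modifyList(base, overlay)
  model_config(base)
}

#' Read / write configurations as YAML
#'
#' `load_config()` reads a YAML overlay file and merges it onto the reference
#' defaults (an empty file returns the reference cell); `save_config()`
#' writes a full configuration.  Round-tripping is the identity.
#'
#' @param path File path.
#' @param cfg A configuration list.
#' @return `load_config()` a validated `ffrcell_config`; `save_config()` the
#'   path, invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  overlay <- yaml::read_yaml(path)
  if (is.null(overlay)) overlay <- list()
  model_config(overlay)
}

#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
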
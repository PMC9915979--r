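#' Tissue benzene concentration under constant arterial supply
#'
#' Saturating uptake curve for a single perfused compartment exposed to a
#' constant arterial benzene concentration:
#' \deqn{C_i(t) = \frac{Q_i P_i C_{art} t}{V_i P_i + Q_i t}}
#' The curve starts at 0, rises monotonically, and approaches the
#' equilibrium value \eqn{P_i C_{art}} as flow-delivered benzene dominates
#' the tissue's storage capacity.
#'
#' @param comp A [compartment_params()] object.
#' @param c_art Arterial benzene concentration, mg/L. Must be >= 0.
#' @param t Time since the start of exposure, min (vectorized). Must be >= 0.
#' @return Tissue benzene concentration(s), mg/L; same length as `t`.
#' @export
#' @examples
#' liver <- compartment_params("liver", Q = 1, V = 10, P = 2)
#' compartment_concentration(liver, c_art = 1, t = c(0, 20, 1e9))
compartment_concentration <- function(comp, c_art, t) {
  if (!inherits(comp, "compartment_params")) {
    abort_domain("`comp` must be a compartment_params object")
  }
  check_scalar(c_art, "c_art", nonnegative = TRUE)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    abort_domain("`t` must be finite and >= 0")
  }
  (comp$Q * comp$P * c_art * t) / (comp$V * comp$P + comp$Q * t)
}

#' Time to effective steady state for a compartment
#'
#' Smallest `t` at which [compartment_concentration()] is within a relative
#' tolerance of its asymptote `P * c_art`. The relative shortfall is
#' `(V*P) / (V*P + Q*t)`, so the bound solves in closed form.
#'
#' @param comp A [compartment_params()] object.
#' @param rel_tol Relative distance from the asymptote, default `1e-6`.
#' @return Time in min.
#' @export
steady_state_time <- function(comp, rel_tol = 1e-6) {
  if (!inherits(comp, "compartment_params")) {
    abort_domain("`comp` must be a compartment_params object")
  }
  check_scalar(rel_tol, "rel_tol", positive = TRUE)
  comp$V * comp$P * (1 / rel_tol - 1) / comp$Q
}

#' Arterial benzene concentration from inhaled air
#'
#' Maps a constant inhaled air concentration to the steady-state arterial
#' blood concentration. Two rules are offered:
#' \describe{
#'   \item{`"equilibrium"` (default)}{Instantaneous blood:air equilibrium,
#'     `C_art = P_blood_air * c_inh / 1000`. This is the package's reading
#'     of the assumption that blood instantaneously reaches steady state.}
#'   \item{`"mass_balance"`}{The standard steady-state inhalation mass
#'     balance `C_art = (Q_alv * c_inh/1000 + Q_card * c_ven) /
#'     (Q_card + Q_alv / P_blood_air)`, with the mixed venous return
#'     concentration `c_ven` supplied by the caller (0 by default, i.e.
#'     complete peripheral extraction — a conservative lower bound).}
#' }
#' The factor 1000 converts air mg/m^3 to mg/L.
#'
#' @param c_inh Inhaled benzene concentration, mg/m^3. Must be >= 0.
#' @param phys A [physiology()] object.
#' @param mode `"equilibrium"` or `"mass_balance"`.
#' @param c_ven Mixed venous concentration, mg/L (mass-balance mode only).
#' @return Arterial concentration, mg/L. Linear in `c_inh`.
#' @export
#' @examples
#' arterial_concentration(5.85, physiology(P_blood_air = 8.0))
arterial_concentration <- function(c_inh, phys,
                                   mode = c("equilibrium", "mass_balance"),
                                   c_ven = 0) {
  mode <- match.arg(mode)
  check_scalar(c_inh, "c_inh", nonnegative = TRUE)
  check_scalar(c_ven, "c_ven", nonnegative = TRUE)
  c_air <- c_inh / 1000  # mg/m^3 -> mg/L
  if (mode == "equilibrium") {
    phys$P_blood_air * c_air
  } else {
    (phys$Q_alv * c_air + phys$Q_card * c_ven) /
      (phys$Q_card + phys$Q_alv / phys$P_blood_air)
  }
}

#' Hepatic metabolic rate (Michaelis-Menten)
#'
#' @param c_liver_venous Benzene concentration in liver venous blood, mg/L.
#' @param met A [metabolism_params()] object.
#' @return Metabolic rate, mg/min; bounded above by `Vmax`.
#' @export
#' @examples
#' met <- metabolism_params(Vmax = 1, Km = 0.5)
#' metabolic_rate(0.5, met)  # half saturation: 0.5
metabolic_rate <- function(c_liver_venous, met) {
  if (!inherits(met, "metabolism_params")) {
    abort_domain("`met` must be a metabolism_params object")
  }
  if (!is.numeric(c_liver_venous) || any(!is.finite(c_liver_venous)) ||
      any(c_liver_venous < 0)) {
    abort_domain("`c_liver_venous` must be finite and >= 0")
  }
  met$Vmax * c_liver_venous / (met$Km + c_liver_venous)
}

#' Forward chain: air benzene to urinary tt-MA
#'
#' Simulates the steady-state biomarker chain for one subject under constant
#' inhalation exposure: arterial uptake, liver tissue concentration at
#' effective steady state, hepatic Michaelis-Menten metabolism, accumulation
#' of the tt-MA fraction of metabolized benzene in the bladder over one
#' micturition interval, and dilution in the void volume.
#'
#' The amount metabolized per void is, by default, the steady-state rate
#' times the micturition interval (the rate is constant once blood is at
#' steady state). Setting `integrate = TRUE` instead integrates the
#' time-varying rate over `[void_start, void_start + interval]` with the
#' liver concentration following its uptake curve from `t = 0` — useful for
#' non-steady configurations such as a void shortly after exposure begins.
#'
#' @param c_inh Inhaled benzene, mg/m^3.
#' @param params A [pbpk_parameters()] object.
#' @param phys A [physiology()] object.
#' @param t_ss Time at which the liver is evaluated, min. Default: the
#'   closed-form time at which the liver uptake curve is within `1e-6`
#'   (relative) of its asymptote.
#' @param arterial_mode Passed to [arterial_concentration()].
#' @param integrate If `TRUE`, integrate the metabolic rate over the voiding
#'   window instead of using the steady-state rate.
#' @param void_start Start of the voiding window, min (integrate mode).
#' @return A `urine_output` list: `ttma_conc` (mg/L urine),
#'   `ttma_per_creatinine` (mg/g), `metabolized_rate` (mg/min at `t_ss`).
#' @export
#' @examples
#' out <- ttma_urine_forward(5.85, default_pbpk_parameters(), physiology())
#' out$ttma_conc
ttma_urine_forward <- function(c_inh, params, phys, t_ss = NULL,
                               arterial_mode = c("equilibrium", "mass_balance"),
                               integrate = FALSE, void_start = NULL) {
  arterial_mode <- match.arg(arterial_mode)
  check_scalar(c_inh, "c_inh", nonnegative = TRUE)
  if (!inherits(params, "pbpk_parameters")) {
    abort_config("`params` must be a pbpk_parameters object")
  }
  if (!inherits(phys, "physiology")) {
    abort_config("`phys` must be a physiology object")
  }
  if (phys$urine_void_volume <= 0) {
    abort_config("`urine_void_volume` must be positive")
  }
  liver <- params$compartments$liver
  met <- params$metabolism
  if (is.null(t_ss)) t_ss <- steady_state_time(liver, 1e-6)
  check_scalar(t_ss, "t_ss", positive = TRUE)

  c_art <- arterial_concentration(c_inh, phys, mode = arterial_mode)
  mw_ratio <- params$constants$mw_ttma / params$constants$mw_benzene
  interval <- phys$micturition_interval

  c_vl_at <- function(t) {
    compartment_concentration(liver, c_art, t) / liver$P
  }
  rate_ss <- metabolic_rate(c_vl_at(t_ss), met)

  if (integrate) {
    t0 <- void_start %||% t_ss
    check_scalar(t0, "void_start", nonnegative = TRUE)
    amount <- stats::integrate(function(t) metabolic_rate(c_vl_at(t), met),
                               lower = t0, upper = t0 + interval,
                               rel.tol = 1e-10, abs.tol = 0)$value
  } else {
    amount <- rate_ss * interval
  }

  ttma_mass <- met$f_ttma * amount * mw_ratio
  ttma_conc <- ttma_mass / phys$urine_void_volume
  structure(list(ttma_conc = ttma_conc,
                 ttma_per_creatinine = ttma_conc / phys$urinary_creatinine,
                 metabolized_rate = rate_ss),
            class = "urine_output")
}

#' Upper bound on the urinary tt-MA the model can produce
#'
#' The metabolic rate saturates at `Vmax`, so urinary tt-MA is bounded by
#' `f_ttma * Vmax * interval * (MW_ttMA / MW_benzene) / void_volume`.
#' Observations at or above this bound cannot be explained by any finite
#' air concentration.
#'
#' @inheritParams ttma_urine_forward
#' @return Saturation bound, mg/L urine.
#' @export
ttma_saturation_bound <- function(params, phys) {
  met <- params$metabolism
  mw_ratio <- params$constants$mw_ttma / params$constants$mw_benzene
  met$f_ttma * met$Vmax * phys$micturition_interval * mw_ratio /
    phys$urine_void_volume
}

#' Convert an air concentration from mg/m^3 to ppm
#'
#' `ppm = x * molar_volume / mw`, with defaults for benzene (78.11 g/mol)
#' and the molar gas volume at 25 degrees C and 1 atm (24.45 L/mol).
#'
#' @param x Concentration, mg/m^3. Must be >= 0.
#' @param mw Molecular weight, g/mol.
#' @param molar_volume Molar gas volume, L/mol.
#' @return Concentration in ppm.
#' @export
#' @examples
#' mg_m3_to_ppm(5.85)  # benzene: 1.83 ppm
mg_m3_to_ppm <- function(x, mw = 78.11, molar_volume = 24.45) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort_domain("`x` must be finite and >= 0")
  }
  check_scalar(mw, "mw", positive = TRUE)
  check_scalar(molar_volume, "molar_volume", positive = TRUE)
  x * molar_volume / mw
}
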
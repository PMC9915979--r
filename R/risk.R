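#' Define an inhalation exposure scenario
#'
#' Container for the EPA-style exposure averaging inputs: air concentration
#' `C` (mg/m^3), exposure time `ET` (min/day), exposure frequency `EF`
#' (days/year), exposure duration `ED` (years) and averaging time `AT`
#' (days). `AT` defaults to `ED * 365`, the convention used throughout this
#' package; with that convention `ED` cancels out of the chronic exposure.
#'
#' @param label Scenario name.
#' @param C Air benzene concentration, mg/m^3.
#' @param ET Exposure time, min/day, in (0, 1440].
#' @param EF Exposure frequency, days/year, in (0, 365].
#' @param ED Exposure duration, years.
#' @param AT Averaging time, days.
#' @return An `exposure_scenario` object.
#' @export
exposure_scenario <- function(label, C, ET, EF, ED, AT = ED * 365) {
  check_scalar(C, "C", nonnegative = TRUE)
  check_scalar(ET, "ET", positive = TRUE)
  check_scalar(EF, "EF", positive = TRUE)
  check_scalar(ED, "ED", positive = TRUE)
  check_scalar(AT, "AT", positive = TRUE)
  if (ET > 1440) abort_domain("`ET` cannot exceed 1440 min/day")
  if (EF > 365) abort_domain("`EF` cannot exceed 365 days/year")
  structure(list(label = as.character(label), C = C, ET = ET, EF = EF,
                 ED = ED, AT = AT),
            class = "exposure_scenario")
}

#' Chronic exposure concentration
#'
#' Time-averaged exposure concentration
#' \deqn{CE = \frac{C \times ET \times EF \times ED}{1440 \times AT}}
#' in mg/m^3. The denominator is the product `1440 * AT` (minutes per day
#' times averaging days): continuous exposure (`ET = 1440`, `EF = 365`,
#' `AT = ED * 365`) returns `C` unchanged.
#'
#' @param s An [exposure_scenario()].
#' @return CE in mg/m^3; linear in `C`, `ET` and `EF`.
#' @export
#' @examples
#' s <- exposure_scenario("4 h/day", C = 5.85, ET = 240, EF = 300, ED = 6)
#' chronic_exposure(s)  # 0.80 at 2 d.p.
chronic_exposure <- function(s) {
  if (!inherits(s, "exposure_scenario")) {
    abort_domain("`s` must be an exposure_scenario")
  }
  if (s$AT <= 0) abort_domain("`AT` must be positive")
  (s$C * s$ET * s$EF * s$ED) / (1440 * s$AT)
}

#' Toxicity criteria for benzene inhalation
#'
#' The reference concentration (RfC) for the critical non-cancer effect
#' (decreased lymphocyte count) and the inhalation unit risk (IUR) interval
#' for leukemia. The IUR is stored internally per ug/m^3; values quoted per
#' mg/m^3 (e.g. 2.2e-3) are normalized by setting `iur_unit = "per_mg_m3"`.
#'
#' @param rfc Reference concentration, mg/m^3 (default 0.03).
#' @param iur_low,iur_high Inhalation unit risk bounds (default 2.2e-6 and
#'   7.8e-6 per ug/m^3).
#' @param iur_unit `"per_ug_m3"` (default) or `"per_mg_m3"`.
#' @return A `toxicity_criteria` object with IURs per ug/m^3.
#' @export
toxicity_criteria <- function(rfc = 0.03, iur_low = 2.2e-6, iur_high = 7.8e-6,
                              iur_unit = c("per_ug_m3", "per_mg_m3")) {
  iur_unit <- match.arg(iur_unit)
  check_scalar(rfc, "rfc", positive = TRUE)
  check_scalar(iur_low, "iur_low", positive = TRUE)
  check_scalar(iur_high, "iur_high", positive = TRUE)
  if (iur_unit == "per_mg_m3") {
    iur_low <- iur_low / 1000
    iur_high <- iur_high / 1000
  }
  if (iur_low > iur_high) abort_domain("`iur_low` must be <= `iur_high`")
  structure(list(rfc = rfc, iur_low = iur_low, iur_high = iur_high,
                 iur_unit = "per_ug_m3"),
            class = "toxicity_criteria")
}

#' Hazard quotient
#'
#' `HQ = CE / RfC`. By presentation convention the CE entering the ratio is
#' first rounded to 2 decimal places — the precision at which chronic
#' exposures are reported — so that quotients match reported tables; set
#' `round_ce = FALSE` for the raw ratio. An HQ below 1 means no adverse
#' non-cancer effects are expected.
#'
#' @param ce Chronic exposure, mg/m^3.
#' @param rfc Reference concentration, mg/m^3.
#' @param round_ce Round CE to 2 d.p. before dividing (default TRUE).
#' @return The hazard quotient (dimensionless).
#' @export
#' @examples
#' hazard_quotient(0.80, 0.03)  # 26.7 at 1 d.p.
hazard_quotient <- function(ce, rfc = 0.03, round_ce = TRUE) {
  if (!is.numeric(ce) || any(!is.finite(ce)) || any(ce < 0)) {
    abort_domain("`ce` must be finite and >= 0")
  }
  check_scalar(rfc, "rfc", positive = TRUE)
  if (round_ce) ce <- round(ce, 2)
  ce / rfc
}

#' Increased lifetime cancer risk
#'
#' `ICR = CE x IUR`, with CE converted to ug/m^3 (factor 1000) to match the
#' IUR's per-ug basis. Both IUR bounds give an interval of lifetime excess
#' leukemia probabilities. Presentation values round the risk to one
#' significant figure and express it per 1000 exposed.
#'
#' @param ce Chronic exposure, mg/m^3.
#' @param tox A [toxicity_criteria()] object.
#' @param round_ce Round CE to 2 d.p. first (presentation convention).
#' @return A list: `icr_low`, `icr_high` (lifetime probabilities),
#'   `icr_per_1000_low`, `icr_per_1000_high` (1 s.f., per 1000).
#' @export
#' @examples
#' cancer_risk(0.80, toxicity_criteria())  # 2 to 6 per 1000
cancer_risk <- function(ce, tox = toxicity_criteria(), round_ce = TRUE) {
  if (!is.numeric(ce) || length(ce) != 1L || !is.finite(ce) || ce < 0) {
    abort_domain("`ce` must be a finite scalar >= 0")
  }
  if (!inherits(tox, "toxicity_criteria")) {
    abort_domain("`tox` must be a toxicity_criteria object")
  }
  if (round_ce) ce <- round(ce, 2)
  ce_ug <- ce * 1000
  icr_low <- ce_ug * tox$iur_low
  icr_high <- ce_ug * tox$iur_high
  list(icr_low = icr_low, icr_high = icr_high,
       icr_per_1000_low = signif(icr_low, 1) * 1000,
       icr_per_1000_high = signif(icr_high, 1) * 1000)
}

#' Build the three standard exposure scenarios
#'
#' Scenario definitions for a shoe-workshop exposure setting:
#' \describe{
#'   \item{a}{para-occupational child exposure, 4 h/day (240 min), 300
#'     days/year, 6 years;}
#'   \item{b}{occupational child exposure, 8 h/day (480 min), 300 days/year,
#'     6 years;}
#'   \item{c}{lifetime projection, 8 h/day, 300 days/year, from birth to 70
#'     years.}
#' }
#' All use `AT = ED * 365`.
#'
#' @param C Air benzene concentration, mg/m^3.
#' @return A named list of three [exposure_scenario()] objects (`a`, `b`, `c`).
#' @export
build_scenarios <- function(C) {
  check_scalar(C, "C", positive = TRUE)
  list(
    a = exposure_scenario("children exposed 4 h/day", C, ET = 240, EF = 300, ED = 6),
    b = exposure_scenario("children exposed 8 h/day", C, ET = 480, EF = 300, ED = 6),
    c = exposure_scenario("adults: 8 h/day lifetime projection", C, ET = 480,
                          EF = 300, ED = 70)
  )
}

#' Scenario risk table
#'
#' Runs the full exposure-and-risk chain for the three standard scenarios
#' and returns one row per scenario with raw and presentation values:
#' chronic exposure (raw and 2 d.p.), hazard quotient (1 d.p.), and the
#' cancer-risk interval (raw and per 1000 at 1 s.f.).
#'
#' `scenario_c_ce_override` substitutes an externally supplied chronic
#' exposure for scenario c (the lifetime projection). With `AT = ED * 365`
#' the duration cancels and scenario c's computed CE equals scenario b's;
#' published lifetime projections often carry age-dependent adjustments that
#' this package does not model, so the override lets a reported value flow
#' through the risk arithmetic unchanged. The computed CE is always kept in
#' the `CE_raw` column.
#'
#' @param C Air benzene concentration, mg/m^3.
#' @param tox A [toxicity_criteria()] object.
#' @param scenario_c_ce_override Optional CE (mg/m^3) replacing scenario c's
#'   computed value, or `NULL` to use the computed one.
#' @return A data.frame with columns `scenario`, `label`, `CE_raw`, `CE`,
#'   `HQ`, `HQ_raw`, `ICR_low`, `ICR_high`, `ICR_per_1000_low`,
#'   `ICR_per_1000_high`.
#' @export
#' @examples
#' risk_table(5.85, scenario_c_ce_override = 1.11)
risk_table <- function(C, tox = toxicity_criteria(),
                       scenario_c_ce_override = NULL) {
  scens <- build_scenarios(C)
  if (!is.null(scenario_c_ce_override)) {
    check_scalar(scenario_c_ce_override, "scenario_c_ce_override",
                 nonnegative = TRUE)
  }
  rows <- lapply(names(scens), function(key) {
    s <- scens[[key]]
    ce_raw <- chronic_exposure(s)
    ce_used <- if (key == "c" && !is.null(scenario_c_ce_override)) {
      scenario_c_ce_override
    } else {
      ce_raw
    }
    risk <- cancer_risk(ce_used, tox)
    data.frame(
      scenario = key,
      label = s$label,
      CE_raw = ce_raw,
      CE = round(ce_used, 2),
      HQ = round(hazard_quotient(ce_used, tox$rfc), 1),
      HQ_raw = hazard_quotient(ce_used, tox$rfc, round_ce = FALSE),
      ICR_low = risk$icr_low,
      ICR_high = risk$icr_high,
      ICR_per_1000_low = risk$icr_per_1000_low,
      ICR_per_1000_high = risk$icr_per_1000_high,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Expected leukemia burden in an exposed population
#'
#' Scales a per-capita lifetime risk interval to an exposed population:
#' `n_exposed = n_units * children_per_unit` children (two per workshop by
#' default), expressed as a rounded percentage of a reference population,
#' with expected case counts as the nearest integer of
#' `n_exposed * risk`.
#'
#' @param n_units Number of exposure units (workshops).
#' @param children_per_unit Exposed children per unit.
#' @param ref_population Reference child population size.
#' @param risk_interval Length-2 numeric, per-capita lifetime risk
#'   (low, high), e.g. `c(2e-3, 6e-3)`.
#' @return A `population_burden` list: `n_units`, `children_per_unit`,
#'   `n_exposed`, `pct_of_population`, `expected_cases_low`,
#'   `expected_cases_high`.
#' @export
#' @examples
#' population_burden(234, 2, 7041, c(2e-3, 6e-3))  # 468 children, 1-3 cases
population_burden <- function(n_units, children_per_unit, ref_population,
                              risk_interval) {
  check_scalar(n_units, "n_units", nonnegative = TRUE)
  check_scalar(children_per_unit, "children_per_unit", nonnegative = TRUE)
  check_scalar(ref_population, "ref_population", nonnegative = TRUE)
  if (ref_population == 0) abort_domain("`ref_population` must be positive")
  if (!is.numeric(risk_interval) || length(risk_interval) != 2L ||
      any(!is.finite(risk_interval)) || any(risk_interval < 0) ||
      risk_interval[1] > risk_interval[2]) {
    abort_domain("`risk_interval` must be a nondecreasing pair of risks >= 0")
  }
  n_exposed <- n_units * children_per_unit
  structure(list(
    n_units = n_units,
    children_per_unit = children_per_unit,
    n_exposed = n_exposed,
    pct_of_population = round(n_exposed / ref_population * 100),
    expected_cases_low = round(n_exposed * risk_interval[1]),
    expected_cases_high = round(n_exposed * risk_interval[2])
  ), class = "population_burden")
}

#' @export
print.population_burden <- function(x, ...) {
  cat(sprintf("Population burden: %d x %g = %g exposed children (%d%% of reference population)\n",
              x$n_units, x$children_per_unit, x$n_exposed, x$pct_of_population))
  cat(sprintf("  expected leukemia cases: %d to %d\n",
              x$expected_cases_low, x$expected_cases_high))
  invisible(x)
}
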
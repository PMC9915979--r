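#' PBPK parameter containers
#'
#' Constructors and validators for the building blocks of the four-compartment
#' benzene PBPK model: per-compartment flows/volumes/partition coefficients,
#' Michaelis-Menten hepatic metabolism, and subject physiology (ventilation,
#' cardiac output, urine voiding pattern).
#'
#' Units follow the conventions used throughout the package: flows in L/min,
#' volumes in L, concentrations in mg/L (blood, tissue, urine) or mg/m^3
#' (air), times in min.
#'
#' @name pbpk-parameters
NULL

COMPARTMENT_NAMES <- c("richly_perfused", "fat", "poorly_perfused", "liver")

#' Create a single tissue compartment
#'
#' @param name One of `"richly_perfused"`, `"fat"`, `"poorly_perfused"`,
#'   `"liver"`.
#' @param Q Blood flow to the compartment, L/min.
#' @param V Tissue volume, L.
#' @param P Tissue:blood partition coefficient (dimensionless).
#' @return A `compartment_params` object.
#' @export
#' @examples
#' liver <- compartment_params("liver", Q = 0.75, V = 0.85, P = 1.7)
compartment_params <- function(name, Q, V, P) {
  name <- match.arg(name, COMPARTMENT_NAMES)
  check_scalar(Q, "Q", positive = TRUE)
  check_scalar(V, "V", positive = TRUE)
  check_scalar(P, "P", positive = TRUE)
  structure(list(name = name, Q = Q, V = V, P = P),
            class = "compartment_params")
}

#' Create Michaelis-Menten metabolism parameters
#'
#' @param Vmax Maximum hepatic metabolic capacity, mg/min.
#' @param Km Michaelis-Menten constant, mg/L.
#' @param t_half Benzene half-life, min. Carried for completeness; the
#'   steady-state chain does not use it.
#' @param f_ttma Fraction of metabolized benzene excreted in urine as
#'   trans,trans-muconic acid, in (0, 1].
#' @return A `metabolism_params` object.
#' @export
metabolism_params <- function(Vmax, Km, t_half = 30, f_ttma = 0.02) {
  check_scalar(Vmax, "Vmax", positive = TRUE)
  check_scalar(Km, "Km", positive = TRUE)
  check_scalar(t_half, "t_half", positive = TRUE)
  check_scalar(f_ttma, "f_ttma")
  if (f_ttma <= 0 || f_ttma > 1) abort_domain("`f_ttma` must be in (0, 1]")
  structure(list(Vmax = Vmax, Km = Km, t_half = t_half, f_ttma = f_ttma),
            class = "metabolism_params")
}

#' Create subject physiology
#'
#' @param age Age in years.
#' @param body_weight Body weight, kg.
#' @param P_blood_air Blood:air partition coefficient (dimensionless).
#' @param Q_alv Alveolar ventilation, L/min.
#' @param Q_card Cardiac output, L/min.
#' @param urine_void_volume Urine volume per micturition, L.
#' @param micturition_interval Time between successive bladder voids, min.
#'   Defaults to 180 (three hours), the assumed voiding interval over which
#'   urinary metabolites accumulate.
#' @param urinary_creatinine Urinary creatinine, g/L, used to express tt-MA
#'   per gram creatinine.
#' @return A `physiology` object.
#' @export
physiology <- function(age = 9, body_weight = 32, P_blood_air = 8.2,
                       Q_alv = 2.0, Q_card = 3.0,
                       urine_void_volume = 0.2, micturition_interval = 180,
                       urinary_creatinine = 1.0) {
  check_scalar(age, "age", positive = TRUE)
  check_scalar(body_weight, "body_weight", positive = TRUE)
  check_scalar(P_blood_air, "P_blood_air", positive = TRUE)
  check_scalar(Q_alv, "Q_alv", positive = TRUE)
  check_scalar(Q_card, "Q_card", positive = TRUE)
  check_scalar(urine_void_volume, "urine_void_volume", positive = TRUE)
  check_scalar(micturition_interval, "micturition_interval", positive = TRUE)
  check_scalar(urinary_creatinine, "urinary_creatinine", positive = TRUE)
  structure(list(age = age, body_weight = body_weight,
                 P_blood_air = P_blood_air, Q_alv = Q_alv, Q_card = Q_card,
                 urine_void_volume = urine_void_volume,
                 micturition_interval = micturition_interval,
                 urinary_creatinine = urinary_creatinine),
            class = "physiology")
}

#' Assemble a full PBPK parameter set
#'
#' @param compartments A list of exactly four [compartment_params()] objects,
#'   one per compartment name (richly perfused, fat, poorly perfused, liver).
#' @param metabolism A [metabolism_params()] object; metabolism is hepatic,
#'   so the liver compartment must be present.
#' @param constants Chemistry constants: molecular weights of benzene and
#'   tt-MA (g/mol) and the molar gas volume (L/mol) used for ppm conversion.
#' @param provenance Named character vector mapping parameter names to a
#'   free-text source citation; carried verbatim into run logs so that
#'   illustrative defaults are never mistaken for literature values.
#' @return A `pbpk_parameters` object.
#' @export
pbpk_parameters <- function(compartments, metabolism,
                            constants = list(mw_benzene = 78.11,
                                             mw_ttma = 142.11,
                                             molar_volume = 24.45),
                            provenance = character()) {
  if (!inherits(metabolism, "metabolism_params")) {
    abort_config("`metabolism` must be a metabolism_params object")
  }
  nms <- vapply(compartments, function(x) {
    if (!inherits(x, "compartment_params")) {
      abort_config("every compartment must be a compartment_params object")
    }
    x$name
  }, character(1))
  if (!setequal(nms, COMPARTMENT_NAMES) || anyDuplicated(nms)) {
    abort_config(paste("`compartments` must contain exactly one of each:",
                       paste(COMPARTMENT_NAMES, collapse = ", ")))
  }
  names(compartments) <- nms
  for (k in c("mw_benzene", "mw_ttma", "molar_volume")) {
    check_scalar(constants[[k]] %||% NA_real_, k, positive = TRUE)
  }
  structure(list(compartments = compartments[COMPARTMENT_NAMES],
                 metabolism = metabolism, constants = constants,
                 provenance = provenance),
            class = "pbpk_parameters")
}

#' Default PBPK parameter set
#'
#' Illustrative defaults for a school-age child (reference: 9 years, 32 kg).
#' Flows are fractions of a 3 L/min cardiac output, volumes fractions of
#' body weight, and partition coefficients are in the range reported for
#' benzene in human tissue. These are plausible order-of-magnitude values
#' intended for testing and demonstration: replace them with
#' literature-derived values (via [read_pbpk_config()]) before drawing
#' subject-specific conclusions. Every entry carries a provenance string
#' saying exactly that.
#'
#' @return A `pbpk_parameters` object.
#' @export
#' @examples
#' p <- default_pbpk_parameters()
#' p$compartments$liver
default_pbpk_parameters <- function() {
  prov <- c(
    compartments = "illustrative defaults - replace with literature values",
    metabolism = "illustrative defaults - replace with literature values",
    constants = "benzene 78.11 g/mol, tt-MA (C6H6O4) 142.11 g/mol, 24.45 L/mol at 25 C / 1 atm"
  )
  pbpk_parameters(
    compartments = list(
      compartment_params("richly_perfused", Q = 1.35, V = 1.60, P = 1.6),
      compartment_params("fat",             Q = 0.15, V = 4.80, P = 28.0),
      compartment_params("poorly_perfused", Q = 0.75, V = 19.8, P = 1.0),
      compartment_params("liver",           Q = 0.75, V = 0.85, P = 1.7)
    ),
    metabolism = metabolism_params(Vmax = 0.35, Km = 0.35,
                                   t_half = 30, f_ttma = 0.02),
    provenance = prov
  )
}

#' Scale reference physiology to a child's anthropometry
#'
#' Ventilation and cardiac output scale allometrically with body weight
#' (exponent 0.75) relative to the 32 kg reference child; urine void volume
#' scales linearly with weight. Urinary creatinine, when measured, replaces
#' the reference value.
#'
#' @param age Age, years.
#' @param body_weight Body weight, kg.
#' @param urinary_creatinine Measured urinary creatinine, g/L, or `NULL` to
#'   keep the reference value.
#' @param base Reference [physiology()].
#' @return A `physiology` object for this child.
#' @export
child_physiology <- function(age, body_weight, urinary_creatinine = NULL,
                             base = physiology()) {
  check_scalar(age, "age", positive = TRUE)
  check_scalar(body_weight, "body_weight", positive = TRUE)
  f_allo <- (body_weight / base$body_weight)^0.75
  f_lin <- body_weight / base$body_weight
  physiology(
    age = age, body_weight = body_weight,
    P_blood_air = base$P_blood_air,
    Q_alv = base$Q_alv * f_allo, Q_card = base$Q_card * f_allo,
    urine_void_volume = base$urine_void_volume * f_lin,
    micturition_interval = base$micturition_interval,
    urinary_creatinine = urinary_creatinine %||% base$urinary_creatinine
  )
}

#' Read PBPK parameters and physiology from a YAML config file
#'
#' The config mirrors the structure of the parameter objects: a
#' `compartments` section with one block per compartment (keys `Q`, `V`,
#' `P`), a `metabolism` section (`Vmax`, `Km`, `t_half`, `f_ttma`), an
#' optional `physiology` section and an optional `constants` section. Every
#' numeric key admits a sibling `<key>_source` string recording where the
#' value came from; these are collected into the returned object's
#' `provenance` field. Keys not present fall back to the package defaults.
#'
#' @param path Path to a YAML file; see
#'   `system.file("extdata", "pbpk_defaults.yaml", package = "benzrisk")`
#'   for a complete annotated example.
#' @return A list with elements `params` ([pbpk_parameters()]) and
#'   `physiology` ([physiology()]).
#' @export
read_pbpk_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  defaults <- default_pbpk_parameters()
  prov <- character()
  grab <- function(section, key, fallback, label = key) {
    val <- section[[key]] %||% fallback
    src <- section[[paste0(key, "_source")]]
    if (!is.null(src)) prov[[label]] <<- src
    val
  }
  comps <- lapply(COMPARTMENT_NAMES, function(nm) {
    sec <- cfg$compartments[[nm]] %||% list()
    def <- defaults$compartments[[nm]]
    compartment_params(nm,
                       Q = grab(sec, "Q", def$Q, paste0(nm, ".Q")),
                       V = grab(sec, "V", def$V, paste0(nm, ".V")),
                       P = grab(sec, "P", def$P, paste0(nm, ".P")))
  })
  msec <- cfg$metabolism %||% list()
  met <- metabolism_params(
    Vmax = grab(msec, "Vmax", defaults$metabolism$Vmax),
    Km = grab(msec, "Km", defaults$metabolism$Km),
    t_half = grab(msec, "t_half", defaults$metabolism$t_half),
    f_ttma = grab(msec, "f_ttma", defaults$metabolism$f_ttma)
  )
  csec <- cfg$constants %||% list()
  constants <- list(
    mw_benzene = grab(csec, "mw_benzene", defaults$constants$mw_benzene),
    mw_ttma = grab(csec, "mw_ttma", defaults$constants$mw_ttma),
    molar_volume = grab(csec, "molar_volume", defaults$constants$molar_volume)
  )
  psec <- cfg$physiology %||% list()
  base <- physiology()
  phys <- physiology(
    age = grab(psec, "age", base$age),
    body_weight = grab(psec, "body_weight", base$body_weight),
    P_blood_air = grab(psec, "P_blood_air", base$P_blood_air),
    Q_alv = grab(psec, "Q_alv", base$Q_alv),
    Q_card = grab(psec, "Q_card", base$Q_card),
    urine_void_volume = grab(psec, "urine_void_volume", base$urine_void_volume),
    micturition_interval = grab(psec, "micturition_interval",
                                base$micturition_interval),
    urinary_creatinine = grab(psec, "urinary_creatinine",
                              base$urinary_creatinine)
  )
  params <- pbpk_parameters(comps, met, constants = constants,
                            provenance = if (length(prov)) unlist(prov)
                                         else defaults$provenance)
  list(params = params, physiology = phys)
}

#' @export
print.pbpk_parameters <- function(x, ...) {
  cat("Four-compartment benzene PBPK parameters\n")
  for (cp in x$compartments) {
    cat(sprintf("  %-16s Q = %.3g L/min, V = %.3g L, P = %.3g\n",
                cp$name, cp$Q, cp$V, cp$P))
  }
  m <- x$metabolism
  cat(sprintf("  metabolism: Vmax = %.3g mg/min, Km = %.3g mg/L, f_ttma = %.3g\n",
              m$Vmax, m$Km, m$f_ttma))
  invisible(x)
}
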
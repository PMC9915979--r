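#' Pipeline configuration
#'
#' Bundles paths and mode flags for an end-to-end run: cohort CSV in,
#' exclusion + scenario reports out.
#'
#' @param cohort_csv Path to a cohort CSV ([cohort-schema]).
#' @param out_dir Output directory (created if absent).
#' @param params_config Optional YAML parameter file for
#'   [read_pbpk_config()]; `NULL` uses package defaults.
#' @param arterial_mode `"equilibrium"` or `"mass_balance"`.
#' @param inversion_mode `"per_child"` or `"pooled"`.
#' @param loq Limit of quantification, mg/L.
#' @param table1_override_air_conc Optional air concentration (mg/m^3) used
#'   for the scenario table in place of the cohort-inverted mean — e.g. an
#'   externally reported estimate whose downstream risks are to be
#'   reproduced.
#' @param scenario_c_ce_override Optional chronic exposure (mg/m^3) for the
#'   lifetime scenario; see [risk_table()].
#' @param tox A [toxicity_criteria()] object.
#' @param burden Population-burden inputs: a list with `n_units`,
#'   `children_per_unit`, `ref_population`.
#' @param seed Integer seed recorded in the run log (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort_csv, out_dir, params_config = NULL,
                            arterial_mode = "equilibrium",
                            inversion_mode = "per_child", loq = 0.06,
                            table1_override_air_conc = NULL,
                            scenario_c_ce_override = NULL,
                            tox = toxicity_criteria(),
                            burden = list(n_units = 234, children_per_unit = 2,
                                          ref_population = 7041),
                            seed = 1) {
  if (!is.null(table1_override_air_conc)) {
    check_scalar(table1_override_air_conc, "table1_override_air_conc",
                 nonnegative = TRUE)
  }
  if (!is.null(scenario_c_ce_override)) {
    check_scalar(scenario_c_ce_override, "scenario_c_ce_override",
                 nonnegative = TRUE)
  }
  structure(list(cohort_csv = cohort_csv, out_dir = out_dir,
                 params_config = params_config,
                 arterial_mode = arterial_mode,
                 inversion_mode = inversion_mode, loq = loq,
                 table1_override_air_conc = table1_override_air_conc,
                 scenario_c_ce_override = scenario_c_ce_override,
                 tox = tox, burden = burden, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full reverse-dosimetry and risk pipeline
#'
#' Executes filter -> invert -> summarize -> scenarios -> risks -> burden
#' and writes `exclusions.csv`, `scenarios.csv`, `scenarios.json` (scenario
#' table plus population burden) and `run.log` (seed, config hash, every
#' PBPK parameter with its provenance) to the output directory. If all
#' children are excluded, the exclusion report is still written before an
#' empty-cohort error is raised.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list: `exclusion` (exclusion_report), `estimate`
#'   (cohort_estimate), `air_conc_used`, `scenarios` (risk_table
#'   data.frame), `burden` (population_burden), `paths` (written files).
#' @export
#' @examples
#' csv <- system.file("extdata", "cohort_fixture_synthetic.csv",
#'                    package = "benzrisk")
#' cfg <- pipeline_config(csv, tempfile("run"),
#'                        table1_override_air_conc = 5.85,
#'                        scenario_c_ce_override = 1.11)
#' res <- run_pipeline(cfg)
#' res$scenarios[, c("scenario", "CE", "HQ")]
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) {
    abort_config("`cfg` must be a pipeline_config")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  setup <- if (is.null(cfg$params_config)) {
    list(params = default_pbpk_parameters(), physiology = physiology())
  } else {
    read_pbpk_config(cfg$params_config)
  }

  cohort <- read_cohort_csv(cfg$cohort_csv)
  excl <- filter_cohort(cohort, loq = cfg$loq)
  excl_path <- file.path(cfg$out_dir, "exclusions.csv")
  ret_out <- excl$retained
  ret_out$reason <- rep("retained", nrow(ret_out))
  excl_out <- rbind(ret_out, excl$excluded)
  utils::write.csv(excl_out, excl_path, row.names = FALSE, quote = FALSE)

  if (excl$n_retained == 0) {
    abort_empty_cohort(sprintf(
      "all %d children excluded (exclusion report written to %s)",
      excl$n_input, excl_path))
  }

  est <- cohort_estimate(excl, setup$params, base_phys = setup$physiology,
                         mode = cfg$inversion_mode,
                         arterial_mode = cfg$arterial_mode)
  air_used <- cfg$table1_override_air_conc %||% est$air_conc_mean

  scen <- risk_table(air_used, tox = cfg$tox,
                     scenario_c_ce_override = cfg$scenario_c_ce_override)
  scen_csv <- file.path(cfg$out_dir, "scenarios.csv")
  utils::write.csv(scen, scen_csv, row.names = FALSE, quote = FALSE)

  burden <- population_burden(
    cfg$burden$n_units, cfg$burden$children_per_unit,
    cfg$burden$ref_population,
    risk_interval = c(scen$ICR_per_1000_low[scen$scenario == "a"],
                      scen$ICR_per_1000_high[scen$scenario == "a"]) / 1000
  )

  json_path <- file.path(cfg$out_dir, "scenarios.json")
  jsonlite::write_json(
    list(air_concentration_mg_m3 = air_used,
         cohort = list(n = est$n, ttma_mean = est$ttma_mean,
                       ttma_sd = est$ttma_sd,
                       air_conc_mean = est$air_conc_mean,
                       air_conc_sd = est$air_conc_sd),
         scenarios = scen,
         population_burden = unclass(burden)),
    json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )

  log_path <- file.path(cfg$out_dir, "run.log")
  cfg_for_hash <- cfg[setdiff(names(cfg), "out_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  saveRDS(cfg_for_hash, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  prov <- setup$params$provenance
  log_lines <- c(
    sprintf("seed: %d", cfg$seed),
    sprintf("config_hash: %s", cfg_hash),
    sprintf("cohort: %s (%d records, %d retained)", cfg$cohort_csv,
            excl$n_input, excl$n_retained),
    sprintf("arterial_mode: %s; inversion_mode: %s", cfg$arterial_mode,
            cfg$inversion_mode),
    sprintf("air_concentration_used: %.6g mg/m^3%s", air_used,
            if (is.null(cfg$table1_override_air_conc)) " (cohort inversion)"
            else " (override)"),
    "parameter provenance:",
    sprintf("  %s: %s", names(prov), prov)
  )
  writeLines(log_lines, log_path)

  invisible(list(exclusion = excl, estimate = est, air_conc_used = air_used,
                 scenarios = scen, burden = burden,
                 paths = c(exclusions = excl_path, scenarios_csv = scen_csv,
                           scenarios_json = json_path, log = log_path)))
}
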
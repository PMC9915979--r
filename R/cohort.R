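#' Cohort table schema
#'
#' A cohort is a plain `data.frame` with one row per child and columns
#' `child_id`, `age_y`, `weight_kg`, `height_cm`, `ttma_mg_L`, `below_loq`,
#' `creatinine_g_L`, `acr_mg_g`, `acr_normal`. `ttma_mg_L` may be `NA` when
#' `below_loq` is `TRUE` (a censored measurement with no reported value).
#'
#' @name cohort-schema
NULL

COHORT_COLUMNS <- c("child_id", "age_y", "weight_kg", "height_cm",
                    "ttma_mg_L", "below_loq", "creatinine_g_L",
                    "acr_mg_g", "acr_normal")

#' Validate a cohort table against the schema
#'
#' @param cohort A data.frame with the columns of [cohort-schema].
#' @return The validated data.frame, invisibly usable in pipelines.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) abort_validation("cohort must be a data.frame")
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols)) {
    abort_validation(paste("cohort is missing columns:",
                           paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(cohort$child_id)) {
    dup <- unique(cohort$child_id[duplicated(cohort$child_id)])
    abort_validation(paste("duplicate child_id:", paste(dup, collapse = ", ")))
  }
  if (nrow(cohort) == 0) return(cohort)
  for (col in c("age_y", "weight_kg", "height_cm", "creatinine_g_L")) {
    v <- cohort[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      abort_validation(sprintf("column `%s` must be positive and finite", col))
    }
  }
  if (!is.logical(cohort$below_loq) || anyNA(cohort$below_loq)) {
    abort_validation("column `below_loq` must be logical without NA")
  }
  if (!is.logical(cohort$acr_normal) || anyNA(cohort$acr_normal)) {
    abort_validation("column `acr_normal` must be logical without NA")
  }
  tt <- cohort$ttma_mg_L
  if (!is.numeric(tt)) abort_validation("column `ttma_mg_L` must be numeric")
  bad_na <- is.na(tt) & !cohort$below_loq
  if (any(bad_na)) {
    abort_validation("`ttma_mg_L` may be NA only when `below_loq` is TRUE")
  }
  if (any(tt < 0, na.rm = TRUE)) {
    abort_validation("column `ttma_mg_L` must be >= 0")
  }
  cohort
}

#' Read and write cohort CSV files
#'
#' @param path Path to a CSV file following [cohort-schema].
#' @return `read_cohort_csv` returns a validated cohort data.frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("cohort file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(child_id = "character")),
    error = function(e) abort_validation(
      sprintf("failed to parse cohort CSV %s: %s", path, conditionMessage(e)))
  )
  for (col in c("below_loq", "acr_normal")) {
    if (col %in% names(df) && !is.logical(df[[col]])) {
      df[[col]] <- as.logical(df[[col]])
    }
  }
  validate_cohort(df)
}

#' @rdname read_cohort_csv
#' @param cohort A cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the cohort exclusion rules
#'
#' Two sequential exclusions: first, children whose tt-MA is censored below
#' the assay's limit of quantification (the `below_loq` flag, or a reported
#' value under `loq`); second, among the remainder, children with an
#' abnormal albumin/creatinine ratio (`acr_normal == FALSE`), whose renal
#' function violates the toxicokinetic model's assumptions. A record failing
#' both rules counts as below-LOQ. The partition is exhaustive and disjoint.
#'
#' @param cohort A cohort data.frame ([cohort-schema]).
#' @param loq Limit of quantification, in the units of `ttma_mg_L` (mg/L).
#' @param require_normal_acr Apply the albumin/creatinine exclusion?
#' @return An `exclusion_report`: counts `n_input`, `n_below_loq`,
#'   `n_abnormal_acr`, `n_retained`; `retained` (cohort rows kept) and
#'   `excluded` (cohort rows dropped, with a `reason` column, one of
#'   `"below_loq"`, `"abnormal_acr"`).
#' @export
#' @examples
#' rep <- filter_cohort(fixture_cohort_41())
#' c(rep$n_below_loq, rep$n_abnormal_acr, rep$n_retained)
filter_cohort <- function(cohort, loq = 0.06, require_normal_acr = TRUE) {
  validate_cohort(cohort)
  check_scalar(loq, "loq", positive = TRUE)
  below <- cohort$below_loq | (!is.na(cohort$ttma_mg_L) & cohort$ttma_mg_L < loq)
  abnormal <- !below & if (require_normal_acr) !cohort$acr_normal else FALSE
  keep <- !below & !abnormal
  excluded <- cohort[!keep, , drop = FALSE]
  excluded$reason <- ifelse(below[!keep], "below_loq", "abnormal_acr")
  structure(list(
    n_input = nrow(cohort),
    n_below_loq = sum(below),
    n_abnormal_acr = sum(abnormal),
    n_retained = sum(keep),
    retained = cohort[keep, , drop = FALSE],
    excluded = excluded,
    loq = loq
  ), class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Cohort exclusion report (LOQ = %g mg/L)\n", x$loq))
  cat(sprintf("  input:          %d children\n", x$n_input))
  cat(sprintf("  below LOQ:      %d excluded\n", x$n_below_loq))
  cat(sprintf("  abnormal ACR:   %d excluded\n", x$n_abnormal_acr))
  cat(sprintf("  retained:       %d children\n", x$n_retained))
  invisible(x)
}

#' Invert the forward model: urinary tt-MA to air benzene
#'
#' Solves `ttma_urine_forward(c) = ttma_obs` for the air concentration `c`.
#' The forward map is continuous and strictly increasing below metabolic
#' saturation, so a bracketing root search is exact: the upper bracket is
#' doubled from 1 mg/m^3 until it straddles the observation, then
#' [stats::uniroot()] refines it. Convergence is verified by evaluating the
#' forward model at the root (relative mismatch below `rel_tol`).
#'
#' @param ttma_obs Observed urinary tt-MA, mg/L. Must be below the
#'   model's saturation bound ([ttma_saturation_bound()]).
#' @param params A [pbpk_parameters()] object.
#' @param phys A [physiology()] object.
#' @param rel_tol Relative tolerance on the reproduced tt-MA, default 1e-9.
#' @param ... Passed to [ttma_urine_forward()] (e.g. `arterial_mode`).
#' @return Estimated air benzene concentration, mg/m^3.
#' @export
#' @examples
#' p <- default_pbpk_parameters(); ph <- physiology()
#' y <- ttma_urine_forward(5.85, p, ph)$ttma_conc
#' invert_air_concentration(y, p, ph)  # ~5.85
invert_air_concentration <- function(ttma_obs, params, phys,
                                     rel_tol = 1e-9, ...) {
  check_scalar(ttma_obs, "ttma_obs", nonnegative = TRUE)
  if (ttma_obs == 0) return(0)
  bound <- ttma_saturation_bound(params, phys)
  if (ttma_obs >= bound) {
    abort_saturation(sprintf(
      "observed tt-MA %.4g mg/L is at or above the metabolic saturation bound %.4g mg/L; no air concentration can explain it",
      ttma_obs, bound), bound = bound)
  }
  fwd <- function(c_inh) ttma_urine_forward(c_inh, params, phys, ...)$ttma_conc
  upper <- 1
  it <- 0L
  while (fwd(upper) < ttma_obs) {
    upper <- upper * 2
    it <- it + 1L
    if (it > 200L) abort_numeric("failed to bracket the root: forward model does not reach the observation")
  }
  root <- stats::uniroot(function(c_inh) fwd(c_inh) - ttma_obs,
                         interval = c(0, upper),
                         tol = .Machine$double.eps^0.9 * max(upper, 1),
                         maxiter = 2000L)$root
  if (abs(fwd(root) - ttma_obs) > rel_tol * ttma_obs) {
    abort_numeric("root search did not converge to the requested tolerance")
  }
  root
}

#' Summarize a filtered cohort and invert exposure per child
#'
#' Computes the retained-subset tt-MA mean and sample SD (n - 1 denominator)
#' and reconstructs each child's air benzene concentration by inverting the
#' forward model with that child's physiology (anthropometry-scaled from the
#' reference via [child_physiology()]). The default is per-child inversion
#' followed by averaging; `mode = "pooled"` instead inverts the cohort-mean
#' tt-MA once with the reference physiology, for comparison.
#'
#' @param report An `exclusion_report` from [filter_cohort()].
#' @param params A [pbpk_parameters()] object.
#' @param base_phys Reference [physiology()] scaled to each child.
#' @param mode `"per_child"` (default) or `"pooled"`.
#' @param ... Passed to [invert_air_concentration()].
#' @return A `cohort_estimate`: `n`, `ttma_mean`, `ttma_sd`,
#'   `air_conc_per_child`, `air_conc_mean`, `air_conc_sd`, `mode`.
#' @export
cohort_estimate <- function(report, params, base_phys = physiology(),
                            mode = c("per_child", "pooled"), ...) {
  mode <- match.arg(mode)
  if (!inherits(report, "exclusion_report")) {
    abort_validation("`report` must be an exclusion_report from filter_cohort()")
  }
  ret <- report$retained
  if (nrow(ret) == 0) {
    abort_empty_cohort("no children retained after exclusions; nothing to invert")
  }
  ttma <- ret$ttma_mg_L
  ttma_mean <- mean(ttma)
  ttma_sd <- if (nrow(ret) > 1) stats::sd(ttma) else 0
  if (mode == "per_child") {
    air <- vapply(seq_len(nrow(ret)), function(i) {
      phys_i <- child_physiology(ret$age_y[i], ret$weight_kg[i],
                                 urinary_creatinine = ret$creatinine_g_L[i],
                                 base = base_phys)
      invert_air_concentration(ttma[i], params, phys_i, ...)
    }, numeric(1))
  } else {
    air <- invert_air_concentration(ttma_mean, params, base_phys, ...)
  }
  structure(list(
    n = nrow(ret),
    ttma_mean = ttma_mean,
    ttma_sd = ttma_sd,
    air_conc_per_child = air,
    air_conc_mean = mean(air),
    air_conc_sd = if (length(air) > 1) stats::sd(air) else 0,
    mode = mode
  ), class = "cohort_estimate")
}

#' @export
print.cohort_estimate <- function(x, ...) {
  cat(sprintf("Cohort exposure estimate (%s inversion, n = %d)\n", x$mode, x$n))
  cat(sprintf("  urinary tt-MA:  mean %.2f mg/L (SD %.2f)\n",
              x$ttma_mean, x$ttma_sd))
  cat(sprintf("  air benzene:    mean %.2f mg/m^3 (SD %.2f)\n",
              x$air_conc_mean, x$air_conc_sd))
  invisible(x)
}
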
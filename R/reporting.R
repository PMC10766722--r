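#' Packaged allergen reference-dose table
#'
#' Reference doses (mg of total allergenic food protein per portion)
#' currently recommended or issued by the VITAL 3.0 program, national
#' recommendations of Germany (based on VITAL 2.0 action levels), The
#' Netherlands and Belgium, and the 2021 FAO/WHO expert consultation.
#' Entries with no issued dose ("nd") carry `dose_mg = NA`.
#'
#' @return a tibble with columns `allergen`, `scheme`, `dose_mg`, `note`.
#' @export
reference_doses <- function() {
  path <- system.file("extdata", "reference_doses.csv",
                      package = "allerquant", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    allergen = readr::col_character(),
                    scheme = readr::col_character(),
                    dose_mg = readr::col_character(),
                    note = readr::col_character())) |>
    dplyr::mutate(dose_mg = suppressWarnings(as.numeric(.data$dose_mg)))
}

#' Convert a per-gram limit to a per-portion dose
#'
#' @param limit_per_gram method limit in ug TAFP per g of food.
#' @param portion_g portion size in grams (default 25 g, a chocolate
#'   bar).
#' @return absolute amount in mg TAFP per portion.
#' @export
#' @examples
#' portion_dose(0.08) # 0.002 mg over a 25 g portion
portion_dose <- function(limit_per_gram, portion_g = 25) {
  if (any(!is.finite(limit_per_gram) | limit_per_gram <= 0)) {
    stop("`limit_per_gram` must be positive", call. = FALSE)
  }
  assert_scalar_number(portion_g, "portion_g", lower = 0,
                       strict_lower = TRUE)
  limit_per_gram * portion_g / 1000
}

#' Per-gram method limit used for reference-dose comparison
#'
#' Returns the entry's limit in ug TAFP/g on the compliance basis: if the
#' entry defines a `compliance_cf` (e.g. egg white, where dose schemes
#' refer to egg-white protein and the theoretical ovalbumin fraction 0.54
#' replaces the experimental conversion factor), the TAFP limit is
#' rescaled by `ccf / compliance_cf`. Sample quantification never uses
#' `compliance_cf`.
#'
#' @param limit_tafp method limit in ug TAFP/g (from [limits()] with an
#'   entry attached).
#' @param entry the allergen's `aq_entry`.
#' @return the limit on the compliance basis, ug/g.
#' @export
compliance_limit <- function(limit_tafp, entry) {
  stopifnot(inherits(entry, "aq_entry"))
  if (is.null(entry$compliance_cf)) return(limit_tafp)
  limit_tafp * entry$ccf / entry$compliance_cf
}

#' Compare per-portion method limits with reference doses
#'
#' One verdict per (allergen, scheme) pair carrying a numeric dose;
#' schemes with no issued dose yield no verdict. A method is compliant
#' with a scheme when its per-portion limit does not exceed the reference
#' dose. Verdicts are monotone in the reference dose.
#'
#' @param limits_mg named numeric vector of per-portion method limits
#'   (mg TAFP), named by the dose-table allergen (Milk, Egg, Peanut,
#'   Soybean, Hazelnut, Almond).
#' @param doses a reference-dose tibble (default [reference_doses()]).
#' @return a tibble with columns `allergen`, `scheme`,
#'   `method_limit_mg`, `reference_mg`, `compliant`.
#' @export
compliance <- function(limits_mg, doses = reference_doses()) {
  if (is.null(names(limits_mg)) || any(!nzchar(names(limits_mg)))) {
    stop("`limits_mg` must be named by allergen", call. = FALSE)
  }
  assert_columns(doses, c("allergen", "scheme", "dose_mg"), "doses")
  tibble::tibble(allergen = names(limits_mg),
                 method_limit_mg = unname(limits_mg)) |>
    dplyr::inner_join(doses, by = "allergen") |>
    dplyr::filter(!is.na(.data$dose_mg)) |>
    dplyr::transmute(.data$allergen, .data$scheme,
                     .data$method_limit_mg,
                     reference_mg = .data$dose_mg,
                     compliant = .data$method_limit_mg <= .data$reference_mg)
}

#' Assemble the validation report
#'
#' Collects the pipeline outputs into one machine-readable structure and
#' (optionally) writes it as JSON. Rounding rules are applied only here:
#' R-squared to 3 decimals, per-portion limits to one significant figure,
#' quantified contents formatted as "value +/- U (k = 2)" when a budget
#' is present. All internal objects keep full precision.
#'
#' @param fits named list of `aq_fit` objects (calibration summary).
#' @param limits_list named list of `aq_limits` (sensitivity summary).
#' @param quant_results list of `aq_quant` objects.
#' @param precision_results list of `aq_precision` objects (optional).
#' @param recoveries list of `aq_recovery` objects (optional).
#' @param compliance_table tibble from [compliance()] (optional).
#' @param path optional output path for the JSON report.
#' @return the report as a list (invisibly when written to `path`).
#' @export
build_report <- function(fits = list(), limits_list = list(),
                         quant_results = list(), precision_results = list(),
                         recoveries = list(), compliance_table = NULL,
                         path = NULL) {
  calibration <- dplyr::bind_rows(lapply(fits, function(f)
    tibble::tibble(peptide = f$peptide, slope = f$slope,
                   sd_slope = f$sd_slope, intercept = f$intercept,
                   sd_intercept = f$sd_intercept,
                   r_squared = round(f$r_squared, 3), n = f$n)))
  sensitivity <- dplyr::bind_rows(lapply(limits_list, function(l)
    tibble::tibble(peptide = l$peptide, method = l$method, lod = l$lod,
                   loq = l$loq, lod_tafp = l$lod_tafp,
                   loq_tafp = l$loq_tafp)))
  quantification <- dplyr::bind_rows(lapply(quant_results, function(q) {
    rendered <- if (!is.null(q$budget) && !is.na(q$x0_tafp)) {
      u_tafp <- q$budget$u_x0 * q$x0_tafp / q$x0_peptide
      format_measurement(q$x0_tafp, q$budget$k * u_tafp, q$budget$k)
    } else NA_character_
    tibble::tibble(allergen = q$allergen, qtm = q$qtm,
                   x0_peptide = q$x0_peptide, x0_tafp = q$x0_tafp,
                   detected = q$detected, quantifiable = q$quantifiable,
                   flag = q$flag, reported = rendered)
  }))
  precision <- dplyr::bind_rows(lapply(precision_results, function(p) {
    comp <- p$components
    tibble::tibble(total_cv = p$total_cv,
                   factor = comp$factor,
                   weight = comp$weight,
                   poolable = p$anova_poolable)
  }))
  recovery_tbl <- dplyr::bind_rows(lapply(recoveries, function(r)
    tibble::tibble(allergen = r$allergen, qtm = r$qtm,
                   recovery_percent = r$recovery_percent)))
  if (!is.null(compliance_table)) {
    compliance_table <- dplyr::mutate(
      compliance_table, method_limit_mg = signif(.data$method_limit_mg, 1))
  }
  report <- list(calibration = calibration, sensitivity = sensitivity,
                 quantification = quantification, precision = precision,
                 recovery = recovery_tbl, compliance = compliance_table)
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
    return(invisible(report))
  }
  report
}
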
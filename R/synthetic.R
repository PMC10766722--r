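#' Default true calibration slopes for the packaged panel
#'
#' The quantitative-marker slopes are anchored at the published
#' matrix-matched sensitivities of the method (ratio units per fmol/uL);
#' qualitative-marker slopes are representative values of the same
#' magnitude. These are generator truths, not measurements.
#'
#' @return a named numeric vector (one slope per marker code).
#' @export
default_true_slopes <- function() {
  c("mc-FFV" = 0.02121, "mc-NAV" = 0.024,
    "mw-VLV" = 0.0259,  "mw-IDA" = 0.020,
    "ew-ISQ" = 0.0534,  "ew-GGL" = 0.045,
    "ey-ATA" = 0.0597,  "ey-NIG" = 0.050,
    "p-TAN"  = 0.0456,  "p-SPD"  = 0.038,
    "s-VLI"  = 0.0340,  "s-VFD"  = 0.029,
    "h-ALP"  = 0.0391,  "h-ADIY" = 0.035,
    "a-TEE"  = 0.0431,  "a-ADIF" = 0.040)
}

#' Calibration-curve simulation design
#'
#' Describes the study's ten-point calibration layout: levels 0-50
#' fmol/uL including the blank, heavy internal standard fixed at
#' 25 fmol/uL, three technical replicates per level. Noise acts on the
#' L/H ratio (the heavy-normalised signal): Gaussian with standard
#' deviation `sqrt((rel_sd * truth)^2 + abs_sd^2)`, i.e. a relative
#' component with an absolute floor that dominates near the blank.
#' `true_slope` parameterises the matrix-matched curve; standard curves
#' (no matrix suppression) use `true_slope / matrix_attenuation`.
#'
#' @param levels calibrant concentrations, fmol/uL, strictly increasing,
#'   non-negative.
#' @param heavy_level heavy internal-standard concentration, fmol/uL.
#' @param tech_reps technical replicates per level.
#' @param true_slope named numeric vector of matrix-curve slopes per
#'   marker code (default [default_true_slopes()]), or a single unnamed
#'   value applied to every simulated marker.
#' @param true_intercept true ratio at zero concentration (a small blank
#'   background keeps the noise model honest near zero).
#' @param rel_sd relative SD of the ratio noise.
#' @param abs_sd absolute SD floor of the ratio noise.
#' @param matrix_attenuation multiplicative matrix suppression of the
#'   slope (matrix slope / standard slope), in (0, 1].
#' @param heavy_area mean heavy peak area (arbitrary units).
#' @param heavy_cv log-normal CV of heavy peak areas (the L/H
#'   normalisation makes ratios insensitive to it by construction).
#' @return an object of class `aq_cal_design`.
#' @export
calibration_design <- function(levels = c(0, 0.5, 1, 1.5, 2, 3, 5, 10, 25, 50),
                               heavy_level = 25, tech_reps = 3,
                               true_slope = default_true_slopes(),
                               true_intercept = 0.002,
                               rel_sd = 0.05, abs_sd = 5e-4,
                               matrix_attenuation = 0.85,
                               heavy_area = 1e5, heavy_cv = 0.05) {
  if (any(levels < 0) || is.unsorted(levels, strictly = TRUE)) {
    stop("`levels` must be non-negative and strictly increasing",
         call. = FALSE)
  }
  assert_scalar_number(heavy_level, "heavy_level", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(tech_reps, "tech_reps", lower = 1)
  assert_scalar_number(rel_sd, "rel_sd", lower = 0)
  assert_scalar_number(abs_sd, "abs_sd", lower = 0)
  assert_scalar_number(matrix_attenuation, "matrix_attenuation", lower = 0,
                       upper = 1, strict_lower = TRUE)
  structure(list(levels = levels, heavy_level = heavy_level,
                 tech_reps = as.integer(tech_reps), true_slope = true_slope,
                 true_intercept = true_intercept, rel_sd = rel_sd,
                 abs_sd = abs_sd, matrix_attenuation = matrix_attenuation,
                 heavy_area = heavy_area, heavy_cv = heavy_cv),
            class = "aq_cal_design")
}

#' @noRd
.slope_for <- function(true_slope, code) {
  if (is.null(names(true_slope))) return(unname(true_slope[1]))
  if (!code %in% names(true_slope)) {
    stop("no true slope configured for marker ", code, call. = FALSE)
  }
  unname(true_slope[code])
}

#' @noRd
.marker_grid <- function(panel, codes = NULL) {
  grid <- dplyr::bind_rows(lapply(panel$entries, function(e) {
    dplyr::bind_rows(lapply(e$markers, function(m) {
      tibble::tibble(allergen = e$allergen, peptide = m$code,
                     transition_index = seq_len(nrow(m$transitions)))
    }))
  }))
  if (!is.null(codes)) grid <- grid[grid$peptide %in% codes, ]
  grid
}

#' Simulate a calibration experiment
#'
#' Generates a light/heavy peak-area table whose expected L/H ratio at
#' level x is `true_intercept + slope * x`, with the noise model of
#' [calibration_design()]. Heavy areas are drawn around a constant and the
#' light areas derived from the noisy ratio, so the internal-standard
#' normalisation the analysis relies on is structurally present.
#' Deterministic for a fixed seed.
#'
#' @param design an `aq_cal_design`.
#' @param panel an `aq_panel` (supplies markers and transition counts).
#' @param seed integer master seed (fans out to a stream labelled by the
#'   curve type); `NULL` uses the current RNG state.
#' @param curve_type `"matrix"` (matrix-matched, default) or `"standard"`.
#' @param peptides optional character vector restricting which markers are
#'   simulated.
#' @return a peak-area tibble (see [validate_peak_areas()]).
#' @export
simulate_calibration <- function(design, panel, seed = NULL,
                                 curve_type = c("matrix", "standard"),
                                 peptides = NULL) {
  stopifnot(inherits(design, "aq_cal_design"), inherits(panel, "aq_panel"))
  curve_type <- match.arg(curve_type)
  if (!is.null(seed)) {
    set.seed(substream_seed(seed, paste0("calibration/", curve_type)))
  }
  markers <- .marker_grid(panel, peptides)
  grid <- tidyr::expand_grid(
    markers,
    nominal_level = design$levels,
    technical_rep = paste0("t", seq_len(design$tech_reps)))
  slope <- vapply(grid$peptide, .slope_for, 0, true_slope = design$true_slope)
  if (curve_type == "standard") slope <- slope / design$matrix_attenuation
  truth <- design$true_intercept + slope * grid$nominal_level
  sd <- sqrt((design$rel_sd * truth)^2 + design$abs_sd^2)
  ratio <- pmax(0, truth + rnorm(nrow(grid), 0, sd))
  heavy <- design$heavy_area *
    exp(rnorm(nrow(grid), -design$heavy_cv^2 / 2, design$heavy_cv))
  out <- grid |>
    dplyr::mutate(
      sample_id = sprintf("cal-%s-L%g-%s", substr(curve_type, 1, 3),
                          .data$nominal_level, .data$technical_rep),
      condition = dplyr::if_else(.data$nominal_level == 0,
                                 "blank", "calibrant"),
      biological_rep = "b1", day = "d1", analyst = "a1",
      heavy = heavy, light = ratio * heavy)
  tidyr::pivot_longer(out, c("light", "heavy"), names_to = "channel",
                      values_to = "area")[PEAK_AREA_COLS]
}

#' Incurred-sample simulation design
#'
#' Mirrors the validation layout of the study: incurred levels 2, 4, 10
#' and 40 ug TAFP per g of chocolate, three biological (independently
#' prepared) samples each measured in three instrumental replicates, with
#' optional day and analyst factors for intermediate precision. Sample
#' preparation, day and analyst act multiplicatively on the expected
#' ratio (log-normal effects shared by all markers of a prepared sample);
#' the instrumental error is additive Gaussian on the ratio, so it
#' dominates near the detection limit while preparation dominates at high
#' content.
#'
#' @param levels incurred contents, ug TAFP/g.
#' @param bio_reps,tech_reps,days,analysts design sizes (>= 1).
#' @param sigma_sp log-scale SD of the sample-preparation effect.
#' @param sigma_ia absolute SD of the instrumental error (ratio units).
#' @param sigma_da,sigma_a log-scale SDs of the day and analyst effects.
#' @param true_slope,true_intercept calibration truth used to map
#'   concentration to expected ratio (must match the calibration design
#'   used to build the curves).
#' @param heavy_area,heavy_cv heavy-channel parameters as in
#'   [calibration_design()].
#' @return an object of class `aq_inc_design`.
#' @export
incurred_design <- function(levels = c(2, 4, 10, 40),
                            bio_reps = 3, tech_reps = 3,
                            days = 1, analysts = 1,
                            sigma_sp = 0.05, sigma_ia = 0.004,
                            sigma_da = 0.05, sigma_a = 0.02,
                            true_slope = default_true_slopes(),
                            true_intercept = 0.002,
                            heavy_area = 1e5, heavy_cv = 0.05) {
  for (nm in c("bio_reps", "tech_reps", "days", "analysts")) {
    assert_scalar_number(get(nm), nm, lower = 1)
  }
  for (nm in c("sigma_sp", "sigma_ia", "sigma_da", "sigma_a")) {
    assert_scalar_number(get(nm), nm, lower = 0)
  }
  structure(list(levels = levels, bio_reps = as.integer(bio_reps),
                 tech_reps = as.integer(tech_reps), days = as.integer(days),
                 analysts = as.integer(analysts), sigma_sp = sigma_sp,
                 sigma_ia = sigma_ia, sigma_da = sigma_da, sigma_a = sigma_a,
                 true_slope = true_slope, true_intercept = true_intercept,
                 heavy_area = heavy_area, heavy_cv = heavy_cv),
            class = "aq_inc_design")
}

#' Simulate incurred chocolate samples
#'
#' For each allergen the incurred content (ug TAFP/g) is inverted through
#' the reporting-unit equation to the expected marker concentration in the
#' digest (fmol/uL; see [from_tafp()]), mapped to an expected L/H ratio by
#' the calibration truth, and perturbed as
#' `truth * exp(e_SP + e_DA + e_A) + e_IA` with the component SDs of the
#' design. Factor labels are recorded so variance decomposition can
#' recover the components. With all SDs at zero the ratios equal the
#' inverted truth exactly.
#'
#' @param design an `aq_inc_design`.
#' @param panel an `aq_panel` (supplies cMM/cCF per allergen).
#' @param seed integer master seed; `NULL` uses the current RNG state.
#' @param allergens optional subset of allergen names to simulate.
#' @param scale internal multiplier on the expected content (used by the
#'   recovery simulator); default 1.
#' @param condition condition label for the generated rows.
#' @return a peak-area tibble.
#' @export
simulate_incurred <- function(design, panel, seed = NULL, allergens = NULL,
                              scale = 1, condition = "incurred") {
  stopifnot(inherits(design, "aq_inc_design"), inherits(panel, "aq_panel"))
  if (!is.null(seed)) {
    set.seed(substream_seed(seed, paste0("incurred/", condition)))
  }
  entries <- panel$entries
  if (!is.null(allergens)) entries <- entries[allergens]

  units <- tidyr::expand_grid(
    nominal_level = design$levels,
    day = paste0("d", seq_len(design$days)),
    analyst = paste0("a", seq_len(design$analysts)),
    biological_rep = paste0("b", seq_len(design$bio_reps)))
  day_eff <- stats::setNames(rnorm(design$days, 0, design$sigma_da),
                             paste0("d", seq_len(design$days)))
  an_eff <- stats::setNames(rnorm(design$analysts, 0, design$sigma_a),
                            paste0("a", seq_len(design$analysts)))
  units$sp_eff <- rnorm(nrow(units), 0, design$sigma_sp)
  units$mult <- exp(units$sp_eff + day_eff[units$day] + an_eff[units$analyst])

  out <- lapply(entries, function(e) {
    markers <- .marker_grid(marker_panel(list(e),
                                         panel$stock_rel_uncertainty))
    grid <- tidyr::expand_grid(
      units, markers,
      technical_rep = paste0("t", seq_len(design$tech_reps)))
    x_pep <- from_tafp(grid$nominal_level * scale, e)
    slope <- vapply(grid$peptide, .slope_for, 0,
                    true_slope = design$true_slope)
    truth <- design$true_intercept + slope * x_pep
    ratio <- pmax(0, truth * grid$mult +
                    rnorm(nrow(grid), 0, design$sigma_ia))
    heavy <- design$heavy_area *
      exp(rnorm(nrow(grid), -design$heavy_cv^2 / 2, design$heavy_cv))
    grid |>
      dplyr::mutate(
        sample_id = sprintf("%s-L%g-%s-%s-%s", condition,
                            .data$nominal_level, .data$day, .data$analyst,
                            .data$biological_rep),
        condition = condition, heavy = heavy, light = ratio * heavy)
  })
  dplyr::bind_rows(out) |>
    tidyr::pivot_longer(c("light", "heavy"), names_to = "channel",
                        values_to = "area") |>
    dplyr::select(dplyr::all_of(PEAK_AREA_COLS))
}

#' Discovery-proteomics simulation design
#'
#' Emulates the structure of a label-free protein-intensity table (one
#' MaxQuant-style proteinGroups row per accession and replicate): each
#' replicate draws intensities proportional to the true relative
#' abundances with log-normal noise.
#'
#' @param proteins data frame with columns `accession`, `molar_mass`,
#'   `rel_abundance` (summing to 1) and `carries_marker` (logical).
#' @param replicates number of independent replicates (>= 2).
#' @param intensity_cv relative SD of the log-normal intensity noise.
#' @param total_intensity total intensity per replicate (arbitrary units).
#' @return an object of class `aq_disc_design`.
#' @export
discovery_design <- function(proteins, replicates = 6,
                             intensity_cv = 0.10, total_intensity = 1e9) {
  proteins <- tibble::as_tibble(proteins)
  assert_columns(proteins,
                 c("accession", "molar_mass", "rel_abundance",
                   "carries_marker"), "proteins")
  if (abs(sum(proteins$rel_abundance) - 1) > 1e-8) {
    stop("`rel_abundance` must sum to 1 (got ",
         format(sum(proteins$rel_abundance)), ")", call. = FALSE)
  }
  assert_scalar_number(replicates, "replicates", lower = 2)
  assert_scalar_number(intensity_cv, "intensity_cv", lower = 0)
  structure(list(proteins = proteins, replicates = as.integer(replicates),
                 intensity_cv = intensity_cv,
                 total_intensity = total_intensity),
            class = "aq_disc_design")
}

#' A representative milk-ingredient discovery design
#'
#' Two alpha-S1-casein isoform accessions together carrying the marker at
#' relative abundance 0.374, plus the remaining major milk proteins as
#' distractors. Used as the packaged example of conversion-factor
#' estimation; the abundance profile is a stylised bovine-milk protein
#' profile, not a measured one.
#'
#' @param replicates,intensity_cv passed to [discovery_design()].
#' @return an `aq_disc_design`.
#' @export
default_discovery_design <- function(replicates = 6, intensity_cv = 0.10) {
  proteins <- tibble::tribble(
    ~accession,   ~molar_mass, ~rel_abundance, ~carries_marker,
    "P02662",     23615,       0.200,          TRUE,   # aS1-casein
    "P02662-VAR", 22974,       0.174,          TRUE,   # aS1-casein variant
    "P02663",     24348,       0.090,          FALSE,  # aS2-casein
    "P02666",     23583,       0.280,          FALSE,  # beta-casein
    "P02668",     18974,       0.090,          FALSE,  # kappa-casein
    "P02754",     18281,       0.095,          FALSE,  # beta-lactoglobulin
    "P00711",     14178,       0.036,          FALSE,  # alpha-lactalbumin
    "P02769",     66433,       0.035,          FALSE)  # serum albumin
  discovery_design(proteins, replicates = replicates,
                   intensity_cv = intensity_cv)
}

#' Simulate a discovery protein-intensity table
#'
#' @param design an `aq_disc_design`.
#' @param seed integer master seed; `NULL` uses the current RNG state.
#' @return a tibble with columns `replicate_id`, `accession`, `intensity`,
#'   `unique_peptide_count`.
#' @export
simulate_discovery <- function(design, seed = NULL) {
  stopifnot(inherits(design, "aq_disc_design"))
  if (!is.null(seed)) set.seed(substream_seed(seed, "discovery"))
  p <- design$proteins
  sdlog <- sqrt(log(1 + design$intensity_cv^2))
  grid <- tidyr::expand_grid(
    replicate_id = paste0("r", seq_len(design$replicates)),
    accession = p$accession)
  idx <- match(grid$accession, p$accession)
  noise <- exp(rnorm(nrow(grid), -sdlog^2 / 2, sdlog))
  grid$intensity <- design$total_intensity * p$rel_abundance[idx] * noise
  grid$unique_peptide_count <- ifelse(p$carries_marker[idx], 5L, 3L)
  grid
}

#' Simulate a spike-recovery experiment
#'
#' Generates a pair of peak-area tables for samples spiked with the
#' allergenic-ingredient extract before ("SB") and after ("SA") the
#' extraction/purification steps, at the same nominal level. The SB
#' expected content is `true_recovery` times the SA expected content; both
#' are carried through the ratio model of [simulate_incurred()] with
#' single-day, single-analyst noise.
#'
#' SB and SA are processed in parallel within one run, so the day and
#' analyst effects of the supplied design are zeroed for both arms:
#' arm-to-arm differences come from independent sample preparations and
#' instrumental error only.
#'
#' @param true_recovery generating recovery fraction in `[0, 1]`.
#' @param level spike level, ug TAFP/g (default 40, the study's level).
#' @param panel an `aq_panel`.
#' @param design an `aq_inc_design` providing noise parameters and
#'   replicate counts (its `levels` are ignored in favour of `level`).
#' @param seed integer master seed.
#' @param allergens optional subset of allergen names.
#' @return a list with peak-area tibbles `sb` and `sa`.
#' @export
simulate_recovery_pair <- function(true_recovery, level = 40,
                                   panel = default_panel(),
                                   design = incurred_design(levels = level),
                                   seed = NULL, allergens = NULL) {
  assert_scalar_number(true_recovery, "true_recovery", lower = 0, upper = 1)
  design$levels <- level
  design$sigma_da <- 0
  design$sigma_a <- 0
  sb <- simulate_incurred(design, panel, seed = seed, allergens = allergens,
                          scale = true_recovery, condition = "SB")
  sa <- simulate_incurred(design, panel, seed = if (!is.null(seed)) seed + 1,
                          allergens = allergens, scale = 1, condition = "SA")
  list(sb = sb, sa = sa)
}
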
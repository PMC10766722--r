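PEAK_AREA_COLS <- c("sample_id", "condition", "nominal_level", "peptide",
                    "transition_index", "channel", "area",
                    "biological_rep", "technical_rep", "day", "analyst")

VALID_CONDITIONS <- c("blank", "calibrant", "incurred", "SB", "SA")

#' Validate a long-format peak-area table
#'
#' Checks the fixed column set, the condition vocabulary, non-negative
#' areas, the light/heavy channel vocabulary and non-empty replicate
#' factor labels.
#'
#' @param areas a data frame of peak areas.
#' @return the table, invisibly, as a tibble.
#' @export
validate_peak_areas <- function(areas) {
  assert_columns(areas, PEAK_AREA_COLS, "areas")
  areas <- tibble::as_tibble(areas)
  bad <- setdiff(unique(areas$condition), VALID_CONDITIONS)
  if (length(bad)) {
    stop("invalid condition value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!all(areas$channel %in% c("light", "heavy"))) {
    stop("`channel` must be \"light\" or \"heavy\"", call. = FALSE)
  }
  if (any(!is.finite(areas$area) | areas$area < 0)) {
    stop("`area` must be finite and >= 0", call. = FALSE)
  }
  for (f in c("biological_rep", "technical_rep", "day", "analyst")) {
    if (any(is.na(areas[[f]]) | !nzchar(as.character(areas[[f]])))) {
      stop("replicate factor `", f, "` has empty labels", call. = FALSE)
    }
  }
  invisible(areas)
}

#' Read / write peak-area tables as CSV
#'
#' Fixed column names, RFC-4180 CSV, UTF-8, dot decimal separator.
#'
#' @param path file path.
#' @return `read_peak_areas()` returns a validated tibble;
#'   `write_peak_areas()` returns `path` invisibly.
#' @export
read_peak_areas <- function(path) {
  areas <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             nominal_level = readr::col_double(),
                             transition_index = readr::col_integer(),
                             area = readr::col_double(),
                             .default = readr::col_character()))
  validate_peak_areas(areas)
  tibble::as_tibble(areas)
}

#' @rdname read_peak_areas
#' @param areas a peak-area table.
#' @export
write_peak_areas <- function(areas, path) {
  validate_peak_areas(areas)
  readr::write_csv(areas[PEAK_AREA_COLS], path)
  invisible(path)
}

#' Compute light/heavy peak-area ratios
#'
#' The analytical signal is the ratio of the native ("light") peptide peak
#' area to that of its isotopically labelled ("heavy") internal standard,
#' formed per sample, peptide, transition and replicate. A light row with
#' no matching heavy row is an error (the internal standard is spiked into
#' every sample); a heavy area of zero yields a flagged record with
#' `ratio = NA` and `flag = "zero_heavy"`, which downstream stages treat
#' as "not detected" rather than as a zero signal.
#'
#' @param areas a peak-area table (see [validate_peak_areas()]).
#' @param transition `"quantifier"` (default) keeps only the designated
#'   quantifier transition per peptide; `"all"` returns one ratio per
#'   monitored transition (used by the detection rule and available for
#'   per-transition quantification).
#' @param quantifier_index which transition index acts as the quantifier
#'   (default 1).
#' @return a tibble with columns `sample_id`, `condition`,
#'   `nominal_level`, `peptide`, `transition_index`, `ratio`, `flag`, and
#'   the replicate factors.
#' @export
compute_lh_ratios <- function(areas, transition = c("quantifier", "all"),
                              quantifier_index = 1L) {
  transition <- match.arg(transition)
  areas <- validate_peak_areas(areas)
  if (transition == "quantifier") {
    areas <- dplyr::filter(areas, .data$transition_index == quantifier_index)
  }
  keys <- c("sample_id", "condition", "nominal_level", "peptide",
            "transition_index", "biological_rep", "technical_rep",
            "day", "analyst")
  wide <- tidyr::pivot_wider(areas, id_cols = dplyr::all_of(keys),
                             names_from = "channel", values_from = "area")
  if (!"heavy" %in% names(wide)) wide$heavy <- NA_real_
  if (!"light" %in% names(wide)) wide$light <- NA_real_
  missing_heavy <- is.na(wide$heavy) & !is.na(wide$light)
  if (any(missing_heavy)) {
    off <- wide[missing_heavy, c("sample_id", "peptide", "transition_index")]
    stop("missing heavy channel for: ",
         paste(utils::head(sprintf("%s/%s/t%d", off$sample_id, off$peptide,
                                   off$transition_index), 10),
               collapse = "; "),
         if (nrow(off) > 10) sprintf(" (and %d more)", nrow(off) - 10),
         call. = FALSE)
  }
  wide |>
    dplyr::mutate(
      flag = dplyr::case_when(
        .data$heavy == 0 ~ "zero_heavy",
        is.na(.data$light) ~ "missing_light",
        TRUE ~ "ok"),
      ratio = dplyr::if_else(.data$flag == "ok",
                             .data$light / .data$heavy, NA_real_)) |>
    dplyr::select(dplyr::all_of(keys), "ratio", "flag")
}
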
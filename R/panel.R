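#' Construct a peptide marker
#'
#' A marker is one tryptic signature peptide monitored by MRM, in both its
#' native ("light") and isotopically labelled ("heavy") form. The heavy
#' analogue carries +8 Da on a C-terminal lysine or +10 Da on a C-terminal
#' arginine.
#'
#' @param code short label used throughout result tables, e.g. `"mc-FFV"`.
#' @param sequence amino-acid sequence (uppercase, 20-letter alphabet).
#' @param role `"QTM"` (quantitative marker) or `"QLM"` (qualitative,
#'   confirmatory marker).
#' @param label_shift mass shift of the heavy analogue in Da (8 or 10).
#' @param transitions data frame with columns `precursor_mz`, `product_mz`
#'   (at least one row).
#' @return an object of class `aq_marker`.
#' @export
#' @examples
#' peptide_marker("mc-FFV", "FFVAPFPEVFGK", "QTM", 8,
#'                data.frame(precursor_mz = 692.9, product_mz = 920.5))
peptide_marker <- function(code, sequence, role, label_shift, transitions) {
  stopifnot(is.character(code), length(code) == 1L, nzchar(code))
  if (!is.character(sequence) || length(sequence) != 1L ||
      !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence)) {
    stop("`sequence` must be an uppercase string over the 20-AA alphabet ",
         "(marker ", code, ")", call. = FALSE)
  }
  if (!role %in% c("QTM", "QLM")) {
    stop("`role` must be \"QTM\" or \"QLM\" (marker ", code, ")",
         call. = FALSE)
  }
  assert_scalar_number(label_shift, "label_shift", lower = 0,
                       strict_lower = TRUE)
  transitions <- as.data.frame(transitions)
  assert_columns(transitions, c("precursor_mz", "product_mz"), "transitions")
  if (nrow(transitions) < 1L) {
    stop("`transitions` must have at least one row (marker ", code, ")",
         call. = FALSE)
  }
  structure(list(code = code, sequence = sequence, role = role,
                 label_shift = label_shift,
                 transitions = transitions[c("precursor_mz", "product_mz")]),
            class = "aq_marker")
}

#' Construct a per-allergen panel entry
#'
#' Bundles the markers of one allergenic ingredient with the quantities
#' needed to convert an interpolated peptide concentration (fmol/uL) into
#' total allergenic food protein (ug TAFP per g of food): the centered
#' molar mass `cmm` of the parent protein (midpoint of the min-max range
#' over sequenced isoforms/variants) and the centered conversion factor
#' `ccf` (fraction of the ingredient's total protein contributed by the
#' parent protein(s)), each with a standard uncertainty.
#'
#' @param allergen allergen/ingredient name, unique within a panel.
#' @param accessions character vector of parent-protein accessions (used to
#'   pick marker-carrying proteins out of discovery intensity tables).
#' @param markers list of [peptide_marker()] objects, exactly one of role
#'   `"QTM"`.
#' @param cmm centered molar mass, g/mol (> 0).
#' @param u_mm standard uncertainty of the molar mass, g/mol (>= 0).
#' @param ccf centered conversion factor, in (0, 1].
#' @param u_cf standard uncertainty of the conversion factor (>= 0).
#' @param compliance_cf optional alternative conversion factor used only
#'   when converting method limits for reference-dose comparison (e.g. the
#'   theoretical ovalbumin fraction of egg-white protein when the dose
#'   scheme refers to egg white rather than whole egg). Never used in
#'   sample quantification.
#' @return an object of class `aq_entry`.
#' @export
allergen_entry <- function(allergen, accessions, markers, cmm, u_mm,
                           ccf, u_cf, compliance_cf = NULL) {
  stopifnot(is.character(allergen), length(allergen) == 1L, nzchar(allergen))
  stopifnot(is.character(accessions), length(accessions) >= 1L)
  if (!is.list(markers) || !all(vapply(markers, inherits, TRUE, "aq_marker"))) {
    stop("`markers` must be a list of peptide_marker() objects", call. = FALSE)
  }
  codes <- vapply(markers, `[[`, "", "code")
  if (anyDuplicated(codes)) {
    stop("duplicate marker codes in entry \"", allergen, "\": ",
         paste(codes[duplicated(codes)], collapse = ", "), call. = FALSE)
  }
  roles <- vapply(markers, `[[`, "", "role")
  if (sum(roles == "QTM") != 1L) {
    stop("entry \"", allergen, "\" must have exactly one QTM marker (found ",
         sum(roles == "QTM"), ")", call. = FALSE)
  }
  assert_scalar_number(cmm, "cmm", lower = 0, strict_lower = TRUE)
  assert_scalar_number(u_mm, "u_mm", lower = 0)
  assert_scalar_number(ccf, "ccf", lower = 0, upper = 1, strict_lower = TRUE)
  assert_scalar_number(u_cf, "u_cf", lower = 0)
  if (!is.null(compliance_cf)) {
    assert_scalar_number(compliance_cf, "compliance_cf", lower = 0, upper = 1,
                         strict_lower = TRUE)
  }
  structure(list(allergen = allergen, accessions = accessions,
                 markers = markers, cmm = cmm, u_mm = u_mm, ccf = ccf,
                 u_cf = u_cf, compliance_cf = compliance_cf),
            class = "aq_entry")
}

#' Construct a marker panel
#'
#' @param entries list of [allergen_entry()] objects with unique allergen
#'   names and globally unique marker codes.
#' @param stock_rel_uncertainty relative concentration precision of the
#'   synthetic-peptide calibrant stocks, as quoted by the manufacturer from
#'   amino-acid analysis; the conservative default is 0.30.
#' @return an object of class `aq_panel`.
#' @export
marker_panel <- function(entries, stock_rel_uncertainty = 0.30) {
  if (!is.list(entries) || !length(entries) ||
      !all(vapply(entries, inherits, TRUE, "aq_entry"))) {
    stop("`entries` must be a non-empty list of allergen_entry() objects",
         call. = FALSE)
  }
  nm <- vapply(entries, `[[`, "", "allergen")
  if (anyDuplicated(nm)) {
    stop("duplicate allergen names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  codes <- unlist(lapply(entries, function(e)
    vapply(e$markers, `[[`, "", "code")))
  if (anyDuplicated(codes)) {
    stop("marker codes must be unique across the panel; duplicated: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "),
         call. = FALSE)
  }
  assert_scalar_number(stock_rel_uncertainty, "stock_rel_uncertainty",
                       lower = 0)
  if (stock_rel_uncertainty >= 1) {
    stop("`stock_rel_uncertainty` must be < 1", call. = FALSE)
  }
  names(entries) <- nm
  structure(list(entries = entries,
                 stock_rel_uncertainty = stock_rel_uncertainty),
            class = "aq_panel")
}

#' @export
print.aq_panel <- function(x, ...) {
  cat("<marker panel>", length(x$entries), "allergens,",
      nrow(panel_markers(x)), "markers; stock rel. uncertainty",
      x$stock_rel_uncertainty, "\n")
  print(panel_markers(x))
  invisible(x)
}

#' Tabulate the markers of a panel
#'
#' @param panel an `aq_panel`.
#' @return a tibble with one row per marker: allergen, code, role,
#'   sequence, label_shift, n_transitions.
#' @export
panel_markers <- function(panel) {
  stopifnot(inherits(panel, "aq_panel"))
  dplyr::bind_rows(lapply(panel$entries, function(e) {
    tibble::tibble(
      allergen = e$allergen,
      code = vapply(e$markers, `[[`, "", "code"),
      role = vapply(e$markers, `[[`, "", "role"),
      sequence = vapply(e$markers, `[[`, "", "sequence"),
      label_shift = vapply(e$markers, `[[`, 0, "label_shift"),
      n_transitions = vapply(e$markers, function(m) nrow(m$transitions), 0L))
  }))
}

#' The quantitative marker (QTM) of an entry
#' @param entry an `aq_entry`.
#' @return the `aq_marker` with role `"QTM"`.
#' @export
qtm <- function(entry) {
  stopifnot(inherits(entry, "aq_entry"))
  roles <- vapply(entry$markers, `[[`, "", "role")
  entry$markers[[which(roles == "QTM")]]
}

#' Write a marker panel to JSON
#'
#' @param panel an `aq_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [load_panel()]
#' @export
save_panel <- function(panel, path) {
  stopifnot(inherits(panel, "aq_panel"))
  obj <- list(
    stock_rel_uncertainty = panel$stock_rel_uncertainty,
    entries = lapply(unname(panel$entries), function(e) {
      list(allergen = e$allergen,
           accessions = as.list(e$accessions),
           cmm = e$cmm, u_mm = e$u_mm, ccf = e$ccf, u_cf = e$u_cf,
           compliance_cf = e$compliance_cf,
           markers = lapply(e$markers, function(m) {
             list(code = m$code, sequence = m$sequence, role = m$role,
                  label_shift = m$label_shift,
                  transitions = m$transitions)
           }))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read and validate a marker panel from JSON
#'
#' All panel invariants (role vocabulary, unique codes, exactly one QTM per
#' allergen, positive centered values) are enforced on load; violations
#' raise an error naming the offending field.
#'
#' @param path path to a JSON file written by [save_panel()] (or following
#'   the same schema).
#' @return an `aq_panel`.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$entries)) {
    stop("panel file has no `entries` field: ", path, call. = FALSE)
  }
  entries <- lapply(obj$entries, function(e) {
    markers <- lapply(e$markers, function(m) {
      tr <- dplyr::bind_rows(lapply(m$transitions, function(t)
        tibble::tibble(precursor_mz = as.numeric(t$precursor_mz),
                       product_mz = as.numeric(t$product_mz))))
      peptide_marker(m$code, m$sequence, m$role, as.numeric(m$label_shift), tr)
    })
    allergen_entry(e$allergen,
                   vapply(e$accessions, as.character, ""),
                   markers,
                   cmm = as.numeric(e$cmm), u_mm = as.numeric(e$u_mm),
                   ccf = as.numeric(e$ccf), u_cf = as.numeric(e$u_cf),
                   compliance_cf = if (!is.null(e$compliance_cf))
                     as.numeric(e$compliance_cf))
  })
  marker_panel(entries,
               stock_rel_uncertainty =
                 as.numeric(obj$stock_rel_uncertainty %||% 0.30))
}

#' @noRd
.default_transitions <- function(pre, prods) {
  data.frame(precursor_mz = pre, product_mz = prods)
}

#' The packaged six-allergen chocolate panel
#'
#' Eight entries (milk contributes caseinate and whey, egg contributes
#' white and yolk), each with one quantitative (QTM) and one qualitative
#' (QLM) marker and four monitored transitions per marker. The conversion
#' factors for milk caseinate (0.374), milk whey (0.193), egg white
#' (0.468) and peanut (0.695) are the experimentally published values with
#' their standard uncertainties; the remaining conversion factors and all
#' molar-mass isoform ranges are documented representative defaults
#' (synthetic, chosen to be field-plausible) that users should replace
#' with their own discovery-derived values for real work — see
#' [estimate_cf()] and [centered_molar_mass()].
#'
#' The egg-white entry carries `compliance_cf = 0.54` (theoretical
#' ovalbumin fraction of egg-white protein), used only when converting
#' method limits for comparison with reference doses that refer to
#' egg-white protein.
#'
#' @return an `aq_panel` with 8 entries.
#' @export
default_panel <- function() {
  mk <- peptide_marker
  entries <- list(
    allergen_entry(
      "Milk caseinate", c("P02662"),
      list(mk("mc-FFV", "FFVAPFPEVFGK", "QTM", 8,
              .default_transitions(692.87, c(920.49, 991.53, 1120.57, 627.33))),
           mk("mc-NAV", "NAVPITPTLNR", "QLM", 10,
              .default_transitions(598.34, c(854.49, 757.44, 543.30, 644.35)))),
      cmm = 23294.5, u_mm = 185.0, ccf = 0.374, u_cf = 0.009),
    allergen_entry(
      "Milk whey", c("P02754"),
      list(mk("mw-VLV", "VLVLDTDYK", "QTM", 8,
              .default_transitions(533.30, c(853.41, 754.34, 641.26, 526.23))),
           mk("mw-IDA", "IDALNENK", "QLM", 8,
              .default_transitions(458.74, c(688.36, 504.25, 617.31, 390.21)))),
      cmm = 18320.0, u_mm = 24.8, ccf = 0.193, u_cf = 0.002),
    allergen_entry(
      "Egg white", c("P01012"),
      list(mk("ew-ISQ", "ISQAVHAAHAEINEAGR", "QTM", 10,
              .default_transitions(583.64, c(752.37, 823.41, 894.45, 609.30))),
           mk("ew-GGL", "GGLEPINFQTAADQAR", "QLM", 10,
              .default_transitions(844.43, c(975.49, 1122.56, 846.43, 717.39)))),
      cmm = 42790.0, u_mm = 52.5, ccf = 0.468, u_cf = 0.003,
      compliance_cf = 0.54),
    allergen_entry(
      "Egg yolk", c("P87498", "P02845"),
      list(mk("ey-ATA", "ATAVSLLEWQR", "QTM", 10,
              .default_transitions(616.34, c(1059.57, 960.50, 873.47, 786.44))),
           mk("ey-NIG", "NIGELGVEK", "QLM", 8,
              .default_transitions(472.76, c(717.40, 604.32, 547.30, 418.23)))),
      cmm = 211000, u_mm = 288.7, ccf = 0.30, u_cf = 0.010),
    allergen_entry(
      "Peanut", c("O82580"),
      list(mk("p-TAN", "TANDLNLLILR", "QTM", 10,
              .default_transitions(620.87, c(1068.68, 954.64, 839.61, 726.53))),
           mk("p-SPD", "SPDIYNPQAGSLK", "QLM", 8,
              .default_transitions(695.35, c(1003.52, 840.46, 726.41, 499.30)))),
      cmm = 59200, u_mm = 173.2, ccf = 0.695, u_cf = 0.006),
    allergen_entry(
      "Soybean", c("P04776"),
      list(mk("s-VLI", "VLIVPQNFVVAAR", "QTM", 10,
              .default_transitions(706.93, c(1100.62, 987.53, 888.46, 614.37))),
           mk("s-VFD", "VFDGELQEGR", "QLM", 10,
              .default_transitions(575.28, c(903.43, 788.40, 731.38, 474.24)))),
      cmm = 55600, u_mm = 173.2, ccf = 0.40, u_cf = 0.030),
    allergen_entry(
      "Hazelnut", c("A0A0A0P7E3"),
      list(mk("h-ALP", "ALPDDVLANAFQISR", "QTM", 10,
              .default_transitions(807.93, c(1233.66, 1118.63, 1019.56, 706.39))),
           mk("h-ADIY", "ADIYTEQVGR", "QLM", 10,
              .default_transitions(576.29, c(966.48, 851.45, 688.39, 460.25)))),
      cmm = 58900, u_mm = 115.5, ccf = 0.50, u_cf = 0.020),
    allergen_entry(
      "Almond", c("E3SH28"),
      list(mk("a-TEE", "TEENAFINTLAGR", "QTM", 10,
              .default_transitions(710.85, c(1190.63, 1061.59, 947.55, 631.38))),
           mk("a-ADIF", "ADIFSPR", "QLM", 10,
              .default_transitions(403.21, c(619.33, 506.25, 359.18, 262.14)))),
      cmm = 62400, u_mm = 173.2, ccf = 0.65, u_cf = 0.010))
  marker_panel(entries, stock_rel_uncertainty = 0.30)
}
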
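#' Interpolate a peptide concentration from a calibration fit
#'
#' `x0 = (y0 - a) / b`. Negative interpolations (blank-level signals
#' scattering below the intercept) are floored at 0 and flagged via the
#' `"floored"` attribute; downstream decision rules treat floored values
#' as not detected.
#'
#' @param fit an `aq_fit` with positive slope.
#' @param y0 mean L/H ratio of the determined sample (vectorised).
#' @return concentration(s) in fmol/uL, with logical attribute
#'   `"floored"`.
#' @export
#' @examples
#' f <- fit_curve(tibble::tibble(nominal_level = 0:2,
#'                               ratio = 0.01 + 0.02 * (0:2)))
#' interpolate(f, 0.11) # 5 fmol/uL
interpolate <- function(fit, y0) {
  stopifnot(inherits(fit, "aq_fit"))
  if (fit$slope <= 0) {
    stop("calibration slope must be positive (b = ", format(fit$slope), ")",
         call. = FALSE)
  }
  x0 <- (y0 - fit$intercept) / fit$slope
  floored <- x0 < 0
  x0[floored] <- 0
  attr(x0, "floored") <- floored
  x0
}

#' Convert a peptide concentration to total allergenic food protein
#'
#' `x_TAFP [ug/g] = x_peptide [fmol/uL] * cMM / cCF * m * d`, where `cMM`
#' and `cCF` are the entry's centered molar mass and conversion factor,
#' `m = 1e-5` accounts for the 1:10 matrix-to-solvent extraction ratio
#' and SI prefix conversion, and `d = 1.33` is the digestion-protocol
#' dilution factor. Linear in the concentration; [from_tafp()] is its
#' exact inverse.
#'
#' @param x0_peptide peptide concentration(s), fmol/uL.
#' @param entry an `aq_entry` supplying `cmm` and `ccf`.
#' @param m,d protocol constants (defaults 1e-5 and 1.33).
#' @return content in ug TAFP per g of food.
#' @export
to_tafp <- function(x0_peptide, entry, m = 1e-5, d = 1.33) {
  stopifnot(inherits(entry, "aq_entry"))
  if (entry$ccf <= 0) stop("cCF must be positive", call. = FALSE)
  as.numeric(x0_peptide) * (entry$cmm / entry$ccf) * m * d
}

#' @rdname to_tafp
#' @param x0_tafp content(s) in ug TAFP/g to invert back to fmol/uL.
#' @export
from_tafp <- function(x0_tafp, entry, m = 1e-5, d = 1.33) {
  stopifnot(inherits(entry, "aq_entry"))
  if (entry$ccf <= 0) stop("cCF must be positive", call. = FALSE)
  as.numeric(x0_tafp) / ((entry$cmm / entry$ccf) * m * d)
}

#' Allergen detection rule over peptides and transitions
#'
#' An allergen is considered detected when at least `min_peptides`
#' marker peptides each have at least `min_transitions` transitions whose
#' interpolated concentration is greater than or equal to the
#' peptide-specific LOD (comparisons are inclusive). The rule is monotone:
#' adding qualifying evidence never revokes a detection.
#'
#' @param transition_values tibble with columns `peptide`,
#'   `transition_index`, `value` (interpolated concentration, fmol/uL;
#'   one row per transition, NA = not measurable).
#' @param lods named numeric vector of LODs (fmol/uL) per peptide.
#' @param min_peptides,min_transitions rule thresholds (defaults 2 and 2).
#' @param allow_single_peptide the two-peptide rule degenerates for an
#'   allergen with a single configured marker; this must be explicitly
#'   acknowledged by setting `TRUE`, which lowers `min_peptides` to 1.
#' @return a list with `detected` (logical) and `evidence` (tibble of
#'   qualifying peptide/transition pairs).
#' @export
detection_rule <- function(transition_values, lods, min_peptides = 2L,
                           min_transitions = 2L,
                           allow_single_peptide = FALSE) {
  assert_columns(transition_values, c("peptide", "transition_index", "value"),
                 "transition_values")
  peps <- unique(transition_values$peptide)
  if (length(peps) < 2L && !allow_single_peptide) {
    stop("only one peptide supplied; the >=2-peptide detection rule ",
         "degenerates - set allow_single_peptide = TRUE to override",
         call. = FALSE)
  }
  if (allow_single_peptide) min_peptides <- min(min_peptides, 1L)
  missing_lod <- setdiff(peps, names(lods))
  if (length(missing_lod)) {
    stop("no LOD supplied for peptide(s): ",
         paste(missing_lod, collapse = ", "), call. = FALSE)
  }
  ev <- transition_values |>
    dplyr::mutate(lod = unname(lods[.data$peptide]),
                  qualifies = !is.na(.data$value) & .data$value >= .data$lod)
  qualifying <- ev |>
    dplyr::filter(.data$qualifies) |>
    dplyr::select("peptide", "transition_index", "value", "lod")
  per_pep <- table(qualifying$peptide)
  detected <- sum(per_pep >= min_transitions) >= min_peptides
  list(detected = detected, evidence = qualifying)
}

#' Quantify one allergen in one sample
#'
#' Composes the full decision and quantification chain for a single
#' allergen and incurred/spiked sample: averages the quantifier-transition
#' L/H ratios of the quantitative marker (gated on the replicate-group
#' poolability established by one-way ANOVA), interpolates the
#' matrix-matched curve, applies the two-peptide/two-transition detection
#' rule using per-transition mean ratios interpolated on each marker's own
#' curve, compares the QTM concentration with its LOQ, converts to ug
#' TAFP/g and, when quantifiable, attaches the five-contributor
#' uncertainty budget.
#'
#' @param ratios ratio tibble for this allergen and sample: columns
#'   `peptide`, `transition_index`, `ratio` (replicate rows; from
#'   [compute_lh_ratios()] with `transition = "all"`).
#' @param fits named list of `aq_fit` objects, one per marker peptide.
#' @param entry the allergen's `aq_entry`.
#' @param limits_list optional named list of `aq_limits` per peptide;
#'   computed from `fits` with the intercept-SD method when omitted.
#' @param stock_rel relative stock-solution precision (default 0.30, the
#'   conservative manufacturer bound).
#' @param quantifier_index transition index used for quantification.
#' @param anova_ok result of the poolability check that licenses
#'   averaging replicates across groups; quantification refuses to
#'   average when `FALSE` unless `force = TRUE`.
#' @param force force quantification below LOQ or without poolability;
#'   forced sub-LOQ results carry flag `"<LOQ"`.
#' @param k coverage factor for the expanded uncertainty.
#' @param m,d conversion constants, see [to_tafp()].
#' @param allow_single_peptide passed to [detection_rule()].
#' @return an object of class `aq_quant`: `allergen`, `qtm`, `y0`, `p`,
#'   `x0_peptide`, `x0_tafp`, `detected`, `quantifiable`, `flag`,
#'   `budget` (an `aq_budget` or NULL), `limits`, `evidence`.
#' @export
quantify <- function(ratios, fits, entry, limits_list = NULL,
                     stock_rel = 0.30, quantifier_index = 1L,
                     anova_ok = TRUE, force = FALSE, k = 2,
                     m = 1e-5, d = 1.33, allow_single_peptide = FALSE) {
  assert_columns(ratios, c("peptide", "transition_index", "ratio"), "ratios")
  stopifnot(inherits(entry, "aq_entry"))
  if (!anova_ok && !force) {
    stop("replicate groups are not poolable (ANOVA); refusing to average ",
         "- use force = TRUE to override", call. = FALSE)
  }
  qtm_code <- qtm(entry)$code
  if (!qtm_code %in% names(fits)) {
    stop("no calibration fit supplied for QTM ", qtm_code, call. = FALSE)
  }
  peps <- intersect(unique(ratios$peptide), names(fits))
  if (is.null(limits_list)) {
    limits_list <- lapply(fits[peps], limits, method = "intercept_sd",
                          entry = entry, m = m, d = d)
  }

  # detection: per-transition mean ratios, each marker on its own curve
  trans_means <- ratios |>
    dplyr::filter(.data$peptide %in% peps, !is.na(.data$ratio)) |>
    dplyr::group_by(.data$peptide, .data$transition_index) |>
    dplyr::summarise(ratio = mean(.data$ratio), .groups = "drop")
  trans_means$value <- vapply(seq_len(nrow(trans_means)), function(i) {
    as.numeric(interpolate(fits[[trans_means$peptide[i]]],
                           trans_means$ratio[i]))
  }, 0)
  lods <- vapply(limits_list, `[[`, 0, "lod")
  det <- detection_rule(trans_means[c("peptide", "transition_index", "value")],
                        lods, allow_single_peptide = allow_single_peptide)

  # quantification on the QTM quantifier transition
  qr <- ratios$ratio[ratios$peptide == qtm_code &
                       ratios$transition_index == quantifier_index]
  qr <- qr[!is.na(qr)]
  if (!length(qr)) {
    stop("no quantifier-transition ratios for QTM ", qtm_code, call. = FALSE)
  }
  y0 <- mean(qr)
  p <- length(qr)
  fit <- fits[[qtm_code]]
  lim <- limits_list[[qtm_code]]
  x0 <- as.numeric(interpolate(fit, y0))
  quantifiable <- det$detected && x0 >= lim$loq
  flag <- "ok"
  budget <- NULL
  x0_tafp <- NA_real_
  if (quantifiable || (force && x0 > 0)) {
    if (!quantifiable) flag <- "<LOQ"
    x0_tafp <- to_tafp(x0, entry, m, d)
    reps_x0 <- as.numeric(interpolate(fit, qr))
    u_pr <- if (length(reps_x0) >= 2L) u_precision(reps_x0) else {
      warning("single replicate determination; precision contribution ",
              "set to 0", call. = FALSE)
      0
    }
    budget <- uncertainty_budget(
      x0 = x0,
      u_pr = u_pr,
      u_ss_rel = u_stock(stock_rel),
      u_rl = u_regression(fit, p, y0),
      entry = entry, k = k)
  } else if (!det$detected) {
    flag <- "not detected"
  } else {
    flag <- "<LOQ"
  }
  structure(list(allergen = entry$allergen, qtm = qtm_code, y0 = y0, p = p,
                 x0_peptide = x0, x0_tafp = x0_tafp,
                 detected = det$detected, quantifiable = quantifiable,
                 flag = flag, budget = budget, limits = lim,
                 evidence = det$evidence), class = "aq_quant")
}

#' @export
print.aq_quant <- function(x, ...) {
  cat(sprintf("<quantification: %s (%s)> detected: %s, quantifiable: %s",
              x$allergen, x$qtm, x$detected, x$quantifiable))
  if (!is.na(x$x0_tafp) && !is.null(x$budget)) {
    utafp <- x$budget$u_x0 * x$x0_tafp / x$x0_peptide
    cat("\n  ", format_measurement(x$x0_tafp, x$budget$k * utafp,
                                   x$budget$k), "ug TAFP/g")
  }
  if (x$flag != "ok") cat("  [", x$flag, "]", sep = "")
  cat("\n")
  invisible(x)
}
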
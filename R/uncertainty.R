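#' Precision contribution to the uncertainty budget
#'
#' Standard deviation over repeated determinations divided by sqrt(3)
#' (rectangular-distribution assumption). Both technical and biological
#' replicates enter, so the instrumental variability and the whole
#' sample-preparation chain are represented.
#'
#' @param observations replicate determinations (>= 2), on the peptide
#'   concentration scale (fmol/uL).
#' @return `sd(observations) / sqrt(3)`.
#' @export
u_precision <- function(observations) {
  observations <- observations[!is.na(observations)]
  if (length(observations) < 2L) {
    stop("need at least 2 observations", call. = FALSE)
  }
  sd(observations) / sqrt(3)
}

#' Stock-solution contribution (relative)
#'
#' The synthetic-peptide stock concentration enters the result only
#' through its relative error, so the contribution is a pure relative
#' term: the manufacturer-quoted relative precision divided by sqrt(3).
#' The conservative default takes the upper end (30%) of the quoted
#' 25-30% amino-acid-analysis precision.
#'
#' @param rel relative concentration precision of the stocks (fraction).
#' @return relative standard uncertainty `rel / sqrt(3)`.
#' @export
u_stock <- function(rel = 0.30) {
  assert_scalar_number(rel, "rel", lower = 0)
  rel / sqrt(3)
}

#' Regression (interpolation) contribution
#'
#' Standard uncertainty of an interpolated concentration from an OLS
#' calibration line:
#' `u_RL = S_y/x / b * sqrt(1/p + 1/n + (y0 - y_bar)^2 / (b^2 * Sxx))`
#' with `Sxx = sum((x_i - x_bar)^2)`. Decreasing in both the number of
#' sample replicates `p` and of calibration points `n`, and smallest when
#' the sample signal sits at the centroid of the curve.
#'
#' @param fit an `aq_fit`.
#' @param p number of replicate observations averaged into `y0`.
#' @param y0 mean L/H ratio of the determined sample.
#' @return `u_RL` in fmol/uL.
#' @export
u_regression <- function(fit, p, y0) {
  stopifnot(inherits(fit, "aq_fit"))
  assert_scalar_number(p, "p", lower = 1)
  if (fit$slope == 0) stop("slope is zero", call. = FALSE)
  (fit$s_yx / fit$slope) *
    sqrt(1 / p + 1 / fit$n + (y0 - fit$y_bar)^2 / (fit$slope^2 * fit$sxx))
}

#' Combine the five contributors into a standard uncertainty
#'
#' First-order (GUM law of propagation) combination of the five relative
#' terms:
#' `u_x0 = x0 * sqrt((u_PR/x0)^2 + u_SS_rel^2 + (u_RL/x0)^2 +
#'   (u_MM/cMM)^2 + (u_CF/cCF)^2)`.
#' Homogeneous of degree 1 in `x0` at fixed relative terms, and monotone
#' in every contributor.
#'
#' @param x0 determined value (> 0; combining below LOQ is refused
#'   upstream).
#' @param u_pr precision contribution, same units as `x0`.
#' @param u_ss_rel relative stock contribution (see [u_stock()]).
#' @param u_rl regression contribution, same units as `x0`.
#' @param entry an `aq_entry` supplying `cmm`, `u_mm`, `ccf`, `u_cf`.
#' @return a list with `u_x0` and `rel` (named vector of the five
#'   relative contributions PR, SS, RL, MM, CF).
#' @export
combine_uncertainty <- function(x0, u_pr, u_ss_rel, u_rl, entry) {
  stopifnot(inherits(entry, "aq_entry"))
  assert_scalar_number(x0, "x0", lower = 0, strict_lower = TRUE)
  for (nm in c("u_pr", "u_ss_rel", "u_rl")) {
    assert_scalar_number(get(nm), nm, lower = 0)
  }
  rel <- c(PR = u_pr / x0, SS = u_ss_rel, RL = u_rl / x0,
           MM = entry$u_mm / entry$cmm, CF = entry$u_cf / entry$ccf)
  list(u_x0 = x0 * sqrt(sum(rel^2)), rel = rel)
}

#' Expand a combined standard uncertainty
#'
#' @param u_x0 combined standard uncertainty.
#' @param k coverage factor; the default `k = 2` corresponds to an
#'   approximate 95% confidence level under normality.
#' @return `k * u_x0`.
#' @export
expand_uncertainty <- function(u_x0, k = 2) {
  assert_scalar_number(u_x0, "u_x0", lower = 0)
  assert_scalar_number(k, "k", lower = 0, strict_lower = TRUE)
  k * u_x0
}

#' Assemble a five-contributor uncertainty budget
#'
#' Bundles the contributors, their combination and the expanded
#' uncertainty for one determined content. All contributors are carried
#' on the peptide-concentration scale (fmol/uL), on which the five terms
#' are dimensionless after division; the reporting-unit conversion is
#' linear, so value and uncertainty convert identically.
#'
#' @inheritParams combine_uncertainty
#' @param k coverage factor (default 2).
#' @return an object of class `aq_budget` with the contributors, `u_x0`,
#'   `U_x0`, `k` and the `rel` vector of relative contributions.
#' @export
uncertainty_budget <- function(x0, u_pr, u_ss_rel, u_rl, entry, k = 2) {
  comb <- combine_uncertainty(x0, u_pr, u_ss_rel, u_rl, entry)
  structure(list(x0 = x0, u_pr = u_pr, u_ss_rel = u_ss_rel, u_rl = u_rl,
                 u_mm = entry$u_mm, u_cf = entry$u_cf, cmm = entry$cmm,
                 ccf = entry$ccf, u_x0 = comb$u_x0,
                 U_x0 = expand_uncertainty(comb$u_x0, k), k = k,
                 rel = comb$rel), class = "aq_budget")
}

#' @export
print.aq_budget <- function(x, ...) {
  cat(sprintf("<uncertainty budget> x0 = %.4g, u = %.3g, U = %.3g (k = %g)\n",
              x$x0, x$u_x0, x$U_x0, x$k))
  cat("  relative contributions:",
      paste(sprintf("%s %.1f%%", names(x$rel), 100 * x$rel),
            collapse = ", "), "\n")
  invisible(x)
}
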
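#' Fit a calibration curve by ordinary least squares
#'
#' Regresses the L/H ratio on the calibrant concentration with unweighted
#' OLS. Replicate ratios enter as individual observations (this preserves
#' degrees of freedom for the intercept SD). Flagged ratios (`NA`) are
#' dropped. The blank (0 fmol/uL) is a regular calibration point when its
#' ratio is measurable. `range_limit` restricts the fit to the low
#' concentration range used for detection-limit estimation; points above
#' the limit are never used.
#'
#' @param ratios tibble with columns `nominal_level` and `ratio` (a
#'   `peptide` column, if present, must hold a single marker code).
#' @param range_limit optional maximum concentration (fmol/uL) retained.
#' @return an object of class `aq_fit` with components `slope`,
#'   `intercept`, `sd_slope`, `sd_intercept`, `s_yx` (residual SD), `n`,
#'   `reps_per_point`, `r_squared`, `x_bar`, `y_bar`, `sxx`, `range`,
#'   `peptide`.
#' @export
#' @examples
#' fit_curve(tibble::tibble(nominal_level = c(0, 1, 2), ratio = c(0, 1, 2)))
fit_curve <- function(ratios, range_limit = NULL) {
  assert_columns(ratios, c("nominal_level", "ratio"), "ratios")
  peptide <- NA_character_
  if ("peptide" %in% names(ratios)) {
    pep <- unique(ratios$peptide)
    if (length(pep) > 1L) {
      stop("`ratios` mixes several peptides (", paste(pep, collapse = ", "),
           "); fit one curve per marker or use fit_all_curves()",
           call. = FALSE)
    }
    peptide <- pep
  }
  ratios <- ratios[!is.na(ratios$ratio), ]
  if (!is.null(range_limit)) {
    ratios <- ratios[ratios$nominal_level <= range_limit, ]
  }
  x <- ratios$nominal_level
  y <- ratios$ratio
  if (length(unique(x)) < 3L) {
    stop("need at least 3 distinct calibration levels (got ",
         length(unique(x)), ")", call. = FALSE)
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    sd_slope = unname(sm$coefficients[2, 2]),
    sd_intercept = unname(sm$coefficients[1, 2]),
    s_yx = sm$sigma,
    n = n,
    reps_per_point = n / length(unique(x)),
    r_squared = sm$r.squared,
    x_bar = mean(x), y_bar = mean(y), sxx = sxx,
    range = range(x), peptide = peptide), class = "aq_fit")
}

#' @export
print.aq_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration fit%s> b = %.5g (SD %.2g), a = %.5g (SDa %.2g), S_y/x = %.3g, n = %d, R^2 = %.3f\n",
    if (!is.na(x$peptide)) paste0(": ", x$peptide) else "",
    x$slope, x$sd_slope, x$intercept, x$sd_intercept, x$s_yx, x$n,
    x$r_squared))
  invisible(x)
}

#' Fit one curve per marker
#'
#' @param ratios ratio tibble with a `peptide` column (from
#'   [compute_lh_ratios()]).
#' @param range_limit optional per-call maximum level, as in [fit_curve()].
#' @return a named list of `aq_fit` objects.
#' @export
fit_all_curves <- function(ratios, range_limit = NULL) {
  assert_columns(ratios, c("peptide", "nominal_level", "ratio"), "ratios")
  peps <- unique(ratios$peptide)
  stats::setNames(
    lapply(peps, function(p)
      fit_curve(ratios[ratios$peptide == p, ], range_limit = range_limit)),
    peps)
}

#' Test for a matrix effect by comparing two calibration slopes
#'
#' First screens the regression variances (squared residual SDs) of the
#' matrix-matched and standard curves with a one-tailed Fisher-Snedecor
#' F-test (largest over lowest variance, default alpha 0.01). If the
#' variances are not significantly different they are pooled, weighted by
#' their degrees of freedom, and the slopes are compared with a
#' two-tailed Student t-test (default alpha 0.05) on n1 + n2 - 4 degrees
#' of freedom. When the variances are *not* poolable the t branch is
#' reported as not applicable — no Welch-style fallback is silently
#' applied.
#'
#' @param mmcc,scc `aq_fit` objects for the matrix-matched and standard
#'   curves.
#' @param alpha_f significance level of the one-tailed variance screen.
#' @param alpha_t significance level of the two-tailed slope test.
#' @return an object of class `aq_slope_test` with `f_statistic`,
#'   `f_critical`, `variances_poolable`, `t_statistic`, `t_critical`,
#'   `df`, `slopes_differ` (NA when not poolable).
#' @export
compare_matrix_effect <- function(mmcc, scc, alpha_f = 0.01,
                                  alpha_t = 0.05) {
  stopifnot(inherits(mmcc, "aq_fit"), inherits(scc, "aq_fit"))
  v1 <- mmcc$s_yx^2
  v2 <- scc$s_yx^2
  df1 <- mmcc$n - 2L
  df2 <- scc$n - 2L
  if (v1 >= v2) {
    f <- v1 / v2; fdf <- c(df1, df2)
  } else {
    f <- v2 / v1; fdf <- c(df2, df1)
  }
  f_crit <- qf(1 - alpha_f, fdf[1], fdf[2])
  poolable <- f <= f_crit
  if (poolable) {
    s2p <- (df1 * v1 + df2 * v2) / (df1 + df2)
    se <- sqrt(s2p * (1 / mmcc$sxx + 1 / scc$sxx))
    t_stat <- abs(mmcc$slope - scc$slope) / se
    df <- mmcc$n + scc$n - 4L
    t_crit <- qt(1 - alpha_t / 2, df)
    differ <- t_stat > t_crit
  } else {
    t_stat <- NA_real_; t_crit <- NA_real_; df <- NA_integer_
    differ <- NA
  }
  structure(list(f_statistic = f, f_critical = f_crit,
                 variances_poolable = poolable, t_statistic = t_stat,
                 t_critical = t_crit, df = df, slopes_differ = differ,
                 alpha_f = alpha_f, alpha_t = alpha_t),
            class = "aq_slope_test")
}

#' @export
print.aq_slope_test <- function(x, ...) {
  cat(sprintf("<slope comparison> F = %.3g (crit %.3g, poolable: %s)",
              x$f_statistic, x$f_critical, x$variances_poolable))
  if (isTRUE(x$variances_poolable)) {
    cat(sprintf("; t = %.3g (crit %.3g, df %d) -> slopes %s\n",
                x$t_statistic, x$t_critical, x$df,
                if (x$slopes_differ) "DIFFER" else "do not differ"))
  } else {
    cat("; slope t-test not applicable (variances not poolable)\n")
  }
  invisible(x)
}

#' Detection and quantification limits from a calibration fit
#'
#' LOD = 3 SD / b and LOQ = 10 SD / b, where b is the calibration slope
#' and SD is one of three estimators: the standard deviation of the
#' intercept (`"intercept_sd"`, the default and the most rigorous
#' calibration-based choice), the residual SD of the regression
#' (`"residual_sd"`, typically an overestimate), or the signal SD over
#' replicates of the lowest detected point (`"ldp_sd"`, requiring at
#' least 5 replicate ratios). LOQ/LOD is 10/3 exactly for a given SD.
#'
#' @param fit an `aq_fit`, usually restricted to the low concentration
#'   range via `range_limit` in [fit_curve()].
#' @param method SD estimator, see above.
#' @param ldp_ratios replicate L/H ratios at the lowest detected point
#'   (required for `method = "ldp_sd"`).
#' @param entry optional `aq_entry`; when supplied, limits are also
#'   converted to ug TAFP/g via [to_tafp()].
#' @param m,d conversion constants passed to [to_tafp()].
#' @return an object of class `aq_limits` with `method`, `lod`, `loq`
#'   (fmol/uL) and `lod_tafp`, `loq_tafp` (ug TAFP/g, NA without `entry`).
#' @export
limits <- function(fit, method = c("intercept_sd", "residual_sd", "ldp_sd"),
                   ldp_ratios = NULL, entry = NULL, m = 1e-5, d = 1.33) {
  stopifnot(inherits(fit, "aq_fit"))
  method <- match.arg(method)
  if (fit$slope <= 0) {
    stop("calibration slope must be positive to define limits (b = ",
         format(fit$slope), ")", call. = FALSE)
  }
  sd_est <- switch(method,
    intercept_sd = fit$sd_intercept,
    residual_sd = fit$s_yx,
    ldp_sd = {
      if (is.null(ldp_ratios) || length(ldp_ratios) < 5L) {
        stop("method \"ldp_sd\" needs >= 5 replicate ratios at the lowest ",
             "detected point", call. = FALSE)
      }
      sd(ldp_ratios)
    })
  lod <- 3 * sd_est / fit$slope
  loq <- 10 * sd_est / fit$slope
  structure(list(method = method, lod = lod, loq = loq,
                 lod_tafp = if (!is.null(entry)) to_tafp(lod, entry, m, d)
                            else NA_real_,
                 loq_tafp = if (!is.null(entry)) to_tafp(loq, entry, m, d)
                            else NA_real_,
                 peptide = fit$peptide), class = "aq_limits")
}

#' @export
print.aq_limits <- function(x, ...) {
  cat(sprintf("<limits%s, %s> LOD = %.3g, LOQ = %.3g fmol/uL",
              if (!is.na(x$peptide)) paste0(": ", x$peptide) else "",
              x$method, x$lod, x$loq))
  if (!is.na(x$lod_tafp)) {
    cat(sprintf(" (%.3g / %.3g ug TAFP/g)", x$lod_tafp, x$loq_tafp))
  }
  cat("\n")
  invisible(x)
}

#' Precision at the lowest detected point
#'
#' Relative standard deviation (percent) of replicate L/H ratios at the
#' lowest calibration level with measurable signal.
#'
#' @param ldp_ratios numeric vector of replicate ratios (>= 2 values).
#' @return CV as a percentage.
#' @export
precision_at_ldp <- function(ldp_ratios) {
  ldp_ratios <- ldp_ratios[!is.na(ldp_ratios)]
  if (length(ldp_ratios) < 2L) {
    stop("need at least 2 replicate ratios", call. = FALSE)
  }
  100 * sd(ldp_ratios) / mean(ldp_ratios)
}
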
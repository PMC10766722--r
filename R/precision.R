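#' One-way ANOVA poolability check
#'
#' Tests whether replicate determinations grouped by a factor (e.g.
#' biological sample, day or analyst) share a common mean, licensing the
#' pooling of all observations for quantification. Classical one-way
#' ANOVA with equal-variance assumption; poolable iff p >= alpha.
#'
#' @param values numeric determinations.
#' @param groups grouping factor (>= 2 groups, each with >= 2 values).
#' @param alpha significance level (default 0.05).
#' @return a list with `poolable`, `f_statistic`, `p_value`, `df`.
#' @export
poolability_anova <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  keep <- !is.na(values)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  counts <- table(groups)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  tst <- oneway.test(values ~ groups, var.equal = TRUE)
  list(poolable = tst$p.value >= alpha,
       f_statistic = unname(tst$statistic),
       p_value = tst$p.value,
       df = unname(tst$parameter))
}

#' @noRd
.balance <- function(data, factors, what) {
  counts <- dplyr::count(data, dplyr::across(dplyr::all_of(factors)))
  n_min <- min(counts$n)
  if (length(unique(counts$n)) > 1L) {
    warning("unbalanced ", what, " design; computing on the balanced ",
            "subset (", n_min, " per cell)", call. = FALSE)
    data <- data |>
      dplyr::group_by(dplyr::across(dplyr::all_of(factors))) |>
      dplyr::slice_head(n = n_min) |>
      dplyr::ungroup()
  }
  list(data = data, n = n_min)
}

#' Repeatability (intra-day precision) with variance components
#'
#' One-way random-effects decomposition of determinations from a single
#' day: biological (prepared) samples are the groups, instrumental
#' replicates the within-group observations. Method-of-moments
#' (expected-mean-squares) estimators: the instrumental-analysis variance
#' is the within mean square, the sample-preparation variance is
#' `max(0, (MS_between - MS_within) / t)`. The total CV% is computed on
#' the grand mean of the determined peptide content, and the relative
#' weight of each component is its share of the total variance.
#'
#' @param data tibble with columns `value` (determined peptide content,
#'   fmol/uL), `biological_rep`, `technical_rep`; one day, one analyst.
#' @param alpha significance level for the ANOVA poolability flag.
#' @return an object of class `aq_precision` with `total_cv`,
#'   `components` (tibble: factor, variance, weight), `anova_poolable`,
#'   `grand_mean`, `n_bio`, `n_tech`.
#' @export
repeatability <- function(data, alpha = 0.05) {
  assert_columns(data, c("value", "biological_rep", "technical_rep"), "data")
  data <- data[!is.na(data$value), ]
  bal <- .balance(data, "biological_rep", "repeatability")
  data <- bal$data
  t_reps <- bal$n
  b <- length(unique(data$biological_rep))
  if (b < 2L || t_reps < 2L) {
    stop("need >= 2 biological samples with >= 2 technical replicates",
         call. = FALSE)
  }
  grand <- mean(data$value)
  by_bio <- data |>
    dplyr::group_by(.data$biological_rep) |>
    dplyr::summarise(m = mean(.data$value),
                     ss = sum((.data$value - m)^2), .groups = "drop")
  ms_within <- sum(by_bio$ss) / (b * (t_reps - 1))
  ms_between <- t_reps * sum((by_bio$m - grand)^2) / (b - 1)
  var_ia <- ms_within
  var_sp <- max(0, (ms_between - ms_within) / t_reps)
  total_var <- var_ia + var_sp
  weights <- if (total_var > 0) c(IA = var_ia, SP = var_sp) / total_var * 100
             else c(IA = 0, SP = 0)
  pool <- poolability_anova(data$value, data$biological_rep, alpha)
  structure(list(
    total_cv = if (grand != 0) 100 * sqrt(total_var) / grand else 0,
    components = tibble::tibble(factor = c("IA", "SP"),
                                variance = c(var_ia, var_sp),
                                weight = unname(weights[c("IA", "SP")])),
    anova_poolable = pool$poolable, anova = pool,
    grand_mean = grand, n_bio = b, n_tech = t_reps),
    class = "aq_precision")
}

#' Intermediate precision with day/analyst variance components
#'
#' Decomposes determinations from a multi-day (optionally multi-analyst)
#' design into sample-preparation (SP), day (DA) and analyst (A)
#' components by the method of moments. Technical replicates, when
#' present, are first averaged to prepared-sample means, so the SP
#' component absorbs the (small) residual instrumental share — matching
#' the convention of reporting intermediate-precision weights over
#' SP/DA/A only. Layout: days crossed with analysts, samples nested in
#' the day x analyst cells; expected mean squares give
#' `sigma2_DA = (MS_day - MS_sample) / (a * s)` and
#' `sigma2_A = (MS_analyst - MS_sample) / (d * s)`, negative estimates
#' truncated to zero before weight normalisation. A factor absent from
#' the design (a single analyst) is reported as `"nt"` (not tested) and
#' the weights renormalise over the remaining factors.
#'
#' @param data tibble with columns `value`, `biological_rep`, `day` and
#'   optionally `analyst` and `technical_rep`.
#' @param alpha significance level for the poolability flag (one-way
#'   ANOVA across day x analyst cells).
#' @return an `aq_precision` whose `components` cover SP, DA and A
#'   (variance `NA` and weight `NA` for untested factors).
#' @export
intermediate_precision <- function(data, alpha = 0.05) {
  assert_columns(data, c("value", "biological_rep", "day"), "data")
  data <- data[!is.na(data$value), ]
  if (!"analyst" %in% names(data)) data$analyst <- "a1"
  if ("technical_rep" %in% names(data)) {
    data <- data |>
      dplyr::group_by(.data$day, .data$analyst, .data$biological_rep) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  bal <- .balance(data, c("day", "analyst"), "intermediate-precision")
  data <- bal$data
  s <- bal$n
  d <- length(unique(data$day))
  a <- length(unique(data$analyst))
  if (d < 2L) stop("need >= 2 days", call. = FALSE)
  if (s < 2L) stop("need >= 2 samples per day x analyst cell", call. = FALSE)
  grand <- mean(data$value)

  cells <- data |>
    dplyr::group_by(.data$day, .data$analyst) |>
    dplyr::summarise(m = mean(.data$value),
                     ss = sum((.data$value - m)^2), .groups = "drop")
  ms_sample <- sum(cells$ss) / (d * a * (s - 1))
  day_means <- data |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop")
  ms_day <- a * s * sum((day_means$m - grand)^2) / (d - 1)

  var_sp <- ms_sample
  var_da <- max(0, (ms_day - ms_sample) / (a * s))
  if (a >= 2L) {
    an_means <- data |>
      dplyr::group_by(.data$analyst) |>
      dplyr::summarise(m = mean(.data$value), .groups = "drop")
    ms_an <- d * s * sum((an_means$m - grand)^2) / (a - 1)
    var_a <- max(0, (ms_an - ms_sample) / (d * s))
  } else {
    var_a <- NA_real_
  }
  vars <- c(SP = var_sp, DA = var_da, A = var_a)
  total_var <- sum(vars, na.rm = TRUE)
  weights <- ifelse(is.na(vars), NA_real_,
                    if (total_var > 0) vars / total_var * 100 else 0)
  cell_id <- interaction(data$day, data$analyst, drop = TRUE)
  pool <- poolability_anova(data$value, cell_id, alpha)
  structure(list(
    total_cv = if (grand != 0) 100 * sqrt(total_var) / grand else 0,
    components = tibble::tibble(factor = names(vars),
                                variance = unname(vars),
                                weight = unname(weights)),
    anova_poolable = pool$poolable, anova = pool,
    grand_mean = grand, n_bio = s, n_days = d, n_analysts = a),
    class = "aq_precision")
}

#' @export
print.aq_precision <- function(x, ...) {
  cat(sprintf("<precision> total CV = %.1f%%, poolable: %s\n", x$total_cv,
              x$anova_poolable))
  comp <- x$components
  lab <- ifelse(is.na(comp$weight), "nt",
                sprintf("%.0f%%", comp$weight))
  cat(" ", paste(comp$factor, lab, collapse = ", "), "\n")
  invisible(x)
}

#' Sample stability over storage days
#'
#' Compares the determinations of one prepared sample measured on the
#' reference (first) day against each later day with two-sample t-tests
#' at significance level `alpha`. The sample is declared stable iff no
#' comparison is significant.
#'
#' @param data tibble with columns `value` and `day` (>= 2 days, >= 2
#'   replicates per day).
#' @param alpha significance level (default 0.05).
#' @param reference reference day label; defaults to the first in sorted
#'   order.
#' @return a list with `stable` and a `comparisons` tibble (day,
#'   t_statistic, p_value, significant).
#' @export
stability_test <- function(data, alpha = 0.05, reference = NULL) {
  assert_columns(data, c("value", "day"), "data")
  data <- data[!is.na(data$value), ]
  days <- sort(unique(data$day))
  if (length(days) < 2L) stop("need >= 2 days", call. = FALSE)
  counts <- table(data$day)
  if (any(counts < 2L)) {
    stop("each day needs >= 2 replicates (day(s) ",
         paste(names(counts)[counts < 2L], collapse = ", "), ")",
         call. = FALSE)
  }
  reference <- reference %||% days[1]
  ref_vals <- data$value[data$day == reference]
  comparisons <- dplyr::bind_rows(lapply(setdiff(days, reference), function(dd) {
    other <- data$value[data$day == dd]
    if (sd(ref_vals) == 0 && sd(other) == 0) {
      # degenerate constant data: identical means are trivially stable,
      # different means trivially unstable
      differ <- mean(ref_vals) != mean(other)
      return(tibble::tibble(day = dd,
                            t_statistic = if (differ) Inf else 0,
                            p_value = as.numeric(!differ),
                            significant = differ))
    }
    tt <- t.test(ref_vals, other, var.equal = TRUE)
    tibble::tibble(day = dd, t_statistic = unname(tt$statistic),
                   p_value = tt$p.value, significant = tt$p.value < alpha)
  }))
  list(stable = !any(comparisons$significant), comparisons = comparisons,
       reference = reference)
}

#' Spike recovery from spiked-before / spiked-after samples
#'
#' The percent ratio of the content determined in the sample spiked
#' before extraction/purification (SB) to that spiked after (SA)
#' estimates the method recovery for the allergen's quantitative marker.
#'
#' @param sb,sa `aq_quant` results for the SB and SA samples; both must
#'   be quantifiable.
#' @return an object of class `aq_recovery` with `allergen`, `qtm`,
#'   `recovery_percent`, `sb_value`, `sa_value`.
#' @export
recovery <- function(sb, sa) {
  stopifnot(inherits(sb, "aq_quant"), inherits(sa, "aq_quant"))
  if (!isTRUE(sb$quantifiable) || !isTRUE(sa$quantifiable)) {
    stop("both SB and SA must be quantifiable (>= LOQ)", call. = FALSE)
  }
  if (sb$allergen != sa$allergen) {
    stop("SB and SA quantify different allergens", call. = FALSE)
  }
  structure(list(allergen = sb$allergen, qtm = sb$qtm,
                 recovery_percent = 100 * sb$x0_tafp / sa$x0_tafp,
                 sb_value = sb$x0_tafp, sa_value = sa$x0_tafp),
            class = "aq_recovery")
}

#' @export
print.aq_recovery <- function(x, ...) {
  cat(sprintf("<recovery: %s (%s)> %.0f%% (SB %.3g / SA %.3g ug TAFP/g)\n",
              x$allergen, x$qtm, x$recovery_percent, x$sb_value, x$sa_value))
  invisible(x)
}
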
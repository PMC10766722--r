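test_that("fit_curve matches closed-form OLS on tiny instances", {
  # exact line
  f <- suppressWarnings(
    fit_curve(tibble::tibble(nominal_level = 0:2, ratio = 0:2)))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$s_yx, 0)
  expect_equal(f$r_squared, 1)
  # hand-computed 3-point fit: (0,0),(1,1),(2,1)
  g <- fit_curve(tibble::tibble(nominal_level = c(0, 1, 2),
                                ratio = c(0, 1, 1)))
  expect_equal(g$slope, 0.5)
  expect_equal(g$intercept, 1 / 6)
  expect_equal(g$s_yx, sqrt(sum(c(-1 / 6, 1 / 3, -1 / 6)^2)), tolerance = 1e-12)
  expect_equal(g$sxx, 2)
  # degenerate inputs
  expect_error(fit_curve(tibble::tibble(nominal_level = c(1, 1, 1),
                                        ratio = c(1, 2, 3))), "3 distinct")
  expect_error(fit_curve(tibble::tibble(nominal_level = c(1, 2),
                                        ratio = c(1, 2))), "3 distinct")
})

test_that("fit_curve agrees with a normal-equations oracle on random data", {
  set.seed(101)
  for (i in 1:25) {
    n_lev <- sample(4:8, 1)
    x <- rep(sort(runif(n_lev, 0, 50)), each = sample(1:3, 1))
    y <- 0.01 + 0.03 * x + rnorm(length(x), 0, 0.02)
    f <- fit_curve(tibble::tibble(nominal_level = x, ratio = y))
    o <- ols_oracle(x, y)
    for (fld in c("slope", "intercept", "sd_slope", "sd_intercept",
                  "s_yx", "r_squared")) {
      expect_equal(f[[fld]], o[[fld]], tolerance = 1e-10)
    }
  }
})

test_that("range restriction never uses points above the limit", {
  set.seed(7)
  x <- rep(c(0, 0.5, 1, 1.5, 2, 3, 5, 10, 25, 50), each = 3)
  y <- 0.002 + 0.0212 * x + rnorm(length(x), 0, 0.003)
  full <- fit_curve(tibble::tibble(nominal_level = x, ratio = y))
  low <- fit_curve(tibble::tibble(nominal_level = x, ratio = y),
                   range_limit = 5)
  expect_equal(low$n, sum(x <= 5))
  expect_equal(low$range[2], 5)
  manual <- fit_curve(tibble::tibble(nominal_level = x[x <= 5],
                                     ratio = y[x <= 5]))
  expect_equal(low$slope, manual$slope)
  expect_false(isTRUE(all.equal(low$slope, full$slope)))
})

test_that("matrix-effect comparison behaves at its boundaries", {
  set.seed(3)
  x <- rep(c(0, 1, 2, 5, 10, 25, 50), each = 3)
  y <- 0.01 + 0.02 * x + rnorm(length(x), 0, 0.01)
  f <- fit_curve(tibble::tibble(nominal_level = x, ratio = y))
  same <- compare_matrix_effect(f, f)
  expect_equal(same$f_statistic, 1)
  expect_true(same$variances_poolable)
  expect_equal(same$t_statistic, 0)
  expect_false(same$slopes_differ)
  expect_equal(same$df, 2L * length(x) - 4L)
})

test_that("a 0.7 matrix attenuation is flagged as a slope difference", {
  panel <- mini_panel()
  d <- calibration_design(true_slope = c("mc-FFV" = 0.0212, "mc-NAV" = 0.024),
                          rel_sd = 0.02, abs_sd = 2e-4,
                          matrix_attenuation = 0.7)
  mm <- fit_curve(compute_lh_ratios(
    simulate_calibration(d, panel, seed = 5, curve_type = "matrix",
                         peptides = "mc-FFV")))
  sc <- fit_curve(compute_lh_ratios(
    simulate_calibration(d, panel, seed = 5, curve_type = "standard",
                         peptides = "mc-FFV")))
  cmp <- compare_matrix_effect(mm, sc)
  expect_true(cmp$variances_poolable)
  expect_true(cmp$slopes_differ)
  expect_lt(mm$slope, sc$slope)
})

test_that("limits implement 3x and 10x the chosen SD over the slope", {
  set.seed(9)
  x <- rep(c(0, 0.5, 1, 1.5, 2, 3, 5), each = 3)
  y <- 0.002 + 0.0212 * x + rnorm(length(x), 0, 0.001)
  f <- fit_curve(tibble::tibble(nominal_level = x, ratio = y))
  o <- ols_oracle(x, y)
  li <- limits(f, "intercept_sd")
  expect_equal(li$lod, 3 * o$sd_intercept / o$slope, tolerance = 1e-10)
  lr <- limits(f, "residual_sd")
  expect_equal(lr$lod, 3 * o$s_yx / o$slope, tolerance = 1e-10)
  ldp <- y[x == 0.5]
  ll <- limits(f, "ldp_sd", ldp_ratios = c(ldp, ldp))  # >= 5 values
  expect_equal(ll$lod, 3 * sd(c(ldp, ldp)) / f$slope, tolerance = 1e-12)
  # LOQ/LOD is 10/3 exactly for every estimator
  for (l in list(li, lr, ll)) expect_equal(l$loq / l$lod, 10 / 3)
  # residual-based limits dominate intercept-based ones here
  expect_gt(lr$lod, li$lod)
  expect_error(limits(f, "ldp_sd", ldp_ratios = c(1, 2)), ">= 5")
})

test_that("limits are monotone in SD and antitone in slope", {
  mk_fit <- function(slope, sda) {
    f <- suppressWarnings(fit_curve(tibble::tibble(
      nominal_level = c(0, 1, 2, 3), ratio = slope * c(0, 1, 2, 3))))
    f$sd_intercept <- sda
    f
  }
  expect_gt(limits(mk_fit(0.02, 0.002))$lod, limits(mk_fit(0.02, 0.001))$lod)
  expect_lt(limits(mk_fit(0.04, 0.002))$lod, limits(mk_fit(0.02, 0.002))$lod)
  expect_equal(limits(mk_fit(0.02, 0))$lod, 0)
  f_neg <- mk_fit(0.02, 0.001)
  f_neg$slope <- -0.01
  expect_error(limits(f_neg), "positive")
})

test_that("unit conversion attaches TAFP-scale limits", {
  f <- suppressWarnings(fit_curve(tibble::tibble(
    nominal_level = c(0, 1, 2, 3), ratio = 0.02 * c(0, 1, 2, 3))))
  f$sd_intercept <- 0.02 * 0.11 / 3  # yields LOD 0.11 fmol/uL
  e <- mini_entry()
  l <- limits(f, entry = e)
  expect_equal(l$lod, 0.11, tolerance = 1e-12)
  expect_equal(l$lod_tafp, to_tafp(0.11, e), tolerance = 1e-12)
})

test_that("precision at the lowest detected point is SD over mean", {
  expect_equal(precision_at_ldp(c(2, 2, 2)), 0)
  expect_equal(precision_at_ldp(c(1.0, 1.1)),
               100 * sd(c(1.0, 1.1)) / 1.05, tolerance = 1e-12)
  expect_equal(round(precision_at_ldp(c(1.0, 1.1)), 2), 6.73)
  set.seed(21)
  r <- rnorm(5000, 1, 0.12)
  expect_equal(precision_at_ldp(r), 12, tolerance = 0.05)
  expect_error(precision_at_ldp(1), "at least 2")
})
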
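test_that("simulators are deterministic under a fixed seed", {
  panel <- mini_panel()
  d <- calibration_design()
  expect_identical(simulate_calibration(d, panel, seed = 11),
                   simulate_calibration(d, panel, seed = 11))
  id <- incurred_design()
  expect_identical(simulate_incurred(id, panel, seed = 11),
                   simulate_incurred(id, panel, seed = 11))
  dd <- default_discovery_design()
  expect_identical(simulate_discovery(dd, seed = 11),
                   simulate_discovery(dd, seed = 11))
  # distinct labels give independent substreams
  expect_false(identical(simulate_calibration(d, panel, seed = 11),
                         simulate_calibration(d, panel, seed = 12)))
  expect_true(substream_seed(1, "calibration") !=
                substream_seed(1, "incurred"))
})

test_that("noiseless calibration reproduces the generating line exactly", {
  d <- noiseless_cal_design(true_slope = c("mc-FFV" = 0.04, "mc-NAV" = 0.04))
  tbl <- simulate_calibration(d, mini_panel(), seed = 1)
  r <- compute_lh_ratios(tbl)
  expect_equal(r$ratio[r$nominal_level == 10], rep(0.4, 6),
               tolerance = 1e-12)
  f <- suppressWarnings(fit_curve(dplyr::filter(r, peptide == "mc-FFV")))
  expect_equal(f$slope, 0.04, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
})

test_that("fitted slopes track the generating slope within OLS sampling theory", {
  # 200 seeds; the standardized deviation of the mean fitted slope from
  # truth should behave like a z-score
  panel <- mini_panel()
  d <- calibration_design(true_slope = c("mc-FFV" = 0.0212, "mc-NAV" = 0.024))
  slopes <- vapply(1:200, function(i) {
    tbl <- simulate_calibration(d, panel, seed = i, peptides = "mc-FFV")
    fit_curve(compute_lh_ratios(tbl))$slope
  }, 0)
  z <- (mean(slopes) - 0.0212) / (sd(slopes) / sqrt(length(slopes)))
  expect_lt(abs(z), 3)
})

test_that("noiseless incurred ratios invert the reporting-unit equation", {
  panel <- mini_panel()
  e <- panel$entries[[1]]
  d <- noiseless_inc_design(levels = 40,
                            true_slope = c("mc-FFV" = 0.0212,
                                           "mc-NAV" = 0.024))
  tbl <- simulate_incurred(d, panel, seed = 1)
  r <- compute_lh_ratios(tbl)
  # expected concentration from inverting the conversion equation
  x_expected <- 40 / (e$cmm / e$ccf * 1e-5 * 1.33)
  expect_equal(x_expected, from_tafp(40, e), tolerance = 1e-12)
  expect_equal(unique(r$ratio[r$peptide == "mc-FFV"]),
               0.0212 * x_expected, tolerance = 1e-12)
})

test_that("variance components injected by the generator are recoverable", {
  # method-of-moments estimates averaged over seeds are unbiased for the
  # generating components (3x3 repeatability layout)
  panel <- mini_panel()
  e <- panel$entries[[1]]
  b <- 0.0212
  x40 <- from_tafp(40, e)
  sigma_sp <- 0.05
  sigma_ia <- 0.002
  d <- incurred_design(levels = 40, sigma_sp = sigma_sp,
                       sigma_ia = sigma_ia, sigma_da = 0, sigma_a = 0,
                       true_slope = c("mc-FFV" = b, "mc-NAV" = 0.024))
  fit0 <- suppressWarnings(fit_curve(tibble::tibble(
    nominal_level = c(0, 25, 50),
    ratio = d$true_intercept + b * c(0, 25, 50))))
  V <- vapply(1:200, function(i) {
    tbl <- simulate_incurred(d, panel, seed = i)
    r <- dplyr::filter(compute_lh_ratios(tbl), peptide == "mc-FFV")
    r$value <- as.numeric(interpolate(fit0, r$ratio))
    rep <- repeatability(r)
    stats::setNames(rep$components$variance, rep$components$factor)
  }, c(IA = 0, SP = 0))
  true_sp <- (x40 * sigma_sp)^2        # multiplicative effect on content
  true_ia <- (sigma_ia / b)^2          # additive ratio noise through slope
  expect_equal(mean(V["SP", ]), true_sp, tolerance = 0.15)
  expect_equal(mean(V["IA", ]), true_ia, tolerance = 0.15)
})

test_that("discovery tables respect the abundance contract", {
  bad <- tibble::tibble(accession = c("A", "B"), molar_mass = c(1e4, 2e4),
                        rel_abundance = c(0.6, 0.2),
                        carries_marker = c(TRUE, FALSE))
  expect_error(discovery_design(bad), "sum to 1")

  two <- discovery_design(
    tibble::tibble(accession = c("A", "B"), molar_mass = c(1e4, 2e4),
                   rel_abundance = c(0.75, 0.25),
                   carries_marker = c(TRUE, FALSE)),
    replicates = 3, intensity_cv = 0)
  tbl <- simulate_discovery(two, seed = 1)
  cf <- estimate_cf(tbl, "A")
  expect_equal(cf$centered$center, 0.75, tolerance = 1e-12)

  one <- discovery_design(
    tibble::tibble(accession = "A", molar_mass = 1e4, rel_abundance = 1,
                   carries_marker = TRUE),
    replicates = 3, intensity_cv = 0.5)
  expect_equal(estimate_cf(simulate_discovery(one, seed = 2),
                           "A")$centered$center, 1)
})

test_that("recovery pairs close the loop on the generating recovery", {
  panel <- mini_panel()
  d <- noiseless_inc_design(levels = 40,
                            true_slope = c("mc-FFV" = 0.0212,
                                           "mc-NAV" = 0.024))
  pair <- simulate_recovery_pair(1.0, level = 40, panel = panel,
                                 design = d, seed = 1)
  rb <- compute_lh_ratios(pair$sb)
  ra <- compute_lh_ratios(pair$sa)
  expect_equal(mean(rb$ratio) / mean(ra$ratio), 1, tolerance = 1e-12)

  pair53 <- simulate_recovery_pair(0.53, level = 40, panel = panel,
                                   design = d, seed = 1)
  r53 <- compute_lh_ratios(pair53$sb)
  expect_equal(mean(r53$ratio) / mean(ra$ratio), 0.53, tolerance = 1e-12)

  pair0 <- simulate_recovery_pair(0, level = 40, panel = panel,
                                  design = d, seed = 1)
  r0 <- compute_lh_ratios(pair0$sb)
  expect_true(all(r0$ratio == 0))  # blank-level SB (zero intercept design)
})
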
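test_that("poolability ANOVA flags shifted groups and rejects tiny designs", {
  set.seed(61)
  same <- rnorm(9, 10, 0.5)
  g <- rep(c("b1", "b2", "b3"), each = 3)
  expect_true(poolability_anova(same, g)$poolable)
  shifted <- same + ifelse(g == "b3", 5, 0)  # 10 within-SDs
  expect_false(poolability_anova(shifted, g)$poolable)
  expect_error(poolability_anova(c(1, 2), c("a", "b")), ">= 2 groups")
})

test_that("repeatability decomposes IA and SP by expected mean squares", {
  d <- tidyr::expand_grid(biological_rep = c("b1", "b2", "b3"),
                          technical_rep = c("t1", "t2", "t3"))
  # all equal -> zero CV
  expect_equal(repeatability(dplyr::mutate(d, value = 5))$total_cv, 0)
  # hand-checkable: between-sample shifts only
  d2 <- dplyr::mutate(d, value = c(9, 9, 9, 10, 10, 10, 11, 11, 11))
  r2 <- repeatability(d2)
  expect_equal(r2$components$variance[r2$components$factor == "IA"], 0)
  expect_equal(r2$components$weight[r2$components$factor == "SP"], 100)
  # within-only noise: SP weight collapses in expectation
  set.seed(62)
  w <- replicate(200, {
    rr <- repeatability(dplyr::mutate(d, value = rnorm(9, 10, 0.2)))
    rr$components$weight[rr$components$factor == "SP"]
  })
  expect_lt(mean(w), 25)
  # sigma_SP^2 = 3 sigma_IA^2 -> weights 75/25 from averaged components
  V <- replicate(500, {
    sp <- rnorm(3, 0, sqrt(3)); ia <- rnorm(9, 0, 1)
    rr <- repeatability(dplyr::mutate(d, value = 10 + rep(sp, each = 3) + ia))
    stats::setNames(rr$components$variance, rr$components$factor)
  })
  wsp <- 100 * mean(V["SP", ]) / (mean(V["SP", ]) + mean(V["IA", ]))
  expect_equal(wsp, 75, tolerance = 0.07)
  expect_error(repeatability(d2[1:3, ]), ">= 2 biological")
})

test_that("variance weights are invariant under rescaling", {
  set.seed(63)
  d <- tidyr::expand_grid(biological_rep = c("b1", "b2", "b3"),
                          technical_rep = c("t1", "t2", "t3")) |>
    dplyr::mutate(value = rnorm(9, 10, 1))
  w1 <- repeatability(d)$components$weight
  w2 <- repeatability(dplyr::mutate(d, value = value * 37))$components$weight
  expect_equal(w1, w2, tolerance = 1e-9)
})

test_that("intermediate precision handles day/analyst layouts", {
  grid <- tidyr::expand_grid(day = c("d1", "d2"),
                             biological_rep = c("b1", "b2", "b3"))
  # single analyst: A reported nt, SP/DA weights sum to 100
  set.seed(64)
  d1 <- dplyr::mutate(grid, value = rnorm(6, 10, 0.5))
  ip1 <- intermediate_precision(d1)
  comp <- ip1$components
  expect_true(is.na(comp$variance[comp$factor == "A"]))
  expect_equal(sum(comp$weight, na.rm = TRUE), 100, tolerance = 0.5)
  # day-dominated generator: DA weight approaches 100% as noise vanishes
  d2 <- dplyr::mutate(grid, value = 10 + ifelse(day == "d2", 4, 0) +
                        rnorm(6, 0, 1e-3))
  ip2 <- intermediate_precision(d2)
  expect_gt(ip2$components$weight[ip2$components$factor == "DA"], 99)
  # symmetric components: averaged estimates give ~1/3 each
  g3 <- tidyr::expand_grid(day = paste0("d", 1:3), analyst = c("a1", "a2"),
                           biological_rep = paste0("b", 1:3))
  set.seed(65)
  V <- replicate(300, {
    dd <- g3 |>
      dplyr::group_by(day) |> dplyr::mutate(de = rnorm(1)) |>
      dplyr::group_by(analyst) |> dplyr::mutate(ae = rnorm(1)) |>
      dplyr::ungroup() |>
      dplyr::mutate(value = 10 + de + ae + rnorm(dplyr::n()))
    ip <- intermediate_precision(dd)
    stats::setNames(ip$components$variance, ip$components$factor)
  })
  mv <- rowMeans(V)
  expect_equal(unname(100 * mv / sum(mv)), rep(100 / 3, 3), tolerance = 0.2)
  expect_error(intermediate_precision(dplyr::filter(d1, day == "d1")),
               ">= 2 days")
})

test_that("stability testing compares later days against the reference day", {
  d <- tidyr::expand_grid(day = c("d0", "d1", "d2"), rep = 1:3)
  expect_true(stability_test(dplyr::mutate(d, value = 5))$stable)
  set.seed(66)
  base <- rnorm(9, 10, 0.3)
  stable <- stability_test(dplyr::mutate(d, value = base))
  expect_true(stable$stable)
  expect_equal(nrow(stable$comparisons), 2)
  # day-2 shifted by 8 within-SDs
  shifted <- dplyr::mutate(d, value = base + ifelse(day == "d2", 2.4, 0))
  res <- stability_test(shifted)
  expect_false(res$stable)
  expect_true(res$comparisons$significant[res$comparisons$day == "d2"])
  expect_error(stability_test(tibble::tibble(day = c("d0", "d1"),
                                             value = c(1, 2))),
               ">= 2 replicates")
})

test_that("recovery is the SB/SA percent ratio of quantified contents", {
  panel <- mini_panel()
  e <- panel$entries[[1]]
  cal <- simulate_calibration(noiseless_cal_design(), panel, seed = 2)
  fits <- suppressWarnings(
    fit_all_curves(compute_lh_ratios(cal, transition = "all")))
  d <- noiseless_inc_design(levels = 40,
                            true_slope = c("mc-FFV" = 0.0212,
                                           "mc-NAV" = 0.024))
  pair <- simulate_recovery_pair(0.53, level = 40, panel = panel,
                                 design = d, seed = 1)
  qsb <- quantify(compute_lh_ratios(pair$sb, transition = "all") |>
                    dplyr::select(peptide, transition_index, ratio),
                  fits, e)
  qsa <- quantify(compute_lh_ratios(pair$sa, transition = "all") |>
                    dplyr::select(peptide, transition_index, ratio),
                  fits, e)
  rec <- recovery(qsb, qsa)
  expect_equal(rec$recovery_percent, 53, tolerance = 1e-9)
  expect_equal(recovery(qsa, qsa)$recovery_percent, 100, tolerance = 1e-12)
  # a non-quantifiable SA refuses a recovery estimate
  qbad <- qsa; qbad$quantifiable <- FALSE
  expect_error(recovery(qsb, qbad), "quantifiable")
})
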
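# Shared in-code fixtures: a two-marker single-allergen mini panel and
# noise-free designs used by the identity tests.

mini_marker <- function(code, role = "QTM", n_trans = 2) {
  peptide_marker(code, "FFVAPFPEVFGK", role, 8,
                 data.frame(precursor_mz = 692.9,
                            product_mz = seq(900, by = 10,
                                             length.out = n_trans)))
}

mini_entry <- function(allergen = "Milk caseinate", cmm = 23000,
                       ccf = 0.374, u_mm = 100, u_cf = 0.009) {
  allergen_entry(allergen, "P02662",
                 list(mini_marker("mc-FFV", "QTM"),
                      peptide_marker("mc-NAV", "NAVPITPTLNR", "QLM", 10,
                                     data.frame(precursor_mz = 598.3,
                                                product_mz = c(854.5, 757.4)))),
                 cmm = cmm, u_mm = u_mm, ccf = ccf, u_cf = u_cf)
}

mini_panel <- function(...) marker_panel(list(mini_entry(...)))

noiseless_cal_design <- function(true_slope = c("mc-FFV" = 0.0212,
                                                "mc-NAV" = 0.024), ...) {
  calibration_design(true_slope = true_slope, true_intercept = 0,
                     rel_sd = 0, abs_sd = 0, heavy_cv = 0, ...)
}

noiseless_inc_design <- function(...) {
  incurred_design(sigma_sp = 0, sigma_ia = 0, sigma_da = 0, sigma_a = 0,
                  true_intercept = 0, heavy_cv = 0, ...)
}

# Independent normal-equations OLS oracle (kept free of fit_curve's path)
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  n <- length(y)
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(diag(xtx_inv) * s2)
  list(intercept = unname(beta[1]), slope = unname(beta[2]),
       sd_intercept = unname(se[1]), sd_slope = unname(se[2]),
       s_yx = sqrt(s2),
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2))
}
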
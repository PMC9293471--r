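test_that("simulated points satisfy the coupled supply-demand system", {
  p <- noise_free_params()
  pt <- simulate_point(400, 1500, p, noise = FALSE)
  kin <- list(Km = p$Kc * (1 + 210 / p$Ko))
  # demand at the reported Cc equals the reported An
  Ac <- p$Vcmax * (pt$true_Cc - p$Gamma_star) / (pt$true_Cc + kin$Km)
  Aj_pot <- (0.45 * 1500 + p$Jmax -
               sqrt((0.45 * 1500 + p$Jmax)^2 -
                      4 * p$theta * 0.45 * 1500 * p$Jmax)) /
    (2 * p$theta)
  Aj <- Aj_pot * (pt$true_Cc - p$Gamma_star) /
    (4 * pt$true_Cc + 8 * p$Gamma_star)
  expect_equal(min(Ac, Aj) - p$Rd, pt$true_An, tolerance = 1e-8)
  # supply chain: Ci and Cc drawdowns
  expect_equal(pt$true_Ci, 400 - pt$true_An / (p$gsw / 1.6),
               tolerance = 1e-9)
  expect_equal(pt$true_Cc, pt$true_Ci - pt$true_An / p$gm,
               tolerance = 1e-9)
  # variable-J identity holds exactly for the emitted fluorescence J
  cc_back <- chloroplastic_cc(pt$true_An, p$Rd, pt$true_J,
                              p$Gamma_star)
  expect_equal(cc_back, pt$true_Cc, tolerance = 1e-8)
})

test_that("vanishing drawdowns in the high-conductance limit", {
  p <- noise_free_params(gm = 1e6, gsw = 1e6)
  pt <- simulate_point(400, 1500, p, noise = FALSE)
  expect_equal(pt$true_Ci, 400, tolerance = 1e-3)
  expect_equal(pt$true_Cc, 400, tolerance = 1e-3)
})

test_that("the cuticular construction makes the Ci correction an exact inverse", {
  p <- noise_free_params()
  pt <- simulate_point(400, 1500, p, noise = FALSE)
  out <- correct_ci(pt, Ec = p$Ec)
  expect_equal(out$Ci_corr, pt$true_Ci, tolerance = 1e-9)
  # while the uncorrected instrument Ci is biased
  expect_gt(abs(pt$Ci_raw - pt$true_Ci), 0.5)
})

test_that("low-O2 records produce an exactly linear yield relationship", {
  p <- noise_free_params()
  oc <- simulate_o2_calibration_curve(p, noise = FALSE)
  cal <- calibrate_etr(oc, Rd = p$Rd)
  expect_equal(cal$alpha_beta, p$alpha_beta, tolerance = 1e-9)
  expect_equal(cal$b, 0, tolerance = 1e-9)
  expect_equal(cal$r2, 1, tolerance = 1e-12)
})

test_that("linear low-Ci fixtures intersect at (Ci*, -Rd) exactly", {
  p <- noise_free_params()
  lc <- simulate_laisk_curves(p, noise = FALSE)
  est <- laisk(lc)
  expect_equal(est$Ci_star, p$Ci_star, tolerance = 1e-8)
  expect_equal(est$Rd, p$Rd, tolerance = 1e-8)
  # the curved generator exposes the straight-line fitting bias
  lc2 <- simulate_laisk_curves(p, shape = "fvcb", noise = FALSE)
  est2 <- suppressWarnings(laisk(lc2))
  expect_gt(abs(est2$Ci_star - p$Ci_star), abs(est$Ci_star - p$Ci_star))
})

test_that("noise-free estimators recover every targeted truth parameter", {
  p <- noise_free_params()
  lk <- laisk(simulate_laisk_curves(p, noise = FALSE))
  cal <- calibrate_etr(simulate_o2_calibration_curve(p, noise = FALSE),
                       Rd = lk$Rd)
  expect_equal(lk$Rd, p$Rd, tolerance = 1e-6)
  expect_equal(lk$Ci_star, p$Ci_star, tolerance = 0.1)
  expect_equal(cal$alpha_beta, p$alpha_beta, tolerance = 1e-6)

  curve <- simulate_aci_curve(p, noise = FALSE)
  lk2 <- gamma_star(lk, mode = "iterative", gm = function(gs) {
    e <- gm_variable_j(curve, cal = cal, Rd = lk$Rd, gamma_star = gs)
    median(e$gm[e$reliable], na.rm = TRUE)
  })
  est <- gm_variable_j(curve, cal = cal, Rd = lk$Rd,
                       gamma_star = lk2$gamma_star)
  rel <- est[est$reliable, ]
  expect_true(all(abs(rel$gm - p$gm) / p$gm < 0.02))

  # FvCB parameters from the converted curve; at PPFD 1500 the
  # operating electron transport is the light-response value, not
  # Jmax itself, so that is what the Aj branch identifies
  gm_curve <- rel$gm[rel$Ca == 400][1]
  acc <- aci_to_acc(est, gm = gm_curve)
  kc <- kinetic_constants(Gamma_star25 = p$Gamma_star, Kc25 = p$Kc,
                          Ko25 = p$Ko)
  fit <- fit_fvcb(acc, Rd = p$Rd, constants = kc,
                  Gamma_star = p$Gamma_star)
  q <- p$alpha_beta * 1500
  j_op <- (q + p$Jmax - sqrt((q + p$Jmax)^2 -
                               4 * p$theta * q * p$Jmax)) /
    (2 * p$theta)
  expect_equal(fit$Vcmax, p$Vcmax, tolerance = 0.02)
  expect_equal(fit$Jmax, j_op, tolerance = 0.02)
})

test_that("estimator error grows monotonically with assimilation noise", {
  sig <- c(0, 0.15, 0.3, 0.6)
  rmse <- purrr::map_dbl(sig, function(s) {
    set.seed(101) # common random numbers isolate the noise-level effect
    p <- truth_params(sigma_A = s, sigma_phi = 0, sigma_gsw = 0)
    base <- simulate_aci_curve(noise_free_params(), noise = FALSE)
    errs <- replicate(60, {
      noisy <- base
      noisy$An <- base$true_An + rnorm(nrow(base), 0, s)
      noisy$Ci_raw <- noisy$Ca - 1.6 * noisy$An / noisy$gsw
      est <- gm_variable_j(noisy, Rd = p$Rd,
                           gamma_star = p$Gamma_star,
                           J = base$true_J)
      g <- est$gm[est$reliable]
      median(g, na.rm = TRUE) - p$gm
    })
    sqrt(mean(errs^2))
  })
  expect_true(all(diff(rmse) > 0))
  expect_equal(rmse[1], 0, tolerance = 1e-9)
})

test_that("seeded study simulation is reproducible and labelled", {
  gp <- list(WT = truth_params(), d1 = truth_params(gm = 0.42))
  set.seed(5)
  s1 <- simulate_study(gp, n_plants = 2, days = c(0, 8, 16))
  set.seed(5)
  s2 <- simulate_study(gp, n_plants = 2, days = c(0, 8, 16))
  expect_identical(s1$gasex, s2$gasex)
  expect_identical(s1$pot_weights, s2$pot_weights)
  expect_setequal(unique(s1$gasex$genotype), c("WT", "d1"))
  # pot weights reproduce the intended drydown through the RSWC formula
  pw <- dplyr::left_join(
    s1$pot_weights,
    dplyr::distinct(s1$gasex, plant_id, day, rswc),
    by = c("plant_id", "day"))
  expect_equal(compute_rswc(pw$PW, pw$DW, pw$t0W), pw$rswc,
               tolerance = 1e-9)
})
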
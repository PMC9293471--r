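test_that("cuticular Ci correction follows the conductance algebra", {
  rec <- tibble::tibble(An = 20, Ca = 400, Ci_raw = 280,
                        El = 0.003, Wi = 0.032, Wa = 0.012)
  out <- correct_ci(rec, Ec = 0.005)
  # g_tw = 0.15, g' = 0.14, Ci = 400 - 1.6*20/0.14
  expect_equal(out$Ci_corr, 400 - 1.6 * 20 / 0.14, tolerance = 1e-12)

  expect_equal(correct_ci(rec, mode = "off")$Ci_corr, 280)
  rec0 <- dplyr::mutate(rec, An = 0)
  expect_equal(correct_ci(rec0)$Ci_corr, 400)

  # infeasible correction: g' <= 0 flags and retains Ci_raw
  tiny <- dplyr::mutate(rec, El = 0.0001)
  expect_warning(bad <- correct_ci(tiny), "flagged")
  expect_false(bad$ci_corr_ok)
  expect_equal(bad$Ci_corr, 280)
})

test_that("variable-J Cc matches its closed form and limits", {
  expect_equal(chloroplastic_cc(An = 20, Rd = 1, J = 150,
                                gamma_star = 40),
               40 * (150 + 8 * 21) / (150 - 4 * 21), tolerance = 1e-12)
  # gross assimilation zero -> Cc = Gamma*
  expect_equal(chloroplastic_cc(An = -1, Rd = 1, J = 100,
                                gamma_star = 40), 40)
  # J -> infinity: Cc -> Gamma* from above
  big <- chloroplastic_cc(20, 1, 1e9, 40)
  expect_gt(big, 40)
  expect_equal(big, 40, tolerance = 1e-5)
  # singular denominator flagged as NA
  expect_true(is.na(chloroplastic_cc(20, 1, 84, 40)))
})

test_that("gm estimation reproduces the worked arithmetic and round-trips", {
  # build a record whose corrected Ci is exactly 280
  gsw_st <- 0.3 # stomatal water conductance; instrument adds 2*Ec
  El_tot <- (gsw_st + 2 * 0.005) * 0.02
  rec <- tibble::tibble(An = 20, Ca = 280 + 1.6 * 20 / gsw_st,
                        Ci_raw = NA, gsw = El_tot / 0.02,
                        El = El_tot, Wi = 0.032, Wa = 0.012,
                        Ft = 1500, Fm_prime = 2000, PPFD = 1500)
  est <- gm_variable_j(rec, Rd = 1, gamma_star = 40, J = 150)
  cc <- 40 * 318 / 66
  expect_equal(est$Cc, cc, tolerance = 1e-10)
  expect_equal(est$gm, 20 / (280 - cc), tolerance = 1e-10)
  # Fick round-trip: Ci - An/gm reproduces Cc exactly
  expect_equal(est$Ci_corr - est$An / est$gm, est$Cc, tolerance = 1e-12)
  expect_equal(est$gsc, est$gsw / 1.6)
  expect_equal(est$wue_i, est$An / est$gsw)
  expect_equal(est$drawdown_surface, est$Ca - est$Ci_corr)
  expect_equal(est$drawdown_mesophyll, est$Ci_corr - est$Cc)
})

test_that("near-singular and non-physical estimates are flagged not dropped", {
  El_tot <- 0.31 * 0.02
  base <- tibble::tibble(An = 20, Ca = 280 + 1.6 * 20 / 0.3,
                         Ci_raw = NA, gsw = 0.31, El = El_tot,
                         Wi = 0.032, Wa = 0.012,
                         Ft = 1500, Fm_prime = 2000, PPFD = 1500)
  # J barely above 4(An+Rd): Cc blows past Ci -> gm negative, unreliable
  est <- gm_variable_j(base, Rd = 1, gamma_star = 40, J = 4 * 21 * 1.01)
  expect_false(est$reliable)
  expect_equal(nrow(est), 1) # retained
  # J below the singularity: Cc undefined, gm missing
  est2 <- gm_variable_j(base, Rd = 1, gamma_star = 40, J = 80)
  expect_true(is.na(est2$gm))
  expect_false(est2$reliable)
})

test_that("gm decreases with J at fixed An, Rd, Gamma*, Ci", {
  # larger J pulls Cc toward Gamma*, widening the Ci - Cc drawdown,
  # so the implied gm falls; verified against finite differences
  rec <- tibble::tibble(An = 20, Ca = 280 + 1.6 * 20 / 0.3,
                        Ci_raw = NA, gsw = 0.31, El = 0.31 * 0.02,
                        Wi = 0.032, Wa = 0.012, Ft = 1500,
                        Fm_prime = 2000, PPFD = 1500)
  # admissible region: J comfortably above 4(An + Rd) so Cc < Ci
  js <- seq(140, 240, by = 10)
  gms <- purrr::map_dbl(js, function(j) {
    gm_variable_j(rec, Rd = 1, gamma_star = 40, J = j)$gm
  })
  expect_true(all(gms > 0))
  expect_true(all(diff(gms) < 0))
  # finite-difference sign check on Cc itself
  dcc <- chloroplastic_cc(20, 1, 150 + 1e-4, 40) -
    chloroplastic_cc(20, 1, 150, 40)
  expect_lt(dcc, 0)
})

test_that("forward-simulated records recover the true gm", {
  p <- noise_free_params()
  curve <- simulate_aci_curve(p, noise = FALSE)
  est <- gm_variable_j(curve, Rd = p$Rd, gamma_star = p$Gamma_star,
                       J = curve$true_J)
  rel <- est[est$reliable, ]
  expect_gt(nrow(rel), 3)
  expect_true(all(abs(rel$gm - p$gm) / p$gm < 0.01))
})

test_that("per-genotype gm~gsc regression recovers known slopes", {
  set.seed(77)
  mk <- function(geno, slope, n) {
    gsc <- runif(n, 0.05, 0.25)
    tibble::tibble(genotype = geno, gsc = gsc,
                   gm = 0.05 + slope * gsc + rnorm(n, 0, 0.02),
                   reliable = TRUE)
  }
  fits <- gm_vs_gsc_regression(dplyr::bind_rows(mk("WT", 0.9, 20),
                                                mk("d1", 0.4, 20)))
  expect_equal(sort(fits$genotype), c("WT", "d1") |> sort())
  wt <- fits[fits$genotype == "WT", ]
  d1 <- fits[fits$genotype == "d1", ]
  se_wt <- (wt$slope_high - wt$slope_low) / (2 * 1.96)
  se_d1 <- (d1$slope_high - d1$slope_low) / (2 * 1.96)
  expect_lt(abs(wt$slope - 0.9), 2 * se_wt)
  expect_lt(abs(d1$slope - 0.4), 2 * se_d1)

  # exact line gives exact slope; undersized groups are skipped
  exact <- tibble::tibble(genotype = "g", gsc = c(0.1, 0.2, 0.3),
                          gm = 0.1 + 0.5 * c(0.1, 0.2, 0.3),
                          reliable = TRUE)
  expect_equal(gm_vs_gsc_regression(exact)$slope, 0.5,
               tolerance = 1e-12)
  two <- exact[1:2, ]
  expect_warning(out <- gm_vs_gsc_regression(two), "skipped")
  expect_equal(nrow(out), 0)
})
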
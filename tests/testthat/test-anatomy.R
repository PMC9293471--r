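test_that("surface-per-area and air-space fraction follow their formulas", {
  expect_equal(surface_per_area(l = 100, W = 100), 1.42)
  expect_equal(surface_per_area(l = 200, W = 100), 2.84)
  # inverse computation from a typical rice Sm value
  expect_equal(surface_per_area(l = 1232, W = 100), 17.49, tolerance = 1e-3)
  expect_error(surface_per_area(l = 100, W = 0), "W")

  expect_equal(ias_fraction(0, 70), 0)
  expect_equal(ias_fraction(50, 50), 0.5)
  expect_equal(ias_fraction(30, 70), 0.3)
  expect_error(ias_fraction(0, 0), "zero")
})

test_that("gas-phase conductance matches scalar arithmetic and scales linearly", {
  g <- gas_phase_conductance(f_ias = 0.3, Tleaf_um = 68.5)
  expect_equal(g$g_ias_ms, 1.51e-4 * 0.3 / (68.5e-6 / 2 * 1.57),
               tolerance = 1e-12)
  expect_equal(g$g_ias_ms, 0.8425, tolerance = 1e-4)
  g2 <- gas_phase_conductance(f_ias = 0.6, Tleaf_um = 68.5)
  expect_equal(g2$g_ias_ms, 2 * g$g_ias_ms)
})

test_that("liquid component conductances match scalar arithmetic", {
  # wild-type-like cell wall: Dw*1.0*0.3/0.128um
  expect_equal(liquid_component_conductance(0.128, rf = 1, p = 0.3),
               4.195e-3, tolerance = 1e-3)
  # stroma at half chloroplast thickness: Dw*0.3*1.0/1.3um
  expect_equal(liquid_component_conductance(1.3, rf = 0.3, p = 1),
               4.131e-4, tolerance = 1e-3)
  # halving the path doubles the conductance
  expect_equal(liquid_component_conductance(0.064, rf = 1, p = 0.3),
               2 * liquid_component_conductance(0.128, rf = 1, p = 0.3))
  expect_error(liquid_component_conductance(0), "positive")
})

test_that("compose_gm equals the independent resistor-chain oracle", {
  set.seed(61)
  const <- diffusion_constants()
  anat <- random_anatomy(1000)
  for (i in seq_len(nrow(anat))) {
    a <- anat[i, ]
    got <- compose_gm(a, const)
    want <- oracle_anat_gm(a, const)
    expect_equal(got$r_liq, want$r_liq, tolerance = 1e-12)
    expect_equal(got$gm_model, want$gm_mol, tolerance = 1e-12)
  }
})

test_that("component resistance shares sum to one", {
  set.seed(62)
  anat <- random_anatomy(50)
  for (i in seq_len(nrow(anat))) {
    expect_equal(sum(compose_gm(anat[i, ])$r_share), 1,
                 tolerance = 1e-12)
  }
})

test_that("modeled gm is monotone in every anatomical trait", {
  base <- rice_anatomy_means()[1, ]
  gm0 <- compose_gm(base)$gm_model
  bump <- function(field, f) {
    a <- base; a[[field]] <- a[[field]] * f; compose_gm(a)$gm_model
  }
  # thicker diffusion paths lower gm
  for (f in c("Tcw", "Tcyt", "Tchl")) expect_lt(bump(f, 1.3), gm0)
  # larger exposed surfaces and air fraction raise gm
  expect_gt(bump("Sm", 1.2), gm0)
  expect_gt(bump("f_ias", 1.2), gm0)
  a <- base; a$Sc <- a$Sc * 1.2; expect_gt(compose_gm(a)$gm_model, gm0)
})

test_that("composite gm is bounded by its serial components", {
  res <- compose_gm(rice_anatomy_means()[1, ])
  expect_lt(res$gm_model, res$g_ias_mol)
  # liquid phase in gas-equivalent molar units also bounds gm
  partition <- 8.314 * res$const$Tk / res$const$H
  g_liq_gas_equiv <- res$g_liq_mol / partition
  expect_lt(res$gm_model, g_liq_gas_equiv)
  expect_true(all(res$r_leaf > 0))
})

test_that("genotype comparison reports the documented scaling behavior", {
  am <- rice_anatomy_means()
  wt <- compose_gm(am[1, ])
  cmp_same <- compare_genotypes(wt, wt)
  expect_equal(cmp_same$reduction_per_leaf_area_pct,
               rep(0, nrow(cmp_same)))

  # doubling Sc halves per-leaf-area resistance of intracellular
  # components but leaves per-surface values unchanged
  a2 <- am[1, ]; a2$Sc <- a2$Sc * 2
  # keep Sm >= Sc valid
  a2$Sm <- max(a2$Sm, a2$Sc)
  cmp <- compare_genotypes(wt, compose_gm(a2))
  intra <- cmp[cmp$component %in% c("cyt", "env", "st"), ]
  expect_equal(intra$reduction_per_surface_pct, rep(0, 3),
               tolerance = 1e-9)
  expect_equal(intra$reduction_per_leaf_area_pct, rep(50, 3),
               tolerance = 1e-9)

  expect_error(
    compare_genotypes(wt, compose_gm(am[2, ],
                                     diffusion_constants(Tk = 300))),
    "different")
})

test_that("degenerate anatomies are rejected with named fields", {
  a <- rice_anatomy_means()[1, ]
  a$Sc <- a$Sm + 1
  expect_error(compose_gm(a), "Sc")
  b <- rice_anatomy_means()[1, ]
  b$Tcw <- -1
  expect_error(compose_gm(b), "Tcw")
})
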
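make_exact_curves <- function(slopes = c(0.02, 0.03, 0.05),
                              ci_star = 40, rd = 0.2,
                              ci = seq(50, 150, by = 20)) {
  purrr::map_dfr(seq_along(slopes), function(i) {
    tibble::tibble(PPFD = c(100, 200, 400)[i], Ci = ci,
                   An = -rd + slopes[i] * (ci - ci_star))
  })
}

test_that("exact low-Ci lines are recovered to machine precision", {
  curves <- make_exact_curves()
  lines <- fit_low_ci_lines(curves)
  expect_equal(lines$slope, c(0.02, 0.03, 0.05), tolerance = 1e-12)
  expect_equal(lines$intercept, -0.2 - c(0.02, 0.03, 0.05) * 40,
               tolerance = 1e-10)
})

test_that("window and distinctness guards trigger", {
  curves <- make_exact_curves(ci = c(40, 100, 200, 250))
  # only 2 points with Ci <= 150 per curve
  expect_error(fit_low_ci_lines(curves), "fewer than 3")
  dup <- dplyr::mutate(make_exact_curves(), PPFD = 100)
  expect_error(fit_low_ci_lines(dup), "distinct")
})

test_that("lines through a common point yield that point as (Ci*, -Rd)", {
  est <- laisk(make_exact_curves())
  expect_equal(est$Ci_star, 40, tolerance = 1e-9)
  expect_equal(est$Rd, 0.2, tolerance = 1e-9)
  # all three pairwise intersections coincide
  expect_equal(est$intersections$x, rep(40, 3), tolerance = 1e-9)

  # parallel pair is a degenerate geometry
  expect_error(
    intersect_and_average(tibble::tibble(slope = c(0.02, 0.02, 0.05),
                                         intercept = c(-1, -2, -3))),
    "parallel")
})

test_that("estimate equals the centroid of brute-force pairwise solves", {
  set.seed(52)
  m <- c(0.021, 0.034, 0.049)
  b <- c(-1.0, -1.5, -2.1) + rnorm(3, 0, 0.05)
  est <- intersect_and_average(tibble::tibble(slope = m, intercept = b))
  # independent oracle: solve each 2x2 linear system directly
  xs <- ys <- c()
  for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
    sol <- solve(matrix(c(-m[p[1]], 1, -m[p[2]], 1), 2, byrow = TRUE),
                 c(b[p[1]], b[p[2]]))
    xs <- c(xs, sol[1]); ys <- c(ys, sol[2])
  }
  expect_equal(est$Ci_star, mean(xs), tolerance = 1e-12)
  expect_equal(est$Rd, -mean(ys), tolerance = 1e-12)
})

test_that("the estimate is invariant to curve labeling order", {
  curves <- make_exact_curves(slopes = c(0.018, 0.031, 0.052))
  shuffled <- dplyr::arrange(curves, dplyr::desc(PPFD), Ci)
  e1 <- laisk(curves)
  e2 <- laisk(shuffled)
  expect_equal(e1$Ci_star, e2$Ci_star)
  expect_equal(e1$Rd, e2$Rd)
})

test_that("noisy line slopes are recovered with small bias", {
  set.seed(53)
  xs <- seq(50, 150, length.out = 6)
  slopes <- c(0.02, 0.03, 0.05)
  est <- replicate(500, {
    fit_low_ci_lines(purrr::map_dfr(seq_along(slopes), function(i) {
      tibble::tibble(PPFD = c(100, 200, 400)[i], Ci = xs,
                     An = -0.2 + slopes[i] * (xs - 40) +
                       rnorm(6, 0, 0.2))
    }))$slope
  })
  bias <- abs(rowMeans(est) - slopes) / slopes
  expect_lt(max(bias), 0.05)
})

test_that("gamma* modes behave as documented", {
  est <- laisk(make_exact_curves(ci_star = 40, rd = 1))
  # default: Gamma* = Ci*
  e1 <- gamma_star(est, mode = "ci_star_as_gamma_star")
  expect_equal(e1$gamma_star, e1$Ci_star)
  # fixed gm: fixed point at Ci* + Rd/gm
  e2 <- gamma_star(est, mode = "iterative", gm = 0.25)
  expect_equal(e2$gamma_star, 40 + 1 / 0.25, tolerance = 0.05)
  expect_gte(e2$gamma_star, e1$gamma_star)
  # Rd = 0: the correction vanishes
  est0 <- laisk(make_exact_curves(rd = 0))
  e3 <- gamma_star(est0, mode = "iterative", gm = 0.25)
  expect_equal(e3$gamma_star, est0$Ci_star, tolerance = 0.05)
  # temperature-function constant at 25C equals the configured value
  e4 <- gamma_star(est, mode = "bernacchi_constant", Tleaf_C = 25)
  expect_equal(e4$gamma_star, 42.75)
  expect_error(gamma_star(est, mode = "iterative"), "requires gm")
})
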
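#' Fit low-Ci linear responses at several irradiances
#'
#' The Laisk approach measures the initial (low-Ci) portion of the A-Ci
#' response at several sub-saturating irradiances; in that regime An is
#' close to linear in Ci and the lines for different irradiances cross
#' at the intercellular photo-compensation point. This fits one OLS line
#' per curve within the low-Ci window.
#'
#' @param curves Tibble with columns `Ci`, `An`, `PPFD` (one PPFD level
#'   per curve; typically 100, 200, 400 umol m-2 s-1).
#' @param ci_max Upper bound of the low-Ci window (umol mol-1), default
#'   150.
#' @return Tibble with one row per PPFD level: `PPFD`, `slope`,
#'   `intercept`, `n`. Slopes should increase with PPFD; a warning is
#'   issued if they do not.
#' @export
fit_low_ci_lines <- function(curves, ci_max = 150) {
  stopifnot(is.data.frame(curves),
            all(c("Ci", "An", "PPFD") %in% names(curves)))
  levels <- sort(unique(curves$PPFD))
  if (length(levels) < 2) {
    stop("need at least 2 strictly distinct PPFD levels; got ",
         length(levels), call. = FALSE)
  }
  win <- filter(as_tibble(curves), .data$Ci <= ci_max)
  fits <- win %>%
    group_by(.data$PPFD) %>%
    summarise(n = dplyr::n(),
              slope = if (dplyr::n() >= 3)
                unname(coef(lm(An ~ Ci))[2]) else NA_real_,
              intercept = if (dplyr::n() >= 3)
                unname(coef(lm(An ~ Ci))[1]) else NA_real_,
              .groups = "drop") %>%
    arrange(.data$PPFD)
  if (any(fits$n < 3)) {
    stop("curve(s) at PPFD ", paste(fits$PPFD[fits$n < 3], collapse = ", "),
         " have fewer than 3 points with Ci <= ", ci_max, call. = FALSE)
  }
  if (is.unsorted(fits$slope, strictly = TRUE)) {
    warning("low-Ci slopes do not increase strictly with PPFD; ",
            "check curve quality", call. = FALSE)
  }
  select(fits, "PPFD", "slope", "intercept", "n")
}

#' Intersect low-Ci lines and average into Rd and Ci*
#'
#' Each pair of low-Ci lines at different irradiance intersects at a
#' point near (Ci*, -Rd). The estimate averages the pairwise
#' intersections: `Ci* = mean(x)`, `Rd = -mean(y)` (Rd stored positive).
#'
#' @param lines Tibble from [fit_low_ci_lines()] (columns `slope`,
#'   `intercept`, optionally `PPFD`).
#' @return An object of class `laisk_estimate`: list with `Rd`,
#'   `Ci_star`, `gamma_star` (initialised to `Ci_star`, see
#'   [gamma_star()]), `mode`, and the tibble of pairwise
#'   `intersections`.
#' @export
intersect_and_average <- function(lines) {
  stopifnot(is.data.frame(lines),
            all(c("slope", "intercept") %in% names(lines)),
            nrow(lines) >= 2)
  m <- lines$slope
  b <- lines$intercept
  pairs <- utils::combn(seq_along(m), 2)
  xs <- ys <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    dm <- m[i] - m[j]
    if (abs(dm) < 1e-12 * max(abs(m[i]), abs(m[j]), 1)) {
      stop("lines ", i, " and ", j,
           " are parallel; intersection undefined", call. = FALSE)
    }
    xs[p] <- (b[j] - b[i]) / dm
    ys[p] <- m[i] * xs[p] + b[i]
  }
  ci_star <- mean(xs)
  rd <- -mean(ys)
  if (rd < -1e-9) {
    warning("intersection implies negative Rd (", format(rd),
            "); estimate is suspect", call. = FALSE)
  }
  structure(
    list(Rd = rd, Ci_star = ci_star, gamma_star = ci_star,
         mode = "ci_star_as_gamma_star",
         intersections = tibble(pair = paste0(pairs[1, ], "-", pairs[2, ]),
                                x = xs, y = ys),
         lines = as_tibble(lines)),
    class = "laisk_estimate"
  )
}

#' Estimate Rd and Ci* from low-Ci curves (Laisk method)
#'
#' Convenience wrapper: [fit_low_ci_lines()] then
#' [intersect_and_average()].
#'
#' @inheritParams fit_low_ci_lines
#' @return A `laisk_estimate` object.
#' @export
#' @examples
#' curves <- tidyr::crossing(PPFD = c(100, 200, 400),
#'                           Ci = seq(40, 140, by = 20)) |>
#'   dplyr::mutate(An = dplyr::case_when(
#'     PPFD == 100 ~ -0.2 + 0.02 * (Ci - 40),
#'     PPFD == 200 ~ -0.2 + 0.03 * (Ci - 40),
#'     PPFD == 400 ~ -0.2 + 0.05 * (Ci - 40)
#'   ))
#' laisk(curves) # Ci* = 40, Rd = 0.2
laisk <- function(curves, ci_max = 150) {
  intersect_and_average(fit_low_ci_lines(curves, ci_max = ci_max))
}

#' @export
print.laisk_estimate <- function(x, ...) {
  cat("Laisk estimate (low-Ci intersections)\n")
  cat(sprintf("  Rd = %.3f umol m-2 s-1, Ci* = %.2f umol mol-1\n",
              x$Rd, x$Ci_star))
  cat(sprintf("  Gamma* = %.2f umol mol-1 (mode: %s)\n",
              x$gamma_star, x$mode))
  invisible(x)
}

#' @export
tidy.laisk_estimate <- function(x, ...) {
  tibble(term = c("Rd", "Ci_star", "gamma_star"),
         estimate = c(x$Rd, x$Ci_star, x$gamma_star))
}

#' @export
glance.laisk_estimate <- function(x, ...) {
  tibble(Rd = x$Rd, Ci_star = x$Ci_star, gamma_star = x$gamma_star,
         mode = x$mode)
}

#' Apparent chloroplastic photo-compensation point
#'
#' Converts a Laisk `Ci*` into `Gamma*`. The relation is
#' `Gamma* = Ci* + Rd / gm`, but gm is unknown before gm estimation, so
#' three modes are offered: `"ci_star_as_gamma_star"` (default) takes
#' `Gamma* = Ci*`; `"bernacchi_constant"` uses the temperature response
#' of the configured kinetic constants; `"iterative"` applies a damped
#' fixed-point update `Gamma* <- Ci* + Rd/gm(Gamma*)` until convergence,
#' given a gm provider.
#'
#' @param result A `laisk_estimate`.
#' @param mode One of `"ci_star_as_gamma_star"`, `"bernacchi_constant"`,
#'   `"iterative"`.
#' @param gm For `"iterative"`: either a fixed gm (mol m-2 s-1) or a
#'   function `function(gamma_star)` returning gm.
#' @param Tleaf_C Leaf temperature, needed for `"bernacchi_constant"`.
#' @param constants [kinetic_constants()] for `"bernacchi_constant"`.
#' @param tol Convergence tolerance on Gamma* (umol mol-1).
#' @param max_iter Iteration cap.
#' @param damping Fixed-point damping factor in (0, 1].
#' @return The input `laisk_estimate` with `gamma_star` and `mode`
#'   updated.
#' @export
gamma_star <- function(result,
                       mode = c("ci_star_as_gamma_star",
                                "bernacchi_constant", "iterative"),
                       gm = NULL, Tleaf_C = 25,
                       constants = kinetic_constants(),
                       tol = 0.01, max_iter = 50, damping = 0.5) {
  stopifnot(inherits(result, "laisk_estimate"))
  mode <- match.arg(mode)
  gs <- switch(
    mode,
    ci_star_as_gamma_star = result$Ci_star,
    bernacchi_constant = arrhenius(constants$Gamma_star25, Tleaf_C,
                                   constants$Ea_Gamma_star),
    iterative = {
      if (is.null(gm)) {
        stop("mode 'iterative' requires gm (value or function)",
             call. = FALSE)
      }
      gm_fun <- if (is.function(gm)) gm else function(g) gm
      g_cur <- result$Ci_star
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        g_new <- result$Ci_star + result$Rd / gm_fun(g_cur)
        step <- g_new - g_cur
        g_next <- g_cur + damping * step
        if (abs(g_next - g_cur) < tol) {
          g_cur <- g_next
          converged <- TRUE
          break
        }
        g_cur <- g_next
      }
      if (!converged) {
        stop("Gamma* iteration did not converge in ", max_iter,
             " iterations; last iterate ", format(g_cur), call. = FALSE)
      }
      g_cur
    }
  )
  result$gamma_star <- gs
  result$mode <- mode
  result
}
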
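#' Operating quantum yield of photosystem II
#'
#' Genty-style yield from light-adapted fluorescence:
#' `PhiPSII = (Fm' - Ft) / Fm'`.
#'
#' @param Ft Steady-state fluorescence (instrument units).
#' @param Fm_prime Light-adapted maximal fluorescence after a saturating
#'   flash (instrument units).
#' @return PhiPSII in (0, 1). Vectorised.
#' @export
#' @examples
#' phi_psii(Ft = 500, Fm_prime = 2000) # 0.75
phi_psii <- function(Ft, Fm_prime) {
  if (any(!is.finite(Ft) | !is.finite(Fm_prime) | Ft <= 0 |
            Fm_prime <= Ft)) {
    stop("require Fm_prime > Ft > 0 for every record", call. = FALSE)
  }
  (Fm_prime - Ft) / Fm_prime
}

#' Apparent quantum yield of CO2 fixation
#'
#' `PhiCO2 = (An + Rd) / PPFD`: gross assimilation per incident photon.
#'
#' @param An Net assimilation (umol CO2 m-2 s-1).
#' @param Rd Day respiration (umol CO2 m-2 s-1, positive).
#' @param PPFD Incident photon flux (umol m-2 s-1), must be positive.
#' @return PhiCO2. Vectorised.
#' @export
#' @examples
#' phi_co2(An = 14, Rd = 1, PPFD = 300) # 0.05
phi_co2 <- function(An, Rd, PPFD) {
  if (any(!is.finite(PPFD) | PPFD <= 0)) {
    stop("PPFD must be positive", call. = FALSE)
  }
  if (any(Rd < 0)) stop("Rd must be non-negative", call. = FALSE)
  (An + Rd) / PPFD
}

#' Calibrate fluorescence electron transport against CO2 fixation
#'
#' Under non-photorespiratory conditions (1 percent O2) CO2 fixation is
#' the only electron sink, so PhiPSII is linear in PhiCO2. An ordinary
#' least-squares regression of PhiPSII on PhiCO2, restricted to the
#' linear region `PhiCO2 < 0.05` and `PhiPSII < 0.5`, yields a slope `k`
#' and intercept `b` from which the effective absorbance x PSII
#' partitioning product is `alpha_beta = 4 / k`; the calibrated electron
#' transport rate is then [j_calibrated()].
#'
#' @param records Tibble of gas-exchange records with fluorescence
#'   (`Ft`, `Fm_prime`, `An`, `PPFD`, `O2_frac`) measured at ~1% O2.
#' @param Rd Day respiration (umol m-2 s-1) used inside PhiCO2; the
#'   Laisk estimate by default.
#' @param phi_co2_max,phi_psii_max Linear-region filter bounds.
#' @param o2_max Records with `O2_frac` above this are excluded
#'   (photorespiratory; default 0.05).
#'
#' @return An object of class `etr_calibration`: list with `k`, `b`,
#'   `alpha_beta = 4/k`, `n_used`, `r2`, and the point set used.
#' @export
calibrate_etr <- function(records, Rd, phi_co2_max = 0.05,
                          phi_psii_max = 0.5, o2_max = 0.05) {
  stopifnot(is.data.frame(records), is.numeric(Rd), Rd >= 0)
  df <- as_tibble(records)
  if (!is.null(df$O2_frac)) df <- filter(df, .data$O2_frac <= o2_max)
  df <- filter(df, is.finite(.data$Ft), is.finite(.data$Fm_prime))
  if (nrow(df) < 3) {
    stop("need at least 3 fluorescence records at low O2 to calibrate",
         call. = FALSE)
  }
  df <- mutate(df,
               phi_psii = phi_psii(.data$Ft, .data$Fm_prime),
               phi_co2 = phi_co2(.data$An, Rd, .data$PPFD))
  used <- filter(df, .data$phi_co2 < phi_co2_max,
                 .data$phi_psii < phi_psii_max)
  if (nrow(used) < 3) {
    stop("fewer than 3 points survive the linear-region filter ",
         "(PhiCO2 < ", phi_co2_max, ", PhiPSII < ", phi_psii_max, ")",
         call. = FALSE)
  }
  fit <- lm(phi_psii ~ phi_co2, data = used)
  k <- unname(coef(fit)[2])
  b <- unname(coef(fit)[1])
  if (!is.finite(k) || k <= 0) {
    stop("calibration slope k must be positive; got ", format(k),
         call. = FALSE)
  }
  structure(
    list(k = k, b = b, alpha_beta = 4 / k, n_used = nrow(used),
         r2 = suppressWarnings(summary(fit)$r.squared), Rd = Rd,
         points = select(used, "phi_co2", "phi_psii")),
    class = "etr_calibration"
  )
}

#' @export
print.etr_calibration <- function(x, ...) {
  cat("Electron-transport calibration (PhiPSII ~ PhiCO2, 1% O2)\n")
  cat(sprintf("  k = %.4f, b = %.4f, alpha*beta = 4/k = %.4f\n",
              x$k, x$b, x$alpha_beta))
  cat(sprintf("  n = %d points in linear region, r^2 = %.4f\n",
              x$n_used, x$r2))
  invisible(x)
}

#' @export
tidy.etr_calibration <- function(x, ...) {
  tibble(term = c("k", "b", "alpha_beta"),
         estimate = c(x$k, x$b, x$alpha_beta))
}

#' @export
glance.etr_calibration <- function(x, ...) {
  tibble(k = x$k, b = x$b, alpha_beta = x$alpha_beta,
         n_used = x$n_used, r2 = x$r2)
}

#' Calibrated electron transport rate
#'
#' `Jcal = 4 * (PhiPSII - b) / k * PPFD`, using the slope and intercept
#' of an [calibrate_etr()] fit. With `b = 0` this reduces to the
#' uncalibrated `J = PhiPSII * PPFD * alpha * beta`.
#'
#' @param phi_psii Operating PSII yield.
#' @param PPFD Photon flux (umol m-2 s-1).
#' @param cal An `etr_calibration` object (or list with `k` and `b`).
#' @return Jcal (umol electrons m-2 s-1). Non-positive results are
#'   returned as `NA` with a warning: they are non-physical and must be
#'   excluded downstream.
#' @export
j_calibrated <- function(phi_psii, PPFD, cal) {
  stopifnot(is.numeric(phi_psii), is.numeric(PPFD), all(PPFD >= 0))
  j <- 4 * (phi_psii - cal$b) / cal$k * PPFD
  bad <- is.finite(j) & j < 0
  if (any(bad)) {
    warning(sum(bad), " non-positive Jcal value(s) flagged as NA",
            call. = FALSE)
    j[bad] <- NA_real_
  }
  j
}
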
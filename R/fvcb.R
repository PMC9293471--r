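#' Convert an A-Ci curve to an A-Cc curve
#'
#' Applies Fick's law across the mesophyll, `Cc = Ci - An / gm`, using
#' either a single curve-level gm or a per-point gm column.
#'
#' @param curve Tibble with `An` and `Ci_corr` (or `Ci`) columns; for
#'   `gm = "pointwise"` also a `gm` column.
#' @param gm Either a single mesophyll conductance (mol m-2 s-1) applied
#'   to every point, or the string `"pointwise"` to use the curve's `gm`
#'   column.
#' @return The curve with a `Cc` column added, ordered by `Cc`.
#' @export
#' @examples
#' aci_to_acc(tibble::tibble(An = 20, Ci_corr = 280), gm = 0.2292)
aci_to_acc <- function(curve, gm) {
  df <- as_tibble(curve)
  ci_col <- if ("Ci_corr" %in% names(df)) "Ci_corr" else "Ci"
  stopifnot("An" %in% names(df), ci_col %in% names(df))
  if (identical(gm, "pointwise")) {
    if (!"gm" %in% names(df)) {
      stop("gm = \"pointwise\" requires a gm column", call. = FALSE)
    }
    gm_vec <- df$gm
  } else {
    stopifnot(is.numeric(gm), length(gm) == 1)
    gm_vec <- rep(gm, nrow(df))
  }
  bad <- which(!is.finite(gm_vec) | gm_vec <= 0)
  if (length(bad) > 0) {
    stop("missing or non-positive gm at point(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df$Cc <- df[[ci_col]] - df$An / gm_vec
  arrange(df, .data$Cc)
}

#' FvCB net assimilation at given chloroplastic CO2
#'
#' The Farquhar-von Caemmerer-Berry model:
#' Rubisco-limited `Ac = Vcmax * (Cc - Gamma*) / (Cc + Kc * (1 + O/Ko))`
#' and RuBP-regeneration-limited `Aj = J * (Cc - Gamma*) / (4 * Cc + 8 *
#' Gamma*)`; net assimilation is `min(Ac, Aj) - Rd`. No triose-phosphate
#' limitation term.
#'
#' @param Cc Chloroplastic CO2 (umol mol-1); vectorised.
#' @param Vcmax Maximum carboxylation rate (umol m-2 s-1).
#' @param J Electron transport rate feeding Aj (umol m-2 s-1). For a
#'   light-saturated curve this is effectively Jmax.
#' @param Rd Day respiration (umol m-2 s-1).
#' @param Gamma_star Photo-compensation point (umol mol-1).
#' @param Kc Michaelis constant for CO2 (umol mol-1).
#' @param Ko Michaelis constant for O2 (mmol mol-1).
#' @param O Oxygen mole fraction (mmol mol-1).
#' @return Net assimilation An (umol m-2 s-1).
#' @export
#' @examples
#' fvcb_assimilation(Cc = 300, Vcmax = 80, J = 140, Rd = 1,
#'                   Gamma_star = 40, Kc = 270, Ko = 165, O = 210)
fvcb_assimilation <- function(Cc, Vcmax, J, Rd, Gamma_star,
                              Kc = 404.9, Ko = 278.4, O = 210) {
  stopifnot(all(Cc >= 0))
  Km <- Kc * (1 + O / Ko)
  Ac <- Vcmax * (Cc - Gamma_star) / (Cc + Km)
  Aj <- J * (Cc - Gamma_star) / (4 * Cc + 8 * Gamma_star)
  pmin(Ac, Aj) - Rd
}

#' Fit the FvCB model to an A-Cc curve
#'
#' Least-squares estimation of `Vcmax` and `Jmax` from an A-Cc response,
#' with `Rd` fixed (the Laisk estimate, the recommended use) or free.
#' The limitation-state minimum makes the objective piecewise-smooth, so
#' the fit uses a coarse grid start followed by Nelder-Mead refinement.
#' The crossover `transition_Cc` between Rubisco- and RuBP-limited
#' regions is located on the fitted parameters; if all points fall on
#' one side, the other parameter is flagged unidentifiable.
#'
#' @param curve Tibble with `An` and `Cc` columns.
#' @param Rd Day respiration (umol m-2 s-1).
#' @param constants [kinetic_constants()].
#' @param Tleaf_C Leaf temperature of the curve (degC); kinetics are
#'   evaluated here and `Vcmax25`/`Jmax25` are normalized back to 25.
#' @param Gamma_star Photo-compensation point to use (umol mol-1);
#'   defaults to the kinetic constants' value at `Tleaf_C`. Pass the
#'   Laisk Ci* to mirror a fluorescence-based workflow.
#' @param Rd_free If `TRUE`, Rd is fitted as a third parameter.
#' @return An object of class `fvcb_fit`: Vcmax, Jmax, Vcmax25, Jmax25,
#'   Amax (observed An at the highest Cc), Rd_used, rmse,
#'   transition_Cc, identifiability flags and the fitted curve.
#' @export
fit_fvcb <- function(curve, Rd, constants = kinetic_constants(),
                     Tleaf_C = 25, Gamma_star = NULL, Rd_free = FALSE) {
  df <- as_tibble(curve)
  stopifnot(all(c("An", "Cc") %in% names(df)))
  df <- filter(df, is.finite(.data$An), is.finite(.data$Cc), .data$Cc > 0)
  if (nrow(df) < 5) {
    warning("fewer than 5 points; FvCB parameters may be poorly ",
            "constrained", call. = FALSE)
  }
  kin <- kinetics_at(constants, Tleaf_C)
  gs <- if (is.null(Gamma_star)) kin$Gamma_star else Gamma_star

  obj <- function(par) {
    v <- exp(par[1]); j <- exp(par[2])
    rd <- if (Rd_free) exp(par[3]) else Rd
    pred <- fvcb_assimilation(df$Cc, v, j, rd, gs,
                              Kc = kin$Kc, Ko = kin$Ko, O = kin$O)
    sum((df$An - pred)^2)
  }
  # coarse grid, then simplex refinement from the best few starts (the
  # min(Ac, Aj) surface has flat ridges when one region dominates)
  grid <- expand.grid(v = log(c(20, 50, 80, 120, 180, 260)),
                      j = log(c(40, 80, 140, 200, 300, 420)))
  if (Rd_free) grid$r <- log(max(Rd, 0.5))
  sse <- apply(grid, 1, obj)
  starts <- lapply(order(sse)[1:4],
                   function(i) as.numeric(grid[i, ]))
  fits <- lapply(starts, function(s) {
    f1 <- optim(s, obj, method = "Nelder-Mead",
                control = list(maxit = 10000, reltol = 1e-12))
    f2 <- optim(f1$par, obj, method = "Nelder-Mead",
                control = list(maxit = 10000, reltol = 1e-12))
    if (f2$convergence != 0) {
      # the min(Ac, Aj) kink can stall the tight-tolerance simplex;
      # certify convergence with a looser-tolerance polish
      f2 <- optim(f2$par, obj, method = "Nelder-Mead",
                  control = list(maxit = 10000, reltol = 1e-8))
    }
    f2
  })
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  if (fit$convergence != 0) {
    stop("FvCB fit did not converge; last iterate Vcmax = ",
         format(exp(fit$par[1])), ", Jmax = ", format(exp(fit$par[2])),
         ", objective = ", format(fit$value), call. = FALSE)
  }
  vcmax <- exp(fit$par[1]); jmax <- exp(fit$par[2])
  rd_used <- if (Rd_free) exp(fit$par[3]) else Rd
  pred <- fvcb_assimilation(df$Cc, vcmax, jmax, rd_used, gs,
                            Kc = kin$Kc, Ko = kin$Ko, O = kin$O)
  rmse <- sqrt(mean((df$An - pred)^2))

  # limitation crossover: Ac = Aj at
  # Cc* solving Vcmax*(4Cc+8G) = J*(Cc+Km)
  a <- 4 * vcmax - jmax
  trans <- if (abs(a) < 1e-12) Inf else
    (jmax * kin$Km - 8 * gs * vcmax) / a
  if (!is.finite(trans) || trans <= gs) trans <- NA_real_
  ac_pts <- sum(df$Cc < ifelse(is.na(trans), Inf, trans))
  aj_pts <- nrow(df) - ac_pts
  vcmax_ident <- ac_pts >= 2
  jmax_ident <- aj_pts >= 2
  if (!jmax_ident) {
    warning("no points beyond the limitation transition; Jmax is ",
            "unidentifiable from this curve", call. = FALSE)
  }
  if (!vcmax_ident) {
    warning("no points below the limitation transition; Vcmax is ",
            "unidentifiable from this curve", call. = FALSE)
  }
  structure(
    list(Vcmax = vcmax, Jmax = jmax,
         Vcmax25 = normalize_25(vcmax, Tleaf_C, constants$Ea_Vcmax),
         Jmax25 = normalize_25(jmax, Tleaf_C, constants$Ea_Jmax),
         Amax = df$An[which.max(df$Cc)],
         Rd_used = rd_used, Rd_free = Rd_free, rmse = rmse,
         transition_Cc = trans, Gamma_star = gs, Tleaf_C = Tleaf_C,
         vcmax_identifiable = vcmax_ident,
         jmax_identifiable = jmax_ident,
         data = mutate(df, fitted = pred)),
    class = "fvcb_fit"
  )
}

#' @export
print.fvcb_fit <- function(x, ...) {
  cat("FvCB fit (A-Cc)\n")
  cat(sprintf("  Vcmax = %.2f (%.2f at 25C), Jmax = %.2f (%.2f at 25C)\n",
              x$Vcmax, x$Vcmax25, x$Jmax, x$Jmax25))
  cat(sprintf("  Rd = %.3f (%s), Amax = %.2f, rmse = %.4f\n",
              x$Rd_used, if (x$Rd_free) "fitted" else "fixed", x$Amax,
              x$rmse))
  cat(sprintf("  transition Cc = %s umol mol-1\n",
              ifelse(is.na(x$transition_Cc), "beyond data",
                     sprintf("%.1f", x$transition_Cc))))
  invisible(x)
}

#' @export
tidy.fvcb_fit <- function(x, ...) {
  tibble(term = c("Vcmax", "Jmax", "Vcmax25", "Jmax25", "Rd"),
         estimate = c(x$Vcmax, x$Jmax, x$Vcmax25, x$Jmax25, x$Rd_used))
}

#' @export
glance.fvcb_fit <- function(x, ...) {
  tibble(Vcmax = x$Vcmax, Jmax = x$Jmax, Vcmax25 = x$Vcmax25,
         Jmax25 = x$Jmax25, Amax = x$Amax, Rd_used = x$Rd_used,
         rmse = x$rmse, transition_Cc = x$transition_Cc,
         n = nrow(x$data))
}

#' @export
augment.fvcb_fit <- function(x, ...) {
  mutate(x$data, .resid = .data$An - .data$fitted)
}

#' Normalize a rate to 25 degrees C
#'
#' Inverse of the simple Arrhenius scaling:
#' `x25 = x / exp(Ea * (Tk - 298.15) / (298.15 * R * Tk))`. Identity at
#' 25 degC or `Ea = 0`.
#'
#' @param value Rate at `Tleaf_C`.
#' @param Tleaf_C Leaf temperature (degC), physical range 0-50.
#' @param Ea Activation energy (J mol-1).
#' @return Value at 25 degC.
#' @export
#' @examples
#' normalize_25(120, 35, 65330)
normalize_25 <- function(value, Tleaf_C, Ea) {
  stopifnot(all(Tleaf_C >= 0), all(Tleaf_C <= 50))
  value / exp(Ea * ((Tleaf_C + 273.15) - 298.15) /
                (298.15 * 8.314 * (Tleaf_C + 273.15)))
}
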
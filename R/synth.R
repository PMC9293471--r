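#' Ground-truth parameter set for the forward simulator
#'
#' Defines a virtual leaf: FvCB biochemistry (`Vcmax`, `Jmax`, `Rd`,
#' `Gamma_star`), diffusive pathway (`gm`, `gsw`), light harvesting
#' (`alpha_beta`, curvature `theta`), cuticular water conductance `Ec`,
#' and instrument noise levels. The implied intercellular
#' photo-compensation point is `Ci_star = Gamma_star - Rd / gm`.
#' Default magnitudes represent a well-watered rice flag leaf measured
#' at saturating light; default noise levels are instrument-scale
#' (sigma_A = 0.3 umol m-2 s-1 on assimilation, sigma_phi = 0.005 on
#' PhiPSII, sigma_gsw = 0.01 mol m-2 s-1).
#'
#' @param gm Mesophyll conductance (mol CO2 m-2 s-1).
#' @param gsw Stomatal conductance to water vapor (mol H2O m-2 s-1).
#' @param Vcmax,Jmax,Rd FvCB parameters at leaf temperature
#'   (umol m-2 s-1).
#' @param Gamma_star Chloroplastic photo-compensation point at ambient
#'   (21 percent) O2 (umol mol-1).
#' @param alpha_beta Product of leaf absorbance and PSII partitioning.
#' @param theta Curvature of the electron-transport light response.
#' @param Ec Cuticular water conductance per leaf surface
#'   (mol H2O m-2 s-1).
#' @param Kc,Ko Michaelis constants at leaf temperature (umol mol-1,
#'   mmol mol-1).
#' @param Tleaf_C Leaf temperature (degC).
#' @param sigma_A,sigma_phi,sigma_gsw Gaussian noise SDs on An, PhiPSII
#'   and gsw.
#' @return A list of class `truth_params` with an added derived
#'   `Ci_star`.
#' @export
#' @examples
#' truth_params(gm = 0.3)
truth_params <- function(gm = 0.3, gsw = 0.3, Vcmax = 100, Jmax = 180,
                         Rd = 1, Gamma_star = 40, alpha_beta = 0.45,
                         theta = 0.7, Ec = 0.005,
                         Kc = 404.9, Ko = 278.4, Tleaf_C = 25,
                         sigma_A = 0.3, sigma_phi = 0.005,
                         sigma_gsw = 0.01) {
  pos <- c(gm = gm, gsw = gsw, Vcmax = Vcmax, Jmax = Jmax, Rd = Rd,
           Gamma_star = Gamma_star, alpha_beta = alpha_beta,
           theta = theta, Ec = Ec, Kc = Kc, Ko = Ko)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("all truth parameters must be positive and finite",
         call. = FALSE)
  }
  if (any(c(sigma_A, sigma_phi, sigma_gsw) < 0)) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  structure(
    list(gm = gm, gsw = gsw, Vcmax = Vcmax, Jmax = Jmax, Rd = Rd,
         Gamma_star = Gamma_star, Ci_star = Gamma_star - Rd / gm,
         alpha_beta = alpha_beta, theta = theta, Ec = Ec,
         Kc = Kc, Ko = Ko, Tleaf_C = Tleaf_C,
         sigma_A = sigma_A, sigma_phi = sigma_phi,
         sigma_gsw = sigma_gsw),
    class = "truth_params"
  )
}

# potential electron transport from the non-rectangular hyperbola
.j_light <- function(PPFD, params) {
  q <- params$alpha_beta * PPFD
  jm <- params$Jmax
  th <- params$theta
  (q + jm - sqrt((q + jm)^2 - 4 * th * q * jm)) / (2 * th)
}

# effective photo-compensation point at a given O2 fraction; low-O2
# measurements are treated as ideally non-photorespiratory, which is
# the assumption the PhiPSII~PhiCO2 calibration itself relies on
.gamma_at_o2 <- function(params, O2_frac, o2_free = 0.02) {
  if (O2_frac <= o2_free) 0 else params$Gamma_star * (O2_frac / 0.21)
}

#' Forward-simulate one gas-exchange + fluorescence observation
#'
#' Solves the coupled supply-demand system
#' `An = FvCB(Cc)`, `Cc = Ci - An / gm`, `Ci = Ca - An / gsc` (with
#' `gsc = gsw / 1.6`) by bracketed root finding, then constructs every
#' observable an LI-6800-style record carries. The fluorescence-derived
#' electron transport equals the actual electron consumption (under
#' RuBP-regeneration limitation this is the light-driven J; under
#' Rubisco limitation it is the rate consumed by carboxylation plus
#' photorespiration), so the variable-J inversion is exact on noise-free
#' output. Transpiration observables are constructed so the cuticular Ci
#' correction is an exact inverse: `Wi - Wa = 0.02` and
#' `El = (gsw + 2 Ec) * (Wi - Wa)`; the recorded `gsw` is the
#' instrument-style total water conductance `El / (Wi - Wa)`, and
#' `Ci_raw` is the uncorrected value implied by it.
#'
#' @param Ca Ambient CO2 (umol mol-1).
#' @param PPFD Photon flux (umol m-2 s-1).
#' @param params A [truth_params()] object.
#' @param O2_frac Oxygen mole fraction (0.21 ambient, 0.01 for
#'   non-photorespiratory calibration; at or below 0.02 the simulated
#'   leaf is fully non-photorespiratory).
#' @param noise Apply the parameter set's Gaussian noise (`TRUE`) or
#'   generate noise-free (`FALSE`).
#' @return One-row tibble with canonical record fields plus ground
#'   truth columns `true_Ci`, `true_Cc`, `true_J`, `true_gm`,
#'   `true_gsw`, `true_An`.
#' @export
#' @examples
#' simulate_point(Ca = 400, PPFD = 1500, params = truth_params(),
#'                noise = FALSE)
simulate_point <- function(Ca, PPFD, params = truth_params(),
                           O2_frac = 0.21, noise = TRUE) {
  stopifnot(inherits(params, "truth_params"), Ca > 0, PPFD >= 0)
  gs_eff <- .gamma_at_o2(params, O2_frac)
  O_mmol <- O2_frac * 1000
  Km <- params$Kc * (1 + O_mmol / params$Ko)
  J_pot <- .j_light(PPFD, params)
  gsc <- params$gsw / 1.6
  transfer <- 1 / gsc + 1 / params$gm # umol mol-1 per umol m-2 s-1

  demand <- function(Cc) {
    Ac <- params$Vcmax * (Cc - gs_eff) / (Cc + Km)
    Aj <- J_pot * (Cc - gs_eff) / (4 * Cc + 8 * gs_eff)
    pmin(Ac, Aj) - params$Rd
  }
  resid <- function(An) demand(Ca - An * transfer) - An
  lower <- -params$Rd - 2
  upper <- min(params$Vcmax, J_pot / 4, Ca / transfer) - 1e-9
  if (resid(lower) < 0 || resid(upper) > 0) {
    stop("no admissible root for An in [", format(lower), ", ",
         format(upper), "] at Ca = ", Ca, ", PPFD = ", PPFD,
         "; residuals ", format(resid(lower)), " / ",
         format(resid(upper)), call. = FALSE)
  }
  An <- uniroot(resid, c(lower, upper), tol = 1e-12)$root
  Ci <- Ca - An / gsc
  Cc <- Ci - An / params$gm

  Ac <- params$Vcmax * (Cc - gs_eff) / (Cc + Km)
  Aj <- J_pot * (Cc - gs_eff) / (4 * Cc + 8 * gs_eff)
  J_fluor <- if (Aj <= Ac) {
    J_pot
  } else {
    4 * (An + params$Rd) * (Cc + 2 * gs_eff) / (Cc - gs_eff)
  }
  phi <- J_fluor / (PPFD * params$alpha_beta)

  gsw_obs <- params$gsw
  An_obs <- An
  phi_obs <- phi
  if (noise) {
    An_obs <- An + rnorm(1, 0, params$sigma_A)
    phi_obs <- min(max(phi + rnorm(1, 0, params$sigma_phi), 1e-4),
                   0.999)
    gsw_obs <- max(params$gsw + rnorm(1, 0, params$sigma_gsw), 1e-4)
  }
  dW <- 0.02
  Wa <- 0.012
  El <- (gsw_obs + 2 * params$Ec) * dW
  gsw_inst <- El / dW # total water conductance the instrument reports
  Ci_raw <- Ca - 1.6 * An_obs / gsw_inst
  Fm_prime <- 2000
  tibble(
    An = An_obs, Ca = Ca, Ci_raw = Ci_raw, gsw = gsw_inst, El = El,
    Wi = Wa + dW, Wa = Wa, PPFD = PPFD, Tleaf_C = params$Tleaf_C,
    O2_frac = O2_frac, Ft = Fm_prime * (1 - phi_obs),
    Fm_prime = Fm_prime,
    true_An = An, true_Ci = Ci, true_Cc = Cc, true_J = J_fluor,
    true_gm = params$gm, true_gsw = params$gsw
  )
}

#' Simulate a CO2-response curve
#'
#' Runs [simulate_point()] over a sequence of ambient CO2 steps at
#' fixed light. The default sequence is the instrument protocol used
#' for combined gas-exchange/fluorescence curves: start at 400, step
#' down to 50, return to 400, step up to 1600 umol mol-1.
#'
#' @param params A [truth_params()] object.
#' @param Ca_steps Ambient CO2 sequence (umol mol-1).
#' @param PPFD Photon flux (umol m-2 s-1).
#' @param O2_frac Oxygen fraction.
#' @param noise Apply measurement noise.
#' @param curve_id Label stored in the `curve_id` column.
#' @return Tibble, one row per step, in protocol order.
#' @export
simulate_aci_curve <- function(params = truth_params(),
                               Ca_steps = c(400, 300, 200, 150, 100, 50,
                                            400, 600, 800, 1000, 1200,
                                            1600),
                               PPFD = 1500, O2_frac = 0.21,
                               noise = TRUE, curve_id = "aci") {
  out <- purrr::map(Ca_steps, simulate_point, PPFD = PPFD,
                    params = params, O2_frac = O2_frac, noise = noise)
  mutate(bind_rows(out), curve_id = curve_id)
}

#' Simulate low-Ci curves for Laisk estimation
#'
#' Generates the low-CO2 portion of the A-Ci response at several
#' sub-saturating irradiances. By default (`shape = "linear"`) each
#' curve is the idealized linear regime the Laisk estimator assumes: a
#' straight line through the common point `(Ci*, -Rd)` whose slope is
#' the FvCB tangent at that point for that irradiance
#' (`dAn/dCc = J/(12 Gamma*)` under RuBP-regeneration limitation,
#' attenuated by the finite mesophyll conductance). `shape = "fvcb"`
#' instead runs the full curved forward model, which exposes the
#' curvature bias of fitting straight lines to a saturating response.
#'
#' @param params A [truth_params()] object.
#' @param Ca_steps Low ambient CO2 steps (umol mol-1).
#' @param PPFD_levels Irradiances (umol m-2 s-1).
#' @param shape `"linear"` (estimator-consistent) or `"fvcb"` (curved).
#' @param noise Apply `sigma_A` noise to An.
#' @return Tibble with columns `Ci`, `An`, `PPFD`, `Ca`, `curve_id`.
#' @export
simulate_laisk_curves <- function(params = truth_params(),
                                  Ca_steps = c(50, 75, 100, 125, 150),
                                  PPFD_levels = c(100, 200, 400),
                                  shape = c("linear", "fvcb"),
                                  noise = TRUE) {
  shape <- match.arg(shape)
  stopifnot(length(PPFD_levels) >= 2,
            length(unique(PPFD_levels)) == length(PPFD_levels))
  gsc <- params$gsw / 1.6
  rows <- purrr::map(PPFD_levels, function(q) {
    if (shape == "linear") {
      J <- .j_light(q, params)
      a <- J / (12 * params$Gamma_star) # dAn/dCc at the common point
      s <- a / (1 + a / params$gm)      # tangent slope in Ci space
      An <- (-params$Rd + s * (Ca_steps - params$Ci_star)) /
        (1 + s / gsc)
      Ci <- Ca_steps - An / gsc
      tibble(Ca = Ca_steps, Ci = Ci, An = An, PPFD = q)
    } else {
      pts <- purrr::map(Ca_steps, simulate_point, PPFD = q,
                        params = params, O2_frac = 0.21, noise = FALSE)
      pts <- bind_rows(pts)
      tibble(Ca = pts$Ca, Ci = pts$true_Ci, An = pts$true_An, PPFD = q)
    }
  })
  out <- bind_rows(rows)
  if (noise && params$sigma_A > 0) {
    out$An <- out$An + rnorm(nrow(out), 0, params$sigma_A)
  }
  mutate(out, curve_id = paste0("laisk_q", .data$PPFD))
}

#' Simulate a non-photorespiratory calibration curve
#'
#' Light-response measurements at 1 percent O2 spanning the linear
#' PhiPSII-PhiCO2 region used to calibrate electron transport.
#'
#' @param params A [truth_params()] object.
#' @param PPFD_levels Irradiances (umol m-2 s-1).
#' @param Ca Ambient CO2 (umol mol-1).
#' @param noise Apply measurement noise.
#' @return Tibble of records at `O2_frac = 0.01`.
#' @export
simulate_o2_calibration_curve <- function(params = truth_params(),
                                          PPFD_levels = c(100, 150, 200,
                                                          300, 400, 600,
                                                          800, 1000,
                                                          1200, 1500),
                                          Ca = 400, noise = TRUE) {
  out <- purrr::map(PPFD_levels, function(q) {
    simulate_point(Ca = Ca, PPFD = q, params = params,
                   O2_frac = 0.01, noise = noise)
  })
  mutate(bind_rows(out), curve_id = "o2_cal")
}

#' Simulate a full drought study
#'
#' Generates the complete fixture bundle for the drought pipeline: one
#' survey record per plant per day at ambient CO2 along a progressive
#' soil drydown, plus per-genotype calibration, low-Ci and anatomy
#' inputs, and daily pot weights. The drydown emulates a 20-day pot
#' experiment: relative soil water content (RSWC) declines linearly
#' from 100 percent, crossing the severe-drought boundary (35 percent)
#' around day 19. Stomata close with soil drying (gsw scales with
#' RSWC/50 below RSWC = 50, with a floor of 5 percent of the
#' well-watered value) and gm declines more gently (40 percent floor),
#' so genotype gm ratios propagate through every drought stage.
#'
#' @param genotype_params Named list of [truth_params()], one per
#'   genotype.
#' @param anatomy Tibble of per-genotype anatomy (columns `genotype`,
#'   `Tleaf`, `f_ias`, `Sm`, `Sc`, `Tcw`, `Tcyt`, `Tchl`); defaults to
#'   [rice_anatomy_means()] rows matched by position.
#' @param n_plants Plants per genotype.
#' @param days Measurement days (day 0 = start of drydown).
#' @param rswc_day0,rswc_decline RSWC (%) on day 0 and its daily
#'   decline. Lysimetric RSWC is 100 on day 0 by construction (the
#'   day-0 pot weight is its own reference), so `rswc_day0` defaults
#'   to 100.
#' @param pot_dry_weight,pot_day0_weight Pot weights (kg) defining the
#'   lysimetry.
#' @param noise Apply measurement noise.
#' @return List of class `synth_study`: `gasex`, `lowci`, `o2_cal`,
#'   `pot_weights`, `anatomy`, `truth` (the input parameter sets plus
#'   drydown settings).
#' @export
simulate_study <- function(genotype_params = list(
                             WT = truth_params(gm = 0.25, gsw = 0.28),
                             d1 = truth_params(gm = 0.35, gsw = 0.33)),
                           anatomy = NULL,
                           n_plants = 5, days = 0:20,
                           rswc_day0 = 100, rswc_decline = 3.5,
                           pot_dry_weight = 4, pot_day0_weight = 10,
                           noise = TRUE) {
  stopifnot(length(genotype_params) >= 1,
            !is.null(names(genotype_params)))
  genos <- names(genotype_params)
  if (is.null(anatomy)) {
    anatomy <- rice_anatomy_means()
    anatomy <- anatomy[rep_len(seq_len(nrow(anatomy)), length(genos)), ]
    anatomy$genotype <- genos
  }
  rswc <- pmax(rswc_day0 - rswc_decline * days, 5)
  # stress multipliers applied to gsw and gm below RSWC = 50%
  f_gs <- pmax(pmin(rswc / 50, 1), 0.05)
  f_gm <- 0.4 + 0.6 * pmax(pmin(rswc / 50, 1), 0)

  gasex <- purrr::map(genos, function(g) {
    p0 <- genotype_params[[g]]
    purrr::map(seq_len(n_plants), function(pl) {
      purrr::map(seq_along(days), function(d) {
        p <- p0
        p$gsw <- p0$gsw * f_gs[d]
        p$gm <- p0$gm * f_gm[d]
        p$Ci_star <- p$Gamma_star - p$Rd / p$gm
        rec <- simulate_point(Ca = 400, PPFD = 1500, params = p,
                              noise = noise)
        mutate(rec, genotype = g, plant_id = paste0(g, "_", pl),
               day = days[d], rswc = rswc[d], curve_id = "survey")
      }) %>% bind_rows()
    }) %>% bind_rows()
  }) %>% bind_rows()

  lowci <- purrr::map(genos, function(g) {
    mutate(simulate_laisk_curves(genotype_params[[g]], noise = noise),
           genotype = g)
  }) %>% bind_rows()
  o2_cal <- purrr::map(genos, function(g) {
    mutate(simulate_o2_calibration_curve(genotype_params[[g]],
                                         noise = noise),
           genotype = g)
  }) %>% bind_rows()

  span <- pot_day0_weight - pot_dry_weight
  pot_weights <- tidyr::crossing(
    genotype = genos, plant = seq_len(n_plants),
    tibble(day = days, rswc = rswc)
  ) %>%
    mutate(PW = pot_dry_weight + span * .data$rswc / 100,
           DW = pot_dry_weight, t0W = pot_dry_weight + span *
             rswc_day0 / 100,
           plant_id = paste0(.data$genotype, "_", .data$plant)) %>%
    select("genotype", "plant_id", "day", "PW", "DW", "t0W")

  structure(
    list(gasex = gasex, lowci = lowci, o2_cal = o2_cal,
         pot_weights = pot_weights, anatomy = as_tibble(anatomy),
         truth = list(genotype_params = genotype_params,
                      rswc_day0 = rswc_day0,
                      rswc_decline = rswc_decline,
                      f_gs = f_gs, f_gm = f_gm, days = days)),
    class = "synth_study"
  )
}

#' Genotype-mean leaf anatomy of well-watered rice
#'
#' Mean structural traits of the wild-type Taichung 65 cultivar and its
#' Galpha-null `d1` mutant measured on TEM cross-sections of
#' well-watered flag leaves: leaf thickness, mesophyll (`Sm`) and
#' chloroplast (`Sc`) surface exposed to intercellular air space per
#' leaf area, cell wall thickness, cytosol path length, chloroplast
#' length and thickness. The air-space fraction is not part of the
#' published trait table; a typical rice value of 0.3 is supplied for
#' both genotypes (it does not affect liquid-phase comparisons).
#'
#' @return Tibble with one row per genotype.
#' @export
#' @examples
#' rice_anatomy_means()
rice_anatomy_means <- function() {
  tibble(
    genotype = c("T65", "d1"),
    Tleaf = c(68.5, 74.9), LMA = c(62.9, 66.5),
    Sm = c(17.5, 22.5), Sc = c(13.9, 19.5),
    Tcw = c(0.128, 0.106), Tcyt = c(0.05, 0.03),
    Lchl = c(4.3, 4.6), Tchl = c(2.6, 1.48),
    f_ias = c(0.3, 0.3)
  )
}
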
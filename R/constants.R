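#' Rubisco kinetic constants and activation energies
#'
#' Bundles the temperature-dependent Rubisco kinetics used by the FvCB
#' model: Michaelis constants for carboxylation (`Kc`) and oxygenation
#' (`Ko`), the chloroplastic CO2 photo-compensation point `Gamma_star`,
#' and Arrhenius activation energies for each plus `Vcmax` and `Jmax`.
#' Defaults follow the Bernacchi parameterization widely used for C3
#' leaves; every value can be overridden.
#'
#' @param Kc25 Michaelis constant for CO2 at 25 degC (umol mol-1).
#' @param Ko25 Michaelis constant for O2 at 25 degC (mmol mol-1).
#' @param Gamma_star25 Photo-compensation point at 25 degC (umol mol-1).
#' @param Ea_Kc,Ea_Ko,Ea_Gamma_star,Ea_Vcmax,Ea_Jmax Activation energies
#'   (J mol-1).
#' @param O Oxygen mole fraction seen by Rubisco (mmol mol-1); 210 for
#'   ambient air, 10 for the 1 percent O2 used in non-photorespiratory
#'   calibration.
#'
#' @return A list of class `kinetic_constants`.
#' @export
#' @examples
#' kinetic_constants()
#' kinetic_constants(O = 10) # 1% O2
kinetic_constants <- function(Kc25 = 404.9, Ko25 = 278.4,
                              Gamma_star25 = 42.75,
                              Ea_Kc = 79430, Ea_Ko = 36380,
                              Ea_Gamma_star = 37830,
                              Ea_Vcmax = 65330, Ea_Jmax = 43540,
                              O = 210) {
  stopifnot(Kc25 > 0, Ko25 > 0, Gamma_star25 > 0, O > 0)
  structure(
    list(Kc25 = Kc25, Ko25 = Ko25, Gamma_star25 = Gamma_star25,
         Ea_Kc = Ea_Kc, Ea_Ko = Ea_Ko, Ea_Gamma_star = Ea_Gamma_star,
         Ea_Vcmax = Ea_Vcmax, Ea_Jmax = Ea_Jmax, O = O),
    class = "kinetic_constants"
  )
}

#' Arrhenius temperature scaling
#'
#' Scales a rate or constant from 25 degC to leaf temperature with the
#' simple (non-peaked) Arrhenius function
#' `x(T) = x25 * exp(Ea * (Tk - 298.15) / (298.15 * R * Tk))`.
#'
#' @param x25 Value at 25 degC.
#' @param Tleaf_C Leaf temperature (degC).
#' @param Ea Activation energy (J mol-1).
#' @return Value at `Tleaf_C`.
#' @export
arrhenius <- function(x25, Tleaf_C, Ea) {
  Tk <- Tleaf_C + 273.15
  x25 * exp(Ea * (Tk - 298.15) / (298.15 * 8.314 * Tk))
}

#' Kinetic constants evaluated at leaf temperature
#'
#' @param constants A [kinetic_constants()] object.
#' @param Tleaf_C Leaf temperature (degC).
#' @return A list with `Kc`, `Ko`, `Gamma_star`, `Km` (effective
#'   Michaelis constant `Kc * (1 + O/Ko)`) and `O` at `Tleaf_C`. `Kc` and
#'   `Km` are in umol mol-1, `Ko` in mmol mol-1.
#' @export
kinetics_at <- function(constants, Tleaf_C) {
  stopifnot(inherits(constants, "kinetic_constants"))
  Kc <- arrhenius(constants$Kc25, Tleaf_C, constants$Ea_Kc)
  Ko <- arrhenius(constants$Ko25, Tleaf_C, constants$Ea_Ko)
  Gs <- arrhenius(constants$Gamma_star25, Tleaf_C, constants$Ea_Gamma_star)
  list(Kc = Kc, Ko = Ko, Gamma_star = Gs,
       Km = Kc * (1 + constants$O / Ko), O = constants$O)
}

#' Physical constants of the one-dimensional CO2 diffusion model
#'
#' Diffusivities, porosities, diffusive-reduction factors, membrane
#' permeabilities and the gas/liquid partition constants used to model
#' mesophyll conductance from anatomy. Defaults are the values used for
#' rice mesophyll at 25 degC: CO2 diffusivity in air `Da` = 1.51e-4 m2
#' s-1 and in water `Dw` = 1.79e-9 m2 s-1, gas-path tortuosity `tau` =
#' 1.57 (dimensionless), cell-wall porosity 0.3 with no diffusive
#' reduction, unit porosity for cytosol and stroma with diffusive
#' reduction factor 0.3, and plasma-membrane / chloroplast-envelope
#' permeabilities of 0.0035 m s-1 each.
#'
#' @param Da CO2 diffusivity in air (m2 s-1).
#' @param Dw CO2 diffusivity in liquid water (m2 s-1).
#' @param tau Tortuosity of the gas diffusion path (dimensionless).
#' @param p_cw,p_cyt,p_st Effective porosities (m3 m-3) of cell wall,
#'   cytosol and stroma.
#' @param rf_cw,rf_cyt,rf_st Diffusive reduction factors (dimensionless)
#'   accounting for solutes and macromolecules.
#' @param g_pl,g_env Plasma-membrane and chloroplast-envelope CO2
#'   permeabilities (m s-1).
#' @param H Henry's law constant for CO2 (Pa m3 mol-1).
#' @param Tk Absolute temperature (K).
#' @param pressure Ambient pressure (Pa), used to convert conductances
#'   from m s-1 to mol m-2 s-1.
#'
#' @return A list of class `diffusion_constants`.
#' @export
#' @examples
#' diffusion_constants()
diffusion_constants <- function(Da = 1.51e-4, Dw = 1.79e-9, tau = 1.57,
                                p_cw = 0.3, p_cyt = 1, p_st = 1,
                                rf_cw = 1, rf_cyt = 0.3, rf_st = 0.3,
                                g_pl = 0.0035, g_env = 0.0035,
                                H = 2941, Tk = 298.15,
                                pressure = 101325) {
  vals <- c(Da = Da, Dw = Dw, tau = tau, p_cw = p_cw, p_cyt = p_cyt,
            p_st = p_st, rf_cw = rf_cw, rf_cyt = rf_cyt, rf_st = rf_st,
            g_pl = g_pl, g_env = g_env, H = H, Tk = Tk,
            pressure = pressure)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all diffusion constants must be positive and finite",
         call. = FALSE)
  }
  if (any(c(p_cw, p_cyt, p_st, rf_cw, rf_cyt, rf_st) > 1)) {
    stop("porosities and diffusive reduction factors must lie in (0, 1]",
         call. = FALSE)
  }
  structure(as.list(vals), class = "diffusion_constants")
}

# molar (mol m-2 s-1) equivalent of a conductance in m s-1 at P, Tk
.to_molar <- function(g_ms, const) {
  g_ms * const$pressure / (8.314 * const$Tk)
}
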
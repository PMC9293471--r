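#' Surface area per unit leaf area from a traced perimeter
#'
#' Converts a perimeter traced on a leaf cross-section into surface area
#' exposed to intercellular air space per unit leaf area:
#' `S = (l / W) * 1.42`, the factor correcting for the ellipsoidal shape
#' of mesophyll cells. Used for both the mesophyll (`Sm`) and
#' chloroplast (`Sc`) surfaces.
#'
#' @param l Total traced perimeter facing the intercellular air space
#'   (um).
#' @param W Width of the analyzed cross-section (um).
#' @param curvature Curvature correction factor, default 1.42.
#' @return S (m2 m-2). Vectorised.
#' @export
#' @examples
#' surface_per_area(l = 1232, W = 100) # ~17.5, a typical rice Sm
surface_per_area <- function(l, W, curvature = 1.42) {
  if (any(!is.finite(W) | W <= 0)) {
    stop("section width W must be positive", call. = FALSE)
  }
  if (any(!is.finite(l) | l <= 0)) {
    stop("traced perimeter l must be positive", call. = FALSE)
  }
  (l / W) * curvature
}

#' Intercellular air space fraction
#'
#' `f_ias = S_ias / (S_mes + S_ias)` on cross-sectional areas.
#'
#' @param S_ias Cross-sectional area of intercellular air space.
#' @param S_mes Cross-sectional area of mesophyll tissue.
#' @return f_ias in `[0, 1)`. Vectorised.
#' @export
ias_fraction <- function(S_ias, S_mes) {
  if (any(S_ias < 0 | S_mes < 0)) {
    stop("areas must be non-negative", call. = FALSE)
  }
  if (any(S_ias + S_mes == 0)) {
    stop("S_ias and S_mes cannot both be zero", call. = FALSE)
  }
  S_ias / (S_mes + S_ias)
}

#' Gas-phase CO2 conductance through intercellular air spaces
#'
#' `g_ias = Da * f_ias / (dL_ias * tau)` where the effective gas path
#' `dL_ias` is half the mesophyll thickness (approximated by half the
#' leaf thickness).
#'
#' @param f_ias Air space fraction, in (0, 1).
#' @param Tleaf_um Leaf thickness (um).
#' @param const [diffusion_constants()].
#' @return List with `g_ias_ms` (m s-1) and `g_ias_mol` (mol m-2 s-1).
#' @export
#' @examples
#' gas_phase_conductance(f_ias = 0.3, Tleaf_um = 68.5)
gas_phase_conductance <- function(f_ias, Tleaf_um,
                                  const = diffusion_constants()) {
  stopifnot(all(f_ias > 0), all(f_ias < 1), all(Tleaf_um > 0))
  dL <- Tleaf_um * 1e-6 / 2
  g <- const$Da * f_ias / (dL * const$tau)
  list(g_ias_ms = g, g_ias_mol = .to_molar(g, const))
}

#' Liquid-phase component conductance
#'
#' Generic per-surface liquid conductance `g_i = Dw * rf * p / dL` for a
#' diffusion path of length `dL` with effective porosity `p` and
#' diffusive reduction factor `rf`.
#'
#' @param dL_um Diffusion path length (um).
#' @param rf Diffusive reduction factor (dimensionless).
#' @param p Effective porosity (m3 m-3).
#' @param Dw CO2 diffusivity in water (m2 s-1).
#' @return Conductance (m s-1). Vectorised.
#' @export
#' @examples
#' liquid_component_conductance(dL_um = 0.128, rf = 1, p = 0.3)
liquid_component_conductance <- function(dL_um, rf = 1, p = 1,
                                         Dw = 1.79e-9) {
  if (any(!is.finite(dL_um) | dL_um <= 0)) {
    stop("path length dL must be positive", call. = FALSE)
  }
  Dw * rf * p / (dL_um * 1e-6)
}

#' One-dimensional anatomical model of mesophyll conductance
#'
#' Serial-resistance model of CO2 transfer from the substomatal cavity
#' to the chloroplast stroma. The gas phase crosses the intercellular
#' air space (`g_ias`); the liquid phase crosses, in series, the cell
#' wall, plasma membrane, cytosol, chloroplast envelope and stroma.
#' Per-surface conductances (m s-1): wall `Dw*rf_cw*p_cw/Tcw`, membrane
#' and envelope fixed permeabilities, cytosol `Dw*rf_cyt*p_cyt/Tcyt`,
#' stroma `Dw*rf_st*p_st/(Tchl/2)`. Each per-surface resistance is
#' scaled to leaf area by the surface through which it acts: wall and
#' plasma membrane by `Sm`, cytosol, envelope and stroma by `Sc`. The
#' composite is `gm = 1 / (1/g_ias + (R*Tk/H) / g_liq)` where `R*Tk/H`
#' converts liquid-phase conductance to its gas-phase equivalent.
#'
#' @param anatomy One-row data frame (or list) with `Tleaf` (um),
#'   `f_ias` (0-1), `Sm`, `Sc` (m2 m-2), `Tcw`, `Tcyt`, `Tchl` (um);
#'   optionally `genotype`.
#' @param const [diffusion_constants()].
#' @return Object of class `anat_gm`: per-surface conductances (m s-1),
#'   per-leaf-area resistances (s m-1) with their shares, `g_liq`,
#'   `g_ias` and composite `gm_model` (mol m-2 s-1).
#' @export
#' @examples
#' wt <- tibble::tibble(Tleaf = 68.5, f_ias = 0.3, Sm = 17.5, Sc = 13.9,
#'                      Tcw = 0.128, Tcyt = 0.05, Tchl = 2.6)
#' compose_gm(wt)
compose_gm <- function(anatomy, const = diffusion_constants()) {
  a <- as.list(anatomy)
  need <- c("Tleaf", "f_ias", "Sm", "Sc", "Tcw", "Tcyt", "Tchl")
  missing <- setdiff(need, names(a))
  if (length(missing) > 0) {
    stop("anatomy lacks field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (f in need) {
    if (length(a[[f]]) != 1 || !is.finite(a[[f]]) || a[[f]] <= 0) {
      stop("anatomy field '", f, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (a$Sc > a$Sm) {
    stop("Sc cannot exceed Sm (chloroplast surface bounded by ",
         "mesophyll surface)", call. = FALSE)
  }
  if (a$f_ias >= 1) stop("f_ias must be below 1", call. = FALSE)

  gas <- gas_phase_conductance(a$f_ias, a$Tleaf, const)

  # per-surface conductances, m s-1
  g_cw <- liquid_component_conductance(a$Tcw, const$rf_cw, const$p_cw,
                                       const$Dw)
  g_cyt <- liquid_component_conductance(a$Tcyt, const$rf_cyt,
                                        const$p_cyt, const$Dw)
  g_st <- liquid_component_conductance(a$Tchl / 2, const$rf_st,
                                       const$p_st, const$Dw)
  g_pl <- const$g_pl
  g_env <- const$g_env

  # per-leaf-area resistances: wall + membrane act over Sm,
  # intracellular components over Sc
  r_leaf <- c(cw = 1 / (g_cw * a$Sm),
              pl = 1 / (g_pl * a$Sm),
              cyt = 1 / (g_cyt * a$Sc),
              env = 1 / (g_env * a$Sc),
              st = 1 / (g_st * a$Sc))
  r_liq <- sum(r_leaf)
  g_liq <- 1 / r_liq # m s-1 per unit leaf area

  partition <- 8.314 * const$Tk / const$H
  gm_ms <- 1 / (1 / gas$g_ias_ms + partition / g_liq)
  structure(
    list(genotype = a$genotype %||% NA_character_,
         anatomy = as_tibble(a[intersect(c("genotype", need),
                                         names(a))]),
         g_ias_ms = gas$g_ias_ms, g_ias_mol = gas$g_ias_mol,
         g_surface_ms = c(cw = g_cw, pl = g_pl, cyt = g_cyt,
                          env = g_env, st = g_st),
         r_leaf = r_leaf, r_share = r_leaf / r_liq,
         r_liq = r_liq, g_liq_ms = g_liq,
         g_liq_mol = .to_molar(g_liq, const),
         gm_model_ms = gm_ms, gm_model = .to_molar(gm_ms, const),
         const = const),
    class = "anat_gm"
  )
}

#' @export
print.anat_gm <- function(x, ...) {
  cat("Anatomical (1-D serial resistance) mesophyll conductance\n")
  if (!is.na(x$genotype)) cat("  genotype:", x$genotype, "\n")
  cat(sprintf("  g_ias = %.4f m s-1 (%.2f mol m-2 s-1)\n",
              x$g_ias_ms, x$g_ias_mol))
  cat(sprintf("  g_liq = %.5f m s-1 per leaf area; r_liq = %.1f s m-1\n",
              x$g_liq_ms, x$r_liq))
  cat("  resistance shares:",
      paste(sprintf("%s %.1f%%", names(x$r_share), 100 * x$r_share),
            collapse = ", "), "\n")
  cat(sprintf("  modeled gm = %.4f mol m-2 s-1\n", x$gm_model))
  invisible(x)
}

#' @export
tidy.anat_gm <- function(x, ...) {
  tibble(component = names(x$r_leaf),
         g_surface_ms = unname(x$g_surface_ms),
         r_leaf = unname(x$r_leaf),
         r_share = unname(x$r_share))
}

#' @export
glance.anat_gm <- function(x, ...) {
  tibble(genotype = x$genotype, g_ias_mol = x$g_ias_mol,
         g_liq_mol = x$g_liq_mol, r_liq = x$r_liq,
         gm_model = x$gm_model)
}

#' Compare modeled resistances between two genotypes
#'
#' Percent reduction `100 * (1 - r_B / r_A)` for each diffusion
#' component and the liquid-phase total, reported both per unit exposed
#' surface (path-length differences only) and per unit leaf area
#' (additionally reflecting Sm/Sc differences). Positive values mean B
#' has lower resistance than A.
#'
#' @param resultA,resultB `anat_gm` objects built with the same
#'   constants (checked).
#' @return Tibble: `component`, `reduction_per_surface_pct`,
#'   `reduction_per_leaf_area_pct`; components `cw`, `pl`, `cyt`, `env`,
#'   `st` and `liquid_total` (per-leaf-area only).
#' @export
compare_genotypes <- function(resultA, resultB) {
  stopifnot(inherits(resultA, "anat_gm"), inherits(resultB, "anat_gm"))
  if (!isTRUE(all.equal(resultA$const, resultB$const))) {
    stop("results were built with different diffusion constants",
         call. = FALSE)
  }
  comp <- names(resultA$r_leaf)
  per_surface <- 100 * (1 - (1 / resultB$g_surface_ms[comp]) /
                          (1 / resultA$g_surface_ms[comp]))
  per_leaf <- 100 * (1 - resultB$r_leaf[comp] / resultA$r_leaf[comp])
  dplyr::bind_rows(
    tibble(component = comp,
           reduction_per_surface_pct = unname(per_surface),
           reduction_per_leaf_area_pct = unname(per_leaf)),
    tibble(component = "liquid_total",
           reduction_per_surface_pct = NA_real_,
           reduction_per_leaf_area_pct =
             100 * (1 - resultB$r_liq / resultA$r_liq))
  )
}
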
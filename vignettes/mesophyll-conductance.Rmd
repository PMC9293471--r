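---
title: "Estimating mesophyll conductance from gas exchange, fluorescence and anatomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mesophyll conductance from gas exchange, fluorescence and anatomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesocond)
library(dplyr)
```

## The problem

Net CO2 assimilation in a C3 leaf is limited not only by stomata but by
the diffusion path from the intercellular air spaces to the chloroplast
stroma — across the cell wall, plasma membrane, cytosol, chloroplast
envelope and stroma. The aggregate conductance of that path, the
mesophyll conductance

$$g_m = \frac{A_n}{C_i - C_c},$$

cannot be measured directly because the chloroplastic CO2 mole fraction
$C_c$ is not observable by gas exchange alone. `mesocond` implements the
standard fluorescence-assisted workflow for estimating $g_m$ on
LI-6800-style records, a one-dimensional anatomical model that predicts
$g_m$ from leaf ultrastructure, and a forward simulator that generates
records with known ground truth so every estimator in the package is
validated by parameter recovery. The motivating application is the
comparison of rice wild-type and G-protein alpha-subunit null (*d1*)
genotypes along a pot drydown.

## The variable-J chain

The chain has four stages, each its own function so intermediate
results stay inspectable.

**1. Electron-transport calibration** (`calibrate_etr()`). Under
non-photorespiratory conditions (1% O2) CO2 fixation is the only
electron sink, so the PSII operating yield
$\Phi_{PSII} = (F_m' - F_t)/F_m'$ is linear in the CO2 yield
$\Phi_{CO2} = (A_n + R_d)/\mathrm{PPFD}$. An OLS regression of
$\Phi_{PSII}$ on $\Phi_{CO2}$, restricted to the linear region
($\Phi_{CO2} < 0.05$, $\Phi_{PSII} < 0.5$), gives slope $k$ and
intercept $b$, and the calibrated electron transport at ambient O2 is

$$J_{cal} = \frac{4(\Phi_{PSII} - b)}{k}\,\mathrm{PPFD}.$$

The implied absorbance-partitioning product is $\alpha\beta = 4/k$. The
regression direction ($\Phi_{PSII}$ on $\Phi_{CO2}$, plain OLS) follows
the form in which $k$ enters $J_{cal}$. Calibration is per genotype; the
respiration used inside $\Phi_{CO2}$ is the Laisk estimate by default
(the two estimates come from separate measurements, so either ordering
is defensible; using one $R_d$ throughout keeps the chain consistent).

**2. Day respiration and the intercellular compensation point**
(`laisk()`). Low-CO2 response curves measured at several sub-saturating
irradiances are fitted linearly within a low-$C_i$ window (default
$C_i \le 150\,\mu$mol mol$^{-1}$, configurable; the measurements
themselves step ambient CO2 through 50–150 ppm). The three pairwise line
intersections are averaged: the mean $x$ is $C_i^*$ (intercellular
photo-compensation point), the mean $-y$ is $R_d$ (stored positive). We
average pairwise intersection points rather than refitting a common
crossing because the former is what "the average of the intersections"
computes and it keeps the estimator closed-form. The estimator is
order-invariant and exact on exactly linear curves.

**3. Gamma-star** (`gamma_star()`). The chloroplastic compensation
point obeys $\Gamma^* = C_i^* + R_d/g_m$, which is circular before
$g_m$ is known. Three modes are exposed: take $\Gamma^* = C_i^*$ (the
common field shortcut, the default); use a published temperature
response (`bernacchi_constant`); or iterate
$\Gamma^* \leftarrow C_i^* + R_d/g_m(\Gamma^*)$ to completion
(`iterative`, damped fixed point, damping 0.5, tolerance 0.01
$\mu$mol mol$^{-1}$, 50-iteration cap). On simulated data the shortcut
understates $\Gamma^*$ by $R_d/g_m$ (a few $\mu$mol mol$^{-1}$) and
propagates into a substantial downward bias in $g_m$ — the simulator
makes this easy to quantify — while the iterative mode converges to the
generating value. Genotype *rankings* are preserved under either mode
only when the genotypes have similar $R_d/g_m$; recovery testing uses
the iterative mode.

**4. Per-record $C_c$ and $g_m$** (`gm_variable_j()`). Before inverting
the fluorescence relation, $C_i$ is corrected for cuticular water loss:
the instrument's total water conductance $E_l/(W_i - W_a)$ includes a
cuticular component, taken as a constant $E_c = 0.005$ mol m$^{-2}$
s$^{-1}$ per surface, so the stomatal-only value is
$E_l/(W_i - W_a) - 2E_c$ and

$$C_i = C_a - \frac{1.6\,A_n}{E_l/(W_i - W_a) - 2E_c}.$$

This algebra treats $2E_c(W_i - W_a)$ as the two-surface cuticular
water flux; it is dimensionally consistent and disabled with
`ci_mode = "off"`. Then

$$C_c = \frac{\Gamma^*\left[J + 8(A_n + R_d)\right]}{J - 4(A_n + R_d)},
\qquad g_m = \frac{A_n}{C_i - C_c}.$$

The inversion is singular as $J \to 4(A_n + R_d)$, so every record
carries a reliability flag: kept only when the sensitivity
$\mathrm{d}C_c/\mathrm{d}A_n = 12\,J\,\Gamma^*/(J - 4(A_n+R_d))^2$ lies
in $[10, 50]$ and the denominator margin exceeds 5% of $J$ (both
configurable). Unreliable, negative or infinite estimates are retained
with `reliable = FALSE`, never silently dropped. Derived per-record
quantities: $g_{sc} = g_{sw}/1.6$, $\mathrm{WUE}_i = A_n/g_{sw}$
(instrument $g_{sw}$, uncorrected — the axis definition used for the
boxplot comparisons), and the surface ($C_a - C_i$) and mesophyll
($C_i - C_c$) drawdowns.

## FvCB fitting

`aci_to_acc()` converts an A–Ci curve to A–Cc through
$C_c = C_i - A_n/g_m$, with either one curve-level $g_m$ (by default the
reliable estimate at the first $C_a \approx 400$ step, since $g_m$ is
known to drift with $C_i$) or per-point values. `fit_fvcb()` then
estimates $V_{cmax}$ and $J_{max}$ by least squares on

$$A_n = \min(A_c, A_j) - R_d,\quad
A_c = \frac{V_{cmax}(C_c - \Gamma^*)}{C_c + K_c(1 + O/K_o)},\quad
A_j = \frac{J(C_c - \Gamma^*)}{4C_c + 8\Gamma^*},$$

with $R_d$ fixed to the Laisk value by default (freeable). Kinetic
constants default to the Bernacchi parameterization ($K_{c25} = 404.9$
$\mu$mol mol$^{-1}$, $K_{o25} = 278.4$ mmol mol$^{-1}$,
$\Gamma^*_{25} = 42.75$ $\mu$mol mol$^{-1}$, with their activation
energies), all overridable. No triose-phosphate limitation term is
included. Numerically, the kinked $\min(A_c, A_j)$ surface is handled
by a coarse log-scale grid followed by Nelder-Mead refinement from the
best four starts; a stall exactly on the kink is resolved by a
looser-tolerance polish. The limitation crossover $C_c$ is reported,
and a curve whose points all fall on one side flags the other parameter
unidentifiable rather than reporting a spurious value. Parameters are
normalized to 25°C with the simple Arrhenius factor
$\exp[E_a(T_k - 298.15)/(298.15\,R\,T_k)]$; a peaked (deactivating)
form is not implemented, which matters only above the thermal optimum
(≳35°C) where the simple form under-corrects — a known limitation.
Note that a curve measured at a given PPFD identifies the *operating*
electron transport at that light, which is below the asymptotic
$J_{max}$ whenever the light response is saturating.

## The anatomical model

`compose_gm()` implements the one-dimensional serial-resistance model.
Gas phase: $g_{ias} = D_a f_{ias} / (\Delta L_{ias}\,\tau)$ with
$\Delta L_{ias}$ = half the leaf thickness (the trait table reports
$T_{leaf}$, not mesophyll thickness proper) and tortuosity
$\tau = 1.57$ (dimensionless — a ratio, despite occasionally being
printed with units). Liquid phase, per unit exposed surface:
$g_i = D_w r_{f,i} p_i / \Delta L_i$ with path lengths
$\Delta L_{cw} = T_{cw}$, $\Delta L_{cyt} = T_{cyt}$,
$\Delta L_{st} = T_{chl}/2$ (CO2 is consumed throughout the stroma, so
the mean path is half the chloroplast thickness), porosities 0.3 (wall)
and 1 (cytosol, stroma), diffusive-reduction factors 1 (wall) and 0.3
(cytosol, stroma), and fixed membrane permeabilities
$g_{pl} = g_{env} = 0.0035$ m s$^{-1}$. Per-leaf-area resistances scale
each per-surface resistance by the surface through which the flux
passes: $S_m$ for wall and plasma membrane, $S_c$ for cytosol, envelope
and stroma. The composite is

$$g_m = \frac{1}{1/g_{ias} + (R T_k / H)\,/\,g_{liq}}$$

with $H = 2941$ Pa m$^3$ mol$^{-1}$ for CO2 at 25°C (configurable); the
molar conversion uses ambient pressure and temperature.
`compare_genotypes()` reports percent reductions both per unit exposed
surface (pure path-length effects) and per unit leaf area (additionally
reflecting $S_m$/$S_c$); component-level comparisons are conventionally
quoted per surface and the liquid-phase total per leaf area.

```{r anatomy}
am <- rice_anatomy_means()
wt <- compose_gm(am[1, ])
d1 <- compose_gm(am[2, ])
compare_genotypes(wt, d1)
```

The air-space fraction is not part of the genotype trait table; 0.3 (a
typical rice value) is supplied for both genotypes, which leaves every
liquid-phase comparison untouched.

## The forward simulator

`simulate_point()` solves the coupled supply-demand system
$A_n = \mathrm{FvCB}(C_c)$, $C_c = C_i - A_n/g_m$,
$C_i = C_a - 1.6 A_n/g_{sw}$ by bracketed root finding (residual
tolerance $10^{-12}$), then constructs every instrument observable. Key
modelling choices:

* **Fluorescence.** The emitted $\Phi_{PSII}$ corresponds to the actual
  electron consumption — the light-response $J$ under RuBP-regeneration
  limitation, or the carboxylation + photorespiration demand
  $4(A_n + R_d)(C_c + 2\Gamma^*)/(C_c - \Gamma^*)$ under Rubisco
  limitation — so the variable-J inversion is exact on noise-free
  output. $F_m'$ is fixed at 2000 arbitrary units and
  $F_t = F_m'(1 - \Phi_{PSII})$; only the ratio matters downstream.
* **Low O2.** Records at $O_2 \le 2\%$ are simulated as ideally
  non-photorespiratory ($\Gamma^*_{\mathrm{eff}} = 0$). This is the
  assumption the yield calibration itself relies on; without it the
  residual photorespiration at 1% O2 curves the
  $\Phi_{PSII}$–$\Phi_{CO2}$ relation and the simulator would be
  testing the calibration's field bias rather than the package's
  implementation of it.
* **Transpiration.** $W_i - W_a$ is fixed at 0.02 mol mol$^{-1}$ and
  $E_l = (g_{sw} + 2E_c)(W_i - W_a)$, so the recorded conductance is
  the instrument-style total and the cuticular correction is an exact
  inverse — the correction can be tested as such.
* **Laisk fixtures.** `simulate_laisk_curves()` defaults to the
  idealized linear regime the estimator assumes: straight lines through
  the common point $(C_i^*, -R_d)$ with the FvCB tangent slope at that
  point for each irradiance ($\mathrm{d}A_n/\mathrm{d}C_c =
  J/(12\Gamma^*)$, attenuated by finite $g_m$). `shape = "fvcb"` runs
  the full curved model instead, which quantifies the real curvature
  bias of fitting straight lines to a saturating response — several
  $\mu$mol mol$^{-1}$ in $C_i^*$ over a 50–150 ppm window.
* **Noise.** Gaussian, applied to $A_n$, $\Phi_{PSII}$ and $g_{sw}$;
  instrument-scale defaults $\sigma_A = 0.3$ $\mu$mol m$^{-2}$
  s$^{-1}$, $\sigma_\Phi = 0.005$, $\sigma_{gsw} = 0.01$ mol m$^{-2}$
  s$^{-1}$.

`simulate_study()` wraps this into a whole drought experiment:
genotypes × plants × days, lysimetric RSWC declining linearly from 100%
(its day-0 definition) at 3.5%/day so the severe-drought boundary (35%)
is crossed around day 19 of a 20-day drydown; stomata close in
proportion to RSWC/50 below the well-watered boundary (floor 5%) and
$g_m$ declines more gently (floor 40%), so a built-in genotype $g_m$
ratio propagates through every stage. What the generator does *not*
emulate: leaf energy balance, ABA dynamics, day-to-day instrument
drift, non-Gaussian outliers, or genotype differences in the
fluorescence calibration. Passing recovery tests therefore demonstrate
estimator correctness under the measurement model the estimators
assume, not robustness to every failure mode of real campaigns.

```{r study}
set.seed(1)
gp <- list(WT = truth_params(gm = 0.25, gsw = 0.28, sigma_A = 0,
                             sigma_phi = 0, sigma_gsw = 0),
           d1 = truth_params(gm = 0.35, gsw = 0.33, sigma_A = 0,
                             sigma_phi = 0, sigma_gsw = 0))
study <- simulate_study(gp, n_plants = 2, days = seq(0, 20, by = 4),
                        noise = FALSE)
run <- run_pipeline(study$gasex, study$lowci, study$o2_cal,
                    anatomy = study$anatomy, reference = "WT",
                    gamma_star_mode = "iterative")
run
```

## The drought pipeline

`assign_stage()` bins positive RSWC into well-watered (> 50%), moderate
(35–50%] and severe (≤ 35%); exact boundary values fall to the drier
stage (the stricter reading of inequality-defined stages, documented in
output). `summarize_stages()` reports n, mean, sd, median and quartiles
per stage × genotype × variable and contrasts each genotype against the
reference with a two-sample t-test — Welch by default as the robust
choice, pooled available — treating each record as one observation
(`per_plant = TRUE` averages within plants first), with no
cross-variable multiplicity adjustment. `run_pipeline()` chains
calibration → Laisk → per-record $g_m$ → staging → summaries → the
anatomical model, is deterministic given its inputs, and accepts
tibbles or CSV paths.

## Numerical choices and degenerate inputs

Parallel low-Ci lines raise a degenerate-geometry error naming the
pair; the intersection averaging itself is a ratio of fitted
coefficients, so when two irradiances produce nearly equal slopes the
estimate has heavy tails under noise — line slopes are the stable
quantity to monitor. Records with $F_m' \le F_t$, non-positive
corrected water conductance, or a non-positive variable-J denominator
are flagged (and kept) rather than patched. Problem sizes used by the
test suite — 13-point CO2 response curves, 5-point low-Ci curves at 3
irradiances, 500-replicate Monte-Carlo loops, 1000 random anatomies for
the resistor-chain cross-check — keep the full suite around a minute on
one core.

## Known limitations

* The $\Gamma^* = C_i^*$ shortcut biases absolute $g_m$ low; use the
  iterative mode when absolute values matter.
* Simple (non-peaked) Arrhenius normalization only; avoid extrapolating
  normalized parameters from above the thermal optimum.
* The cuticular correction assumes a constant, genotype-independent
  $E_c$.
* No Ethier-type (curve-fitting) or isotopic $g_m$ estimators; the
  variable-J method is the only estimator implemented, and its
  reliability window is the only defence against its singularity.
* The anatomical model is one-dimensional: no explicit chloroplast gap
  fraction, no 3-D tortuous liquid paths, and $\Delta L_{ias}$ proxied
  by half the leaf thickness.
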
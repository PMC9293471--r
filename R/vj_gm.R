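#' Cuticle-corrected intercellular CO2
#'
#' The instrument's Ci assumes all water flux passes through stomata;
#' cuticular transpiration inflates the apparent conductance and biases
#' Ci. Correction: total water conductance `g_tw = El / (Wi - Wa)` minus
#' the two-surface cuticular component `2 * Ec` gives the stomatal water
#' conductance, from which `Ci = Ca - 1.6 * An / (g_tw - 2 * Ec)`.
#'
#' @param records Tibble with `An`, `Ca`, `Ci_raw`, `El`, `Wi`, `Wa`.
#' @param Ec Cuticular transpiration-equivalent water conductance per
#'   surface (mol H2O m-2 s-1), default 0.005.
#' @param mode `"cuticular"` (default) or `"off"` (return `Ci_raw`).
#' @return Input tibble with columns `Ci_corr` and `ci_corr_ok` added.
#'   Records where the corrected conductance is non-positive keep
#'   `Ci_corr = Ci_raw` and are flagged `ci_corr_ok = FALSE` with a
#'   warning.
#' @export
#' @examples
#' rec <- tibble::tibble(An = 20, Ca = 400, Ci_raw = 280,
#'                       El = 0.003, Wi = 0.03, Wa = 0.01)
#' correct_ci(rec)$Ci_corr # 400 - 1.6*20/(0.15 - 0.01) = 171.43
correct_ci <- function(records, Ec = 0.005,
                       mode = c("cuticular", "off")) {
  mode <- match.arg(mode)
  df <- as_tibble(records)
  if (mode == "off") {
    return(mutate(df, Ci_corr = .data$Ci_raw, ci_corr_ok = TRUE))
  }
  stopifnot(all(c("An", "Ca", "El", "Wi", "Wa") %in% names(df)))
  if (any(df$Wi <= df$Wa)) {
    stop("cuticular correction requires Wi > Wa", call. = FALSE)
  }
  g_tw <- df$El / (df$Wi - df$Wa)
  g_prime <- g_tw - 2 * Ec
  ok <- is.finite(g_prime) & g_prime > 0
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with corrected water conductance <= 0; ",
            "Ci_raw retained and flagged", call. = FALSE)
  }
  ci <- ifelse(ok, df$Ca - 1.6 * df$An / g_prime, df$Ci_raw)
  mutate(df, Ci_corr = ci, ci_corr_ok = ok)
}

#' Chloroplastic CO2 from the variable-J relation
#'
#' Harley-style inversion of the RuBP-regeneration-limited FvCB rate:
#' `Cc = Gamma* * (J + 8 * (An + Rd)) / (J - 4 * (An + Rd))`. Valid only
#' while `J > 4 * (An + Rd)`; near that singularity Cc diverges and the
#' estimate is non-physical.
#'
#' @param An Net assimilation (umol m-2 s-1).
#' @param Rd Day respiration (umol m-2 s-1, positive).
#' @param J Electron transport rate (umol m-2 s-1), typically
#'   [j_calibrated()].
#' @param gamma_star Gamma* (umol mol-1).
#' @return Cc (umol mol-1); `NA` where the denominator is non-positive.
#'   Vectorised.
#' @export
#' @examples
#' chloroplastic_cc(An = 20, Rd = 1, J = 150, gamma_star = 40) # 192.73
chloroplastic_cc <- function(An, Rd, J, gamma_star) {
  gross <- An + Rd
  den <- J - 4 * gross
  cc <- ifelse(is.finite(den) & den > 0,
               gamma_star * (J + 8 * gross) / den, NA_real_)
  cc
}

#' Variable-J mesophyll conductance per record
#'
#' The full per-record chain: cuticle-corrected Ci, fluorescence-derived
#' Cc, then `gm = An / (Ci - Cc)` (Fick's law across the mesophyll).
#' Derived quantities: stomatal conductance to CO2 `gsc = gsw / 1.6`,
#' intrinsic water-use efficiency `wue_i = An / gsw`, surface drawdown
#' `Ca - Ci` and mesophyll drawdown `Ci - Cc`.
#'
#' Estimates near the variable-J singularity are notoriously unstable,
#' so each record carries a reliability flag: kept only when the
#' sensitivity `dCc/dAn = 12 * J * Gamma* / (J - 4(An+Rd))^2` lies in
#' `[sens_min, sens_max]` (default 10-50) and `J - 4(An+Rd) > j_margin *
#' J` (default 5 percent). Unreliable, negative or infinite gm values
#' are retained with `reliable = FALSE`, never silently dropped.
#'
#' @param records Tibble of gas-exchange records with fluorescence.
#' @param cal An [calibrate_etr()] result (for Jcal); alternatively
#'   supply `J` directly.
#' @param Rd Day respiration (umol m-2 s-1), e.g. from [laisk()].
#' @param gamma_star Gamma* (umol mol-1).
#' @param Ec Cuticular water conductance per surface (mol m-2 s-1).
#' @param ci_mode `"cuticular"` or `"off"`, see [correct_ci()].
#' @param J Optional explicit electron transport vector overriding the
#'   calibration.
#' @param sens_min,sens_max,j_margin Reliability-filter thresholds.
#' @return Input tibble with added columns `Ci_corr`, `J_used`, `Cc`,
#'   `gm`, `gsc`, `wue_i`, `drawdown_surface`, `drawdown_mesophyll`,
#'   `sensitivity`, `reliable`.
#' @export
gm_variable_j <- function(records, cal = NULL, Rd, gamma_star,
                          Ec = 0.005, ci_mode = c("cuticular", "off"),
                          J = NULL, sens_min = 10, sens_max = 50,
                          j_margin = 0.05) {
  ci_mode <- match.arg(ci_mode)
  df <- correct_ci(records, Ec = Ec, mode = ci_mode)
  if (is.null(J)) {
    if (is.null(cal)) {
      stop("supply either a calibration (cal) or an explicit J vector",
           call. = FALSE)
    }
    psii <- phi_psii(df$Ft, df$Fm_prime)
    J <- suppressWarnings(j_calibrated(psii, df$PPFD, cal))
  }
  gross <- df$An + Rd
  den <- J - 4 * gross
  cc <- chloroplastic_cc(df$An, Rd, J, gamma_star)
  sens <- ifelse(is.finite(den) & den > 0,
                 12 * J * gamma_star / den^2, NA_real_)
  gap <- df$Ci_corr - cc
  gm <- ifelse(is.finite(gap) & abs(gap) > .Machine$double.eps * df$Ci_corr,
               df$An / gap, NA_real_)
  reliable <- is.finite(gm) & gm > 0 &
    is.finite(sens) & sens >= sens_min & sens <= sens_max &
    is.finite(den) & den > j_margin * J &
    df$ci_corr_ok
  mutate(df,
         J_used = J,
         Cc = cc,
         gm = gm,
         gsc = .data$gsw / 1.6,
         wue_i = .data$An / .data$gsw,
         drawdown_surface = .data$Ca - .data$Ci_corr,
         drawdown_mesophyll = .data$Ci_corr - cc,
         sensitivity = sens,
         reliable = reliable)
}

#' Per-genotype regression of gm on stomatal CO2 conductance
#'
#' Drought narrows stomata faster than it degrades the mesophyll path in
#' tolerant genotypes; the slope of gm on gsc captures how tightly the
#' two conductances co-decline. OLS per genotype over reliable
#' estimates, with 95 percent confidence intervals on the slope.
#'
#' @param estimates Output of [gm_variable_j()] with a `genotype`
#'   column.
#' @param min_n Minimum reliable points per genotype (default 3);
#'   smaller groups are skipped with a warning.
#' @return Tibble: `genotype`, `slope`, `intercept`, `slope_low`,
#'   `slope_high` (95% CI), `n`, `r2`.
#' @export
gm_vs_gsc_regression <- function(estimates, min_n = 3) {
  stopifnot(is.data.frame(estimates),
            all(c("gm", "gsc", "genotype", "reliable") %in%
                  names(estimates)))
  df <- filter(as_tibble(estimates), .data$reliable)
  out <- df %>%
    group_by(.data$genotype) %>%
    tidyr::nest(data = -"genotype") %>%
    ungroup()
  res <- purrr::map(out$data, function(d) {
    if (nrow(d) < min_n) return(NULL)
    fit <- lm(gm ~ gsc, data = d)
    ci <- suppressWarnings(confint(fit, "gsc", level = 0.95))
    tibble(slope = unname(coef(fit)[2]),
           intercept = unname(coef(fit)[1]),
           slope_low = ci[1], slope_high = ci[2],
           n = nrow(d),
           r2 = suppressWarnings(summary(fit)$r.squared))
  })
  skipped <- out$genotype[purrr::map_lgl(res, is.null)]
  if (length(skipped) > 0) {
    warning("genotype(s) skipped with fewer than ", min_n,
            " reliable points: ", paste(skipped, collapse = ", "),
            call. = FALSE)
  }
  keep <- !purrr::map_lgl(res, is.null)
  dplyr::bind_cols(tibble(genotype = out$genotype[keep]),
                   dplyr::bind_rows(res[keep]))
}
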
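#' Drought stage boundaries
#'
#' The three lysimetry-defined drought stages: well-watered
#' (RSWC above 50 percent), moderate (35-50) and severe (below 35).
#' Boundary values fall to the drier stage (RSWC = 50 is moderate,
#' RSWC = 35 is severe).
#'
#' @param cut_moderate,cut_severe Stage boundaries (% RSWC).
#' @return Tibble with `label`, `rswc_low`, `rswc_high` partitioning
#'   (0, 100+].
#' @export
drought_stages <- function(cut_moderate = 50, cut_severe = 35) {
  stopifnot(cut_severe > 0, cut_moderate > cut_severe)
  tibble(label = c("well_watered", "moderate", "severe"),
         rswc_low = c(cut_moderate, cut_severe, 0),
         rswc_high = c(Inf, cut_moderate, cut_severe))
}

#' Assign drought stage from relative soil water content
#'
#' Half-open bins, upper-exclusive: a record at exactly 50 percent RSWC
#' is `moderate`, at exactly 35 `severe`.
#'
#' @param rswc RSWC (%), positive; vectorised.
#' @param cut_moderate,cut_severe Stage boundaries (% RSWC).
#' @return Factor with levels `well_watered`, `moderate`, `severe`.
#' @export
#' @examples
#' assign_stage(c(80, 50, 35, 20))
assign_stage <- function(rswc, cut_moderate = 50, cut_severe = 35) {
  if (any(!is.finite(rswc) | rswc <= 0)) {
    stop("RSWC must be positive", call. = FALSE)
  }
  factor(
    dplyr::case_when(
      rswc > cut_moderate ~ "well_watered",
      rswc > cut_severe ~ "moderate",
      TRUE ~ "severe"
    ),
    levels = c("well_watered", "moderate", "severe")
  )
}

#' Stage-by-genotype summaries with wild-type contrasts
#'
#' Summarises physiological variables per drought stage and genotype
#' (n, mean, sd, median, quartiles) and contrasts every genotype
#' against a reference (wild-type) within each stage with a two-sample
#' t-test (Welch by default; `pooled = TRUE` for the classical equal
#' variance form). Each record counts as one observation unless
#' `per_plant = TRUE`, which averages within plants first. Stage cells
#' with fewer than two observations on either side are emitted with
#' `p_value = NA`. No cross-variable multiplicity adjustment is
#' applied.
#'
#' @param estimates Tibble with `genotype`, `stage` and the variables.
#' @param variables Character vector of columns to summarise.
#' @param reference Reference genotype for contrasts; default the first
#'   level encountered.
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @param per_plant Average records within `plant_id` before testing.
#' @return Tibble: `stage`, `genotype`, `variable`, `n`, `mean`, `sd`,
#'   `median`, `q25`, `q75`, `p_value` (NA for the reference rows and
#'   underpowered cells).
#' @export
summarize_stages <- function(estimates,
                             variables = c("An", "gsw", "gm", "wue_i",
                                           "drawdown_surface",
                                           "drawdown_mesophyll"),
                             reference = NULL, pooled = FALSE,
                             per_plant = FALSE) {
  stopifnot(is.data.frame(estimates),
            all(c("genotype", "stage") %in% names(estimates)))
  variables <- intersect(variables, names(estimates))
  if (length(variables) == 0) {
    stop("none of the requested variables are present", call. = FALSE)
  }
  stage_levels <- c("well_watered", "moderate", "severe")
  df <- mutate(as_tibble(estimates),
               stage = factor(.data$stage, levels = stage_levels))
  if (per_plant) {
    stopifnot("plant_id" %in% names(df))
    df <- df %>%
      group_by(.data$genotype, .data$stage, .data$plant_id) %>%
      summarise(across(all_of(variables), ~ mean(.x, na.rm = TRUE)),
                .groups = "drop")
  }
  if (is.null(reference)) reference <- df$genotype[1]
  long <- tidyr::pivot_longer(
    select(df, "genotype", "stage", all_of(variables)),
    cols = all_of(variables), names_to = "variable",
    values_to = "value")
  long <- filter(long, is.finite(.data$value))

  summ <- long %>%
    group_by(.data$stage, .data$genotype, .data$variable) %>%
    summarise(n = dplyr::n(), mean = mean(.data$value),
              sd = sd(.data$value), median = median(.data$value),
              q25 = quantile(.data$value, 0.25),
              q75 = quantile(.data$value, 0.75), .groups = "drop")

  # contrast each non-reference genotype against the reference
  pvals <- long %>%
    group_by(.data$stage, .data$variable, .data$genotype) %>%
    tidyr::nest(data = "value") %>%
    ungroup()
  ref_cells <- filter(pvals, .data$genotype == reference) %>%
    select("stage", "variable", ref_data = "data")
  pvals <- pvals %>%
    left_join(ref_cells, by = c("stage", "variable")) %>%
    mutate(p_value = purrr::pmap_dbl(
      list(.data$data, .data$ref_data, .data$genotype),
      function(d, r, g) {
        if (g == reference || is.null(r)) return(NA_real_)
        if (nrow(d) < 2 || nrow(r) < 2) return(NA_real_)
        if (sd(d$value) == 0 && sd(r$value) == 0) {
          return(if (mean(d$value) == mean(r$value)) 1 else NA_real_)
        }
        tryCatch(t.test(d$value, r$value, var.equal = pooled)$p.value,
                 error = function(e) NA_real_)
      })) %>%
    select("stage", "genotype", "variable", "p_value")

  # emit empty stage x genotype x variable cells explicitly
  grid <- tidyr::crossing(
    stage = factor(stage_levels, levels = stage_levels),
    genotype = unique(df$genotype), variable = variables)
  grid %>%
    left_join(summ, by = c("stage", "genotype", "variable")) %>%
    left_join(pvals, by = c("stage", "genotype", "variable")) %>%
    mutate(n = tidyr::replace_na(.data$n, 0L)) %>%
    arrange(.data$stage, .data$variable, .data$genotype)
}

#' Run the full drought analysis pipeline
#'
#' Orchestrates the study-level chain on tabular inputs:
#' per-genotype electron-transport calibration (1 percent O2 records)
#' -> Laisk Rd / Ci* (low-Ci curves) -> per-record variable-J gm with
#' cuticular Ci correction -> RSWC staging -> stage-by-genotype
#' summaries with WT contrasts -> anatomical gm model per genotype.
#' Deterministic: identical inputs give identical outputs.
#'
#' @param gasex Survey gas-exchange records (tibble or CSV path) with
#'   `genotype`, `plant_id`, `day` and fluorescence fields.
#' @param lowci Low-Ci curves with `genotype`, `Ci`, `An`, `PPFD`.
#' @param o2_cal Non-photorespiratory calibration records with
#'   `genotype` and fluorescence fields.
#' @param pot_weights Daily pot weights with `genotype`, `plant_id`,
#'   `day`, `PW`, `DW`, `t0W` (or an `rswc` column directly on
#'   `gasex`).
#' @param anatomy Optional per-genotype anatomy table for the
#'   one-dimensional gm model.
#' @param reference Reference (wild-type) genotype for contrasts.
#' @param gamma_star_mode Passed to [gamma_star()]:
#'   `"ci_star_as_gamma_star"` (default) or `"iterative"`.
#' @param Ec Cuticular water conductance (mol m-2 s-1).
#' @param const [diffusion_constants()] for the anatomy model.
#' @return List of class `mesocond_run`: `calibrations`, `laisk`,
#'   `estimates` (per-record gm table with stages), `stage_summary`,
#'   `anatomy` (per-genotype `anat_gm` results plus pairwise
#'   comparison when exactly two genotypes are present).
#' @export
run_pipeline <- function(gasex, lowci, o2_cal, pot_weights = NULL,
                         anatomy = NULL, reference = NULL,
                         gamma_star_mode = "ci_star_as_gamma_star",
                         Ec = 0.005, const = diffusion_constants()) {
  load_tbl <- function(x) {
    if (is.character(x)) {
      readr::read_csv(x, show_col_types = FALSE)
    } else {
      as_tibble(x)
    }
  }
  gasex <- load_tbl(gasex)
  lowci <- load_tbl(lowci)
  o2_cal <- load_tbl(o2_cal)
  stopifnot("genotype" %in% names(gasex))
  genos <- unique(gasex$genotype)
  if (is.null(reference)) reference <- genos[1]

  per_geno <- purrr::map(genos, function(g) {
    lc <- filter(lowci, .data$genotype == g)
    oc <- filter(o2_cal, .data$genotype == g)
    lk <- laisk(lc)
    cal <- calibrate_etr(oc, Rd = lk$Rd)
    est <- gm_variable_j(filter(gasex, .data$genotype == g),
                         cal = cal, Rd = lk$Rd,
                         gamma_star = lk$Ci_star, Ec = Ec)
    if (gamma_star_mode == "iterative") {
      lk2 <- gamma_star(lk, mode = "iterative",
                        gm = function(gs) {
                          e <- gm_variable_j(
                            filter(gasex, .data$genotype == g),
                            cal = cal, Rd = lk$Rd, gamma_star = gs,
                            Ec = Ec)
                          median(e$gm[e$reliable], na.rm = TRUE)
                        })
      est <- gm_variable_j(filter(gasex, .data$genotype == g),
                           cal = cal, Rd = lk$Rd,
                           gamma_star = lk2$gamma_star, Ec = Ec)
      lk <- lk2
    }
    list(laisk = lk, cal = cal, est = est)
  })
  names(per_geno) <- genos
  estimates <- bind_rows(purrr::map(per_geno, "est"))

  if (!"rswc" %in% names(estimates)) {
    if (is.null(pot_weights)) {
      stop("supply pot_weights or an rswc column on gasex",
           call. = FALSE)
    }
    pw <- load_tbl(pot_weights)
    pw <- mutate(pw, rswc = compute_rswc(.data$PW, .data$DW, .data$t0W))
    estimates <- left_join(estimates,
                           select(pw, "plant_id", "day", "rswc"),
                           by = c("plant_id", "day"))
  }
  estimates <- mutate(estimates, stage = assign_stage(.data$rswc))
  stage_summary <- summarize_stages(estimates, reference = reference)

  anat <- NULL
  if (!is.null(anatomy)) {
    anatomy <- load_tbl(anatomy)
    fits <- purrr::map(seq_len(nrow(anatomy)),
                       function(i) compose_gm(anatomy[i, ], const))
    names(fits) <- anatomy$genotype
    cmp <- if (nrow(anatomy) == 2) {
      compare_genotypes(fits[[1]], fits[[2]])
    } else {
      NULL
    }
    anat <- list(fits = fits, comparison = cmp)
  }
  structure(
    list(calibrations = purrr::map(per_geno, "cal"),
         laisk = purrr::map(per_geno, "laisk"),
         estimates = estimates, stage_summary = stage_summary,
         anatomy = anat, reference = reference),
    class = "mesocond_run"
  )
}

#' @export
print.mesocond_run <- function(x, ...) {
  cat("mesocond pipeline run\n")
  cat("  genotypes:", paste(names(x$laisk), collapse = ", "),
      "(reference:", x$reference, ")\n")
  cat("  records:", nrow(x$estimates), "of which",
      sum(x$estimates$reliable), "reliable gm estimates\n")
  gm_tab <- filter(x$stage_summary, .data$variable == "gm",
                   .data$n > 0)
  if (nrow(gm_tab) > 0) {
    cat("  stage means of gm (mol m-2 s-1):\n")
    for (i in seq_len(nrow(gm_tab))) {
      cat(sprintf("    %-12s %-8s %.3f (n=%d)\n",
                  as.character(gm_tab$stage[i]), gm_tab$genotype[i],
                  gm_tab$mean[i], gm_tab$n[i]))
    }
  }
  invisible(x)
}
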
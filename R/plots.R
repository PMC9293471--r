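#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_abline
#'   geom_col geom_boxplot geom_hline geom_vline labs facet_wrap
#'   autoplot theme_minimal position_dodge
NULL

#' Plot an electron-transport calibration
#'
#' PhiPSII against PhiCO2 for the points retained in the linear region,
#' with the fitted calibration line.
#'
#' @param object An [calibrate_etr()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.etr_calibration <- function(object, ...) {
  ggplot(object$points, aes(x = .data$phi_co2, y = .data$phi_psii)) +
    geom_point() +
    geom_abline(slope = object$k, intercept = object$b,
                colour = "steelblue") +
    labs(x = expression(Phi[CO2]), y = expression(Phi[PSII]),
         title = sprintf("k = %.2f, b = %.3f, alpha.beta = %.3f",
                         object$k, object$b, object$alpha_beta)) +
    theme_minimal()
}

#' Plot a Laisk estimate
#'
#' The fitted low-Ci lines at each irradiance with their pairwise
#' intersections; the average intersection is the (Ci*, -Rd) estimate.
#'
#' @param object A [laisk()] result.
#' @param ci_range Ci range (umol mol-1) over which to draw the lines.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.laisk_estimate <- function(object, ci_range = c(0, 150), ...) {
  lines <- object$lines
  seg <- tidyr::crossing(lines, Ci = ci_range) %>%
    mutate(An = .data$intercept + .data$slope * .data$Ci)
  ggplot(seg, aes(x = .data$Ci, y = .data$An)) +
    geom_line(aes(group = factor(.data$PPFD),
                  colour = factor(.data$PPFD))) +
    geom_point(data = object$intersections,
               aes(x = .data$x, y = .data$y), shape = 4, size = 3,
               inherit.aes = FALSE) +
    geom_point(x = object$Ci_star, y = -object$Rd, colour = "red",
               size = 2) +
    labs(x = expression(C[i] ~ (mu * mol ~ mol^-1)),
         y = expression(A[n] ~ (mu * mol ~ m^-2 ~ s^-1)),
         colour = "PPFD",
         title = sprintf("Ci* = %.1f, Rd = %.2f", object$Ci_star,
                         object$Rd)) +
    theme_minimal()
}

#' Plot an FvCB fit
#'
#' Observed and fitted A-Cc points with the limitation transition.
#'
#' @param object A [fit_fvcb()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fvcb_fit <- function(object, ...) {
  p <- ggplot(object$data, aes(x = .data$Cc)) +
    geom_point(aes(y = .data$An)) +
    geom_line(aes(y = .data$fitted), colour = "steelblue") +
    labs(x = expression(C[c] ~ (mu * mol ~ mol^-1)),
         y = expression(A[n] ~ (mu * mol ~ m^-2 ~ s^-1)),
         title = sprintf("Vcmax = %.1f, Jmax = %.1f (rmse %.3f)",
                         object$Vcmax, object$Jmax, object$rmse)) +
    theme_minimal()
  if (is.finite(object$transition_Cc %||% NA)) {
    p <- p + geom_vline(xintercept = object$transition_Cc,
                        linetype = "dashed", colour = "grey50")
  }
  p
}

#' Plot the anatomical resistance partition
#'
#' Per-leaf-area resistance of each liquid-phase component for one or
#' more genotypes.
#'
#' @param ... One or more [compose_gm()] results.
#' @return A ggplot object.
#' @export
plot_resistance_partition <- function(...) {
  objs <- list(...)
  stopifnot(length(objs) >= 1,
            all(purrr::map_lgl(objs, inherits, "anat_gm")))
  df <- purrr::imap(objs, function(o, i) {
    mutate(tidy(o),
           genotype = if (!is.na(o$genotype)) o$genotype else
             paste0("genotype_", i))
  }) %>% bind_rows()
  ggplot(df, aes(x = .data$component, y = .data$r_leaf,
                 fill = .data$genotype)) +
    geom_col(position = position_dodge()) +
    labs(x = "diffusion component",
         y = expression(r ~ (s ~ m^-1) ~ "per leaf area"),
         fill = "genotype") +
    theme_minimal()
}

#' Boxplots of a variable by drought stage and genotype
#'
#' @param estimates Per-record estimates with `stage`, `genotype` and
#'   the variable.
#' @param variable Column to plot (string), e.g. `"gm"`.
#' @return A ggplot object.
#' @export
plot_stage_boxes <- function(estimates, variable = "gm") {
  stopifnot(variable %in% names(estimates))
  ggplot(filter(as_tibble(estimates),
                is.finite(.data[[variable]])),
         aes(x = .data$stage, y = .data[[variable]],
             fill = .data$genotype)) +
    geom_boxplot() +
    labs(x = "drought stage", y = variable, fill = "genotype") +
    theme_minimal()
}
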
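#' Forest plot of MR estimates
#'
#' One point and 95% interval per method (intercept rows drawn alongside,
#' since a nonzero Egger intercept is the pleiotropy signal).
#'
#' @param object An `mr_result` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mr_result <- function(object, ...) {
  tb <- as_tibble(object)
  tb <- tb[!is.na(tb$estimate), ]
  tb$method <- factor(tb$method, levels = rev(unique(tb$method)))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$estimate, y = .data$method)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey55") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper),
      height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Causal estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of instrument effects with fitted causal slopes
#'
#' The conventional MR diagnostic: per-instrument outcome effects against
#' exposure effects (with 1-SE bars), the IVW through-origin slope, and the
#' MR-Egger line with its free intercept.
#'
#' @param object A `harmonized_instruments` tibble.
#' @param results Optional `mr_result` table (e.g. from [mr_all()]) whose
#'   IVW/MR-Egger rows supply the slopes; computed from `object` when
#'   absent.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.harmonized_instruments <- function(object, results = NULL, ...) {
  h <- as_tibble(object)
  ivw_row <- egger_slope <- egger_int <- NULL
  if (is.null(results)) {
    ivw_row <- mr_ivw(h)$estimate
    if (nrow(h) >= 3) {
      e <- mr_egger(h)
      egger_slope <- e$estimate
      egger_int <- e$intercept
    }
  } else {
    tb <- as_tibble(results)
    if ("IVW" %in% tb$method) ivw_row <- tb$estimate[tb$method == "IVW"]
    if ("MR-Egger" %in% tb$method) {
      egger_slope <- tb$estimate[tb$method == "MR-Egger"]
      egger_int <- tb$estimate[tb$method == "(Intercept)"][1] %||% 0
    }
  }
  lines <- dplyr::bind_rows(
    if (!is.null(ivw_row)) tibble(method = "IVW", slope = ivw_row, intercept = 0),
    if (!is.null(egger_slope)) tibble(method = "MR-Egger", slope = egger_slope,
                                      intercept = egger_int %||% 0))
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$beta_exposure,
                                       y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$beta_outcome - .data$se_outcome,
                   ymax = .data$beta_outcome + .data$se_outcome),
      width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta_exposure - .data$se_exposure,
                   xmax = .data$beta_exposure + .data$se_exposure),
      height = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Effect on exposure (per allele)",
                  y = "Effect on outcome (per allele)") +
    ggplot2::theme_minimal()
  if (nrow(lines)) {
    p <- p + ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$method)) +
      ggplot2::labs(colour = NULL)
  }
  p
}

#' Plot simulation-study metrics
#'
#' Bias (with empirical-SE whiskers) per method and scenario.
#'
#' @param object A `scenario_metrics` table from [simulation_study()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scenario_metrics <- function(object, ...) {
  tb <- as_tibble(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$method, y = .data$mean_bias)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey55") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_bias - .data$empirical_se,
                   ymax = .data$mean_bias + .data$empirical_se)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$scenario), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Bias (whiskers: empirical SE)") +
    ggplot2::theme_minimal()
}
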
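#' Plot the per-face thickness distribution
#'
#' Histogram of thickness values over the surface model, optionally
#' filtered by direction weight, mirroring the per-participant thickness
#' histograms used to inspect calcification morphometry.
#'
#' @param object a `morphometry_result` from [morphometry()].
#' @param min_weight only faces with at least this direction weight
#'   (default 0: all measured faces).
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
#' @export autoplot.morphometry_result
autoplot.morphometry_result <- function(object, min_weight = 0, bins = 40, ...) {
  d <- dplyr::filter(object$faces, !.data$missing, .data$weight >= min_weight)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$thickness_mm,
                                  weight = .data$weight)) +
    ggplot2::geom_histogram(bins = bins, fill = "firebrick", colour = "grey20") +
    ggplot2::geom_vline(xintercept = object$summary$T_rep_mm,
                        linetype = "dashed") +
    ggplot2::labs(x = "per-face thickness T (mm)",
                  y = "weighted face count",
                  title = sprintf("S = %.1f mm², representative T = %.2f mm",
                                  object$summary$S_mm2,
                                  object$summary$T_rep_mm)) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for fitted brain-volume models
#'
#' Dot-and-whisker display of the standardized S and T estimates across
#' regions and model forms, with 95% intervals and FDR-significant
#' estimates filled.
#'
#' @param object a `bv_model_fits` tibble from [fit_bv_models()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
#' @export autoplot.bv_model_fits
autoplot.bv_model_fits <- function(object, ...) {
  d <- dplyr::filter(object, .data$term %in% c("S_mm2", "T_mm"))
  d$exposure <- ifelse(d$term == "S_mm2", "S", "T")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_std, y = .data$region,
                                  colour = .data$exposure)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$beta_std - 1.96 * .data$se_std,
      xmax = .data$beta_std + 1.96 * .data$se_std,
      shape = .data$significant),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::facet_wrap(~model, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "standardized estimate β*",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
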
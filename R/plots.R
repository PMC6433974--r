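#' Plot component loadings of a CPCA fit
#'
#' Horizontal bar panels of region loadings per component, in canonical
#' region order.
#'
#' @param object A `cpca_fit`.
#' @param family Which loading family to plot: `"regions"` (default),
#'   `"predictors_main"` or `"predictors_interaction"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cpca_fit
#' @export
autoplot.cpca_fit <- function(object, family = c("regions", "predictors_main",
                                                 "predictors_interaction"),
                              ...) {
  family <- match.arg(family)
  df <- tidy(object) |> dplyr::filter(.data$family == !!family)
  df$term <- factor(df$term, rev(unique(df$term)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$loading, y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = "loading (correlation with component scores)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of bootstrap loading intervals
#'
#' Point estimates with percentile confidence intervals; BH-significant
#' loadings drawn solid, others hollow.
#'
#' @param object A `cpca_boot`.
#' @param family Loading family, as in [autoplot.cpca_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cpca_boot
#' @export
autoplot.cpca_boot <- function(object, family = c("regions", "predictors_main",
                                                  "predictors_interaction"),
                               ...) {
  family <- match.arg(family)
  df <- object$tbl |> dplyr::filter(.data$family == !!family)
  df$term <- factor(df$term, rev(unique(df$term)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term,
                                   shape = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.25) +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = paste0("BH q = ", object$q)) +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = "loading (bootstrap percentile CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of component-outcome correlations
#'
#' @param tbl A tibble from [correlate_components_outcomes()].
#' @param alpha Significance level used to annotate cells (default 0.05,
#'   raw p).
#' @return A ggplot object.
#' @export
plot_outcome_correlations <- function(tbl, alpha = 0.05) {
  tbl$outcome <- factor(tbl$outcome, rev(unique(tbl$outcome)))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$component, y = .data$outcome,
                                    fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = paste0(round(.data$r, 2), ifelse(.data$p < alpha, "*", ""))
    ), size = 3) +
    ggplot2::scale_fill_gradient2(low = "darkred", mid = "white",
                                  high = "darkblue", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
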
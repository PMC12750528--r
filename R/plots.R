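# ggplot2 output for the result types.

#' Scatter plot of measured quotas vs reconstructed abundances
#'
#' One point per metal on log-log axes, with the least-squares line behind
#' the points.
#'
#' @param object A `metallome_cor` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.metallome_cor <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$quota, y = .data$abundance)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey60", linewidth = 0.5) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$metal),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Metal quota (mmol/mol C, ICP-MS)",
      y = "Metallome abundance (arbitrary units)",
      title = sprintf("r² = %.2f over %d metals",
                      object$r_squared, object$n_points)
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential protein expression
#'
#' log2 fold change against -log10 p; significant proteins are filled,
#' non-significant ones open, matching the usual presentation of
#' metalloprotein expression differences between strains.
#'
#' @param object A `metallome_de` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.metallome_de <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$p) & !is.na(df$log2fc), ]
  alpha <- attr(object, "alpha")
  groups <- attr(object, "groups")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p),
                                   shape = .data$significant)) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16),
                                name = sprintf("p < %.2g", alpha)) +
    ggplot2::labs(
      x = sprintf("log2 fold change (%s / %s)", groups[["b"]], groups[["a"]]),
      y = expression(-log[10] ~ p)
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of a metallome profile
#'
#' @param profile Profile tibble from [compute_metallome()].
#' @return A ggplot with one bar per metal (log scale) and replicate-SD
#'   error bars, faceted by group when several are present.
#' @export
plot_metallome_profile <- function(profile) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = stats::reorder(.data$metal,
                                                       -.data$abundance),
                                    y = .data$abundance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$abundance - .data$sd, 0),
                   ymax = .data$abundance + .data$sd),
      width = 0.3, na.rm = TRUE
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Relative abundance (arbitrary units)") +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(profile$group) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$group))
  }
  p
}

#' Dot plot of between-strain metal ratios
#'
#' Ratios from [strain_ratio()] with their propagated SDs; the dashed line
#' at 1 marks "no difference". Plotting quota-based and metallome-based
#' ratios from the same strains side by side (via `label`) reproduces the
#' luxury-uptake diagnostic: a metal with a quota ratio above 1 but a
#' metallome ratio near 1 is accumulated beyond use.
#'
#' @param ... Named ratio tibbles (names become panel labels), or a single
#'   unnamed one.
#' @return A ggplot.
#' @export
plot_strain_ratios <- function(...) {
  inputs <- list(...)
  if (is.null(names(inputs)) || any(names(inputs) == "")) {
    names(inputs) <- paste0("ratios", seq_along(inputs))
  }
  df <- dplyr::bind_rows(inputs, .id = "source")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metal, y = .data$ratio,
                                   colour = .data$source)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = pmax(.data$ratio - .data$sd, 1e-12),
                   ymax = .data$ratio + .data$sd),
      position = ggplot2::position_dodge(width = 0.4), na.rm = TRUE
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Ratio", colour = NULL) +
    ggplot2::theme_minimal()
}
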
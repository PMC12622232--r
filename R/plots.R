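#' Plot within-genus versus between-genera value distributions
#'
#' Overlaid histograms of POCP/POCPu values for the two pair classes with
#' the decision threshold as a dashed vertical line -- the standard visual
#' check of how well a threshold separates genera.
#'
#' @param values A labeled-value tibble (columns `value`, `same_genus`).
#' @param threshold Threshold to draw. Default 50.
#' @param binwidth Histogram bin width in percent. Default 2.
#' @return A ggplot object.
#' @export
plot_value_distribution <- function(values, threshold = 50, binwidth = 2) {
  check_labeled_values(values)
  df <- dplyr::mutate(
    values,
    class = ifelse(.data$same_genus, "Within-genus", "Between-genera")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$class)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6, boundary = 0) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c("Between-genera" = "#E69F00",
                                          "Within-genus" = "#56B4E9")) +
    ggplot2::labs(x = "Conserved proteins (%)", y = "Genome pairs",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname optimize_threshold
#' @param object A `pocp_threshold_opt` or `pocp_concordance` object.
#' @export
autoplot.pocp_threshold_opt <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_vline(xintercept = object$default_threshold,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$threshold, colour = "#D55E00") +
    ggplot2::annotate("text", x = object$threshold, y = 1,
                      label = sprintf("MCC %.2f", object$mcc_at_threshold),
                      hjust = -0.1) +
    ggplot2::xlim(0, 100) +
    ggplot2::labs(
      x = "Conserved proteins (%)", y = NULL,
      title = paste0("Optimized genus threshold: ", object$family)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot per-family delineation performance
#'
#' Ranks families by MCC at the default threshold, with the pooled global
#' MCC as a dashed reference line; when optimized thresholds are present
#' the attainable maximum MCC is shown as a second point per family.
#'
#' @param report Output of [evaluate_per_family()].
#' @return A ggplot object.
#' @export
plot_family_mcc <- function(report) {
  stopifnot(all(c("family", "mcc_at_default") %in% names(report)))
  global <- report$mcc_at_default[report$family == "global"]
  df <- report[report$family != "global", , drop = FALSE]
  df$family <- stats::reorder(df$family, df$mcc_at_default)
  p <- ggplot2::ggplot(df, ggplot2::aes(y = .data$family)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$mcc_at_default)) +
    ggplot2::labs(x = "MCC", y = NULL) +
    ggplot2::xlim(-1, 1) +
    ggplot2::theme_minimal()
  if ("mcc_at_threshold" %in% names(df) && any(!is.na(df$mcc_at_threshold))) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(x = .data$mcc_at_threshold),
      colour = "#D55E00", shape = 17, na.rm = TRUE
    )
  }
  if (length(global)) {
    p <- p + ggplot2::geom_vline(xintercept = global, linetype = "dashed")
  }
  p
}

#' @rdname method_concordance
#' @param object A `pocp_concordance` object.
#' @export
autoplot.pocp_concordance <- function(object, ...) {
  df <- object$fit$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#D55E00") +
    ggplot2::labs(
      x = paste0(object$method, " (%)"), y = "Reference method (%)",
      title = sprintf("R² = %.5f (n = %d)", object$r_squared, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
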
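# Dot-and-interval charts for the enrichment and regression tables.

#' Plot category enrichment odds ratios
#'
#' Dot-and-interval chart of per-category odds ratios (log2 scale) with
#' Wald confidence intervals; categories significant at the given q-value
#' threshold are highlighted. Save with `ggplot2::ggsave()` (e.g. to SVG).
#'
#' @param enrichment Tibble from [category_enrichment()].
#' @param q_threshold Highlighting threshold on the BH q-value
#'   (default 0.05).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, q_threshold = 0.05) {
  df <- dplyr::filter(enrichment, is.finite(.data$odds_ratio),
                      .data$odds_ratio > 0)
  df$significant <- df$q_value < q_threshold
  df$category <- stats::reorder(df$category, df$odds_ratio)
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$odds_ratio),
                                   y = .data$category,
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = log2(.data$ci_low), xmax = log2(.data$ci_high)),
      height = 0.2, na.rm = TRUE
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#2166ac", `FALSE` = "grey50"),
      name = paste0("q < ", q_threshold)
    ) +
    ggplot2::labs(x = "log2 odds ratio (matches vs non-matches)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot logistic regression coefficients
#'
#' Point estimates and 95% confidence intervals on the log-odds scale,
#' one row per feature (intercept omitted).
#'
#' @param fit A `phen_logit` from [fit_match_model()].
#' @return A ggplot object.
#' @export
plot_coefficients <- function(fit) {
  df <- dplyr::filter(fit$coefficients, .data$term != "(Intercept)")
  df$term <- stats::reorder(df$term, df$estimate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2
    ) +
    ggplot2::geom_point(size = 2, colour = "#2166ac") +
    ggplot2::labs(x = "coefficient (log-odds)", y = NULL) +
    ggplot2::theme_minimal()
}
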
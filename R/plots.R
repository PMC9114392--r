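#' Bar chart of enhancer-associated fractions per category
#'
#' @param enrichment Output of [enrichment_by_category()].
#' @return A ggplot object.
#' @export
plot_enhancer_fractions <- function(enrichment) {
  check_columns(enrichment, c("category", "fraction"), "enrichment table")
  df <- dplyr::filter(enrichment, !is.na(.data$fraction))
  df$category <- factor(df$category,
                        levels = intersect(apa_categories, df$category))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("n=%d", .data$n)),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x)) +
    ggplot2::labs(x = NULL, y = "enhancer-associated genes",
                  title = "Enhancer association by gene category") +
    ggplot2::theme_minimal()
}

#' Violin plot of gene expression changes by category
#'
#' @param categories Output of [classify_genes()].
#' @return A ggplot object.
#' @export
plot_fc_by_category <- function(categories) {
  check_columns(categories, c("category", "gene_log2fc"), "category table")
  df <- dplyr::filter(categories, .data$category != "unclassified",
                      is.finite(.data$gene_log2fc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category,
                                   y = .data$gene_log2fc)) +
    ggplot2::geom_violin(fill = "grey80", draw_quantiles = c(.25, .5, .75)) +
    ggplot2::labs(x = NULL, y = "gene expression log2 fold change") +
    ggplot2::theme_minimal()
}

#' Change in SU usage (dPAU) by category
#'
#' @param categories Output of [classify_genes()].
#' @return A ggplot object.
#' @export
plot_dpau_by_category <- function(categories) {
  check_columns(categories, c("category", "dpau"), "category table")
  df <- dplyr::filter(categories, .data$category != "unclassified",
                      is.finite(.data$dpau))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$dpau)) +
    ggplot2::geom_violin(fill = "grey80", draw_quantiles = c(.25, .5, .75)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "dPAU (B - A)") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_decay Plot a fitted decay with its data points.
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @export
autoplot.decay_fit <- function(object, ...) {
  grid <- tibble::tibble(
    t_hours = seq(min(object$data$t_hours), max(object$data$t_hours),
                  length.out = 100))
  grid$abundance <- exp(object$k * grid$t_hours)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$t_hours, y = .data$abundance)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (h)", y = "relative abundance",
                  subtitle = sprintf("k = %.3f /h, half-life = %.2f h",
                                     object$k, object$half_life)) +
    ggplot2::theme_minimal()
}
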
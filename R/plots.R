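# ggplot2 views of the main result types.

#' Scatter of contiguous match length vs fold change
#'
#' The classic off-target view: one point per matched gene, match length
#' against |log2FC| (or signed log2FC), coloured by significance class
#' (red = significant DEG, blue = fold change only, gray = unchanged).
#'
#' @param x `match_correlation` from [match_fold_change_correlation()].
#' @param signed plot signed log2FC instead of its absolute value.
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot match_correlation
#' @export
autoplot.match_correlation <- function(x, signed = FALSE, ...) {
  df <- x$genes
  df$y <- if (signed) df$log2fc else df$abs_log2fc
  ggplot2::ggplot(df, ggplot2::aes(x = .data$max_match, y = .data$y,
                                   colour = .data$color_class)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(red = "#d7301f", blue = "#0570b0",
                                            gray = "grey60"),
                                 name = NULL) +
    ggplot2::labs(x = "Maximal contiguous match (bp)",
                  y = if (signed) "log2 fold change" else "|log2 fold change|",
                  subtitle = sprintf("Spearman rho = %.3f (n = %d)", x$rho, x$n)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.match_correlation
#' @export
plot_match_fold_change <- function(x, signed = FALSE) {
  autoplot.match_correlation(x, signed = signed)
}

#' Group comparison of transcriptome entropy
#'
#' Group means with standard-error bars and per-sample points.
#'
#' @param x `entropy_result` from [compare_group_entropy()].
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot entropy_result
#' @export
autoplot.entropy_result <- function(x, ...) {
  ggplot2::ggplot(x$groups, ggplot2::aes(x = .data$group, y = .data$mean_H)) +
    ggplot2::geom_col(fill = "grey80", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_H - .data$se_H,
                                        ymax = .data$mean_H + .data$se_H),
                           width = 0.15) +
    ggplot2::geom_jitter(data = x$samples,
                         ggplot2::aes(x = .data$group, y = .data$H),
                         width = 0.08, size = 2, alpha = 0.8) +
    ggplot2::labs(x = NULL,
                  y = sprintf("Shannon entropy (%s)",
                              if (x$base == 2) "bits" else "nats"),
                  subtitle = sprintf("Student's t p = %.3g", x$pvalue)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.entropy_result
#' @export
plot_entropy <- function(x) autoplot.entropy_result(x)

#' Dot plot of gene-set over-representation
#'
#' @param x `enrichment_result` from [enrich()].
#' @param top number of top sets shown.
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(x, top = 20, ...) {
  df <- head(as_tibble(x), top)
  df$set <- factor(df$set, levels = rev(df$set))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_enrichment, y = .data$set,
                                   size = .data$k, colour = -log10(.data$fdr))) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(name = "-log10 FDR") +
    ggplot2::labs(x = "Fold enrichment", y = NULL, size = "DEGs in set") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.enrichment_result
#' @export
plot_enrichment <- function(x, top = 20) autoplot.enrichment_result(x, top = top)

#' Volcano view of a DE result
#'
#' @param x `de_result` from [nb_wald_test()].
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(x, ...) {
  df <- as_tibble(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = -log10(.data$fdr),
                                   colour = .data$change_class)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(significant_deg = "#d7301f",
                                            fold_only = "#0570b0",
                                            unchanged = "grey60"),
                                 name = NULL) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR") +
    ggplot2::theme_minimal()
}
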
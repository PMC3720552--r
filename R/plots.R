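#' Per-chromosome CNV coverage bar plot
#'
#' @param cov A [coverage_table()] result.
#' @param statistic `"bp_coverage_pct"` or `"snp_density"`.
#' @return A ggplot.
#' @export
plot_coverage <- function(cov, statistic = c("bp_coverage_pct", "snp_density")) {
  statistic <- match.arg(statistic)
  df <- cov[cov$chrom != "total", ]
  df$chrom <- factor(df$chrom, levels = df$chrom)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom, y = .data[[statistic]],
                                   fill = .data$enriched)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick"),
                               na.value = "grey80") +
    ggplot2::labs(x = "chromosome",
                  y = if (statistic == "bp_coverage_pct")
                    "CNVR coverage (% of chromosome)" else
                      "SNPs in CNVRs per bp",
                  fill = "enriched") +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of a CNV association scan
#'
#' Plots -log10 of the pointwise p per region along the genome, shaped by
#' the genome-wide permutation significance.
#'
#' @param object A `cnv_assoc` object.
#' @param alpha Genome-wide significance threshold to highlight (default
#'   0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cnv_assoc
#' @export
autoplot.cnv_assoc <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$p_point), ]
  df$significant <- df$p_genome <= alpha
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = -log10(.data$p_point),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](p[point])),
                  colour = paste0("p_genome <= ", alpha)) +
    ggplot2::theme_minimal()
}

#' qPCR relative-quantity plot
#'
#' Relative quantity per sample with the called copy-number class as the
#' point shape and the diploid line at rq = 1, in the style of a standard
#' qPCR validation figure.
#'
#' @param rq A [relative_quantity()] result.
#' @return A ggplot.
#' @export
plot_qpcr <- function(rq) {
  rq$called_cn <- factor(rq$called_cn, levels = 0:3)
  ggplot2::ggplot(rq, ggplot2::aes(x = .data$sample_id, y = .data$rq,
                                   shape = .data$called_cn)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c(`0` = 16, `1` = 17, `2` = 15,
                                           `3` = 18), drop = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$assay)) +
    ggplot2::labs(x = NULL, y = "relative quantity (2^-ddCt)",
                  shape = "copies") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
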
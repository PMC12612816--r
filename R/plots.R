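#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' PC1/PC2 scatter of samples, colored by karyotype when available
#'
#' @param object an `inv_pca`.
#' @param callset optional `karyotype_calls` to color points.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.inv_pca <- function(object, callset = NULL, ...) {
  d <- tidy.inv_pca(object)
  if (!"PC2" %in% names(d)) d$PC2 <- 0
  if (!is.null(callset)) {
    d <- dplyr::left_join(d, callset$calls[, c("sample", "karyotype")],
                          by = "sample")
  } else d$karyotype <- "unknown"
  ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2,
                                  color = .data$karyotype)) +
    ggplot2::geom_point(size = 2.5, shape = 1, stroke = 1.2) +
    ggplot2::labs(x = "PC1", y = "PC2", color = "Karyotype") +
    ggplot2::theme_minimal()
}

#' Absolute PC1 loadings along the chromosome
#'
#' Mirrors the classic inversion diagnostic: top-loading SNPs form a block
#' whose first/last positions mark the breakpoints.
#'
#' @param pca an `inv_pca`.
#' @param top_frac fraction highlighted as top loadings (default 0.05).
#' @param block optional `(start, end)` to draw breakpoint lines.
#' @return a ggplot.
#' @export
plot_loadings <- function(pca, top_frac = 0.05, block = NULL) {
  d <- tidy.inv_pca(pca, "loadings")
  n_top <- max(2L, ceiling(top_frac * nrow(d)))
  thr <- sort(abs(d$PC1), decreasing = TRUE)[n_top]
  d$top <- abs(d$PC1) >= thr
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$pos / 1e6, abs(.data$PC1),
                                       color = .data$top)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "black"),
                                guide = "none") +
    ggplot2::labs(x = "Position (Mb)", y = "|PC1 loading|") +
    ggplot2::theme_minimal()
  if (!is.null(block)) {
    p <- p + ggplot2::geom_vline(xintercept = block / 1e6, linetype = 2,
                                 color = "red")
  }
  p
}

#' Windowed strata-consistency track
#'
#' @param wins result of [strata_scan()].
#' @return a ggplot of per-window heterozygosity contrast, colored by
#'   consistency with the global ancestry verdict.
#' @export
plot_strata <- function(wins) {
  ggplot2::ggplot(wins, ggplot2::aes((.data$start + .data$end) / 2e6,
                                     .data$d_het,
                                     color = .data$consistent)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "Window midpoint (Mb)",
                  y = "Het-rate contrast (derived - ancestral)",
                  color = "Consistent") +
    ggplot2::theme_minimal()
}

#' Forest plot of meta-summarized karyotype effects
#'
#' @param object a `meta_summary`.
#' @param ... unused.
#' @return a ggplot with per-contrast estimates and 95% CIs.
#' @export
autoplot.meta_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$estimate, .data$contrast)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lo,
                                          xmax = .data$ci_hi)) +
    ggplot2::labs(x = "Standardized effect (vs. AA baseline)", y = NULL) +
    ggplot2::theme_minimal()
}
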
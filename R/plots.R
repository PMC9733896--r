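#' Manhattan plot of a genome scan
#'
#' @param scan A `mixscan_scan` tibble with `chrom` and `pos_bp` attached
#'   (pass `map` to the scan function).
#' @param threshold Genome-wide -log10 threshold line (optional).
#' @param term Which term to plot: `"genetic"` (default), `"interaction"` or
#'   `"treatment"`.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan, threshold = NULL, term = "genetic") {
  stopifnot("chrom" %in% names(scan))
  ycol <- paste0("minus_log10_p_", term)
  d <- dplyr::filter(scan, !.data$degenerate) |>
    dplyr::arrange(.data$chrom, .data$pos_bp) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(x = .data$pos_bp / max(.data$pos_bp)) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data[[ycol]],
                                       colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = sprintf("%s scan: %s (%s term)", scan$scan_kind[1],
                                  scan$trait[1], term)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "blue")
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.mixscan_scan <- function(object, threshold = NULL,
                                  term = "genetic", ...) {
  plot_manhattan(object, threshold = threshold, term = term)
}

#' Distribution of per-treatment diversity slopes
#'
#' @param beta_cwd,beta_r Slope tibbles from [per_treatment_slopes()].
#' @return A ggplot density plot of the two slope distributions.
#' @export
plot_slope_distribution <- function(beta_cwd, beta_r) {
  d <- dplyr::bind_rows(
    dplyr::mutate(beta_cwd, treatment = "CWD"),
    dplyr::mutate(beta_r, treatment = "R"))
  ggplot2::ggplot(d[!is.na(d$slope), ],
                  ggplot2::aes(x = .data$slope, colour = .data$treatment)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(CWD = "firebrick", R = "navy")) +
    ggplot2::labs(x = "diversity slope (trait units per unit HE)",
                  y = "density") +
    ggplot2::theme_minimal()
}
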
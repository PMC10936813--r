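#' Plot a break map region
#'
#' Per-bp HpM signal (Watson up, Crick down) for a chromosome window.
#'
#' @param map A `fullmap`.
#' @param chrom Chromosome to show.
#' @param xlim Optional position range (bp).
#' @return A ggplot.
#' @export
plot_fullmap <- function(map, chrom, xlim = NULL) {
  hp <- fullmap_hpm(map)
  tot <- fullmap_total(map)
  df <- hp[hp$chrom == chrom, ]
  if (!is.null(xlim)) df <- df[df$pos >= xlim[1] & df$pos <= xlim[2], ]
  df <- tidyr::pivot_longer(df, c("watson", "crick"), names_to = "strand",
                            values_to = "count")
  df$hpm_strand <- df$count * 1e6 / tot * ifelse(df$strand == "crick", -1, 1)
  ggplot2::ggplot(df, ggplot2::aes(.data$pos, .data$hpm_strand,
                                   colour = .data$strand)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0)) +
    ggplot2::labs(x = paste0(chrom, " position (bp)"), y = "HpM",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.interference_comparison <- function(object, ...) {
  pts <- dplyr::bind_rows(
    tibble::tibble(group = object$groups$group[1], interference = object$values[[1]]),
    tibble::tibble(group = object$groups$group[2], interference = object$values[[2]]))
  ggplot2::ggplot(object$groups, ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15) +
    ggplot2::geom_jitter(data = pts,
                         ggplot2::aes(.data$group, .data$interference),
                         width = 0.08, shape = 21, fill = "white") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "DSB interference (-log2 obs/exp DCs)") +
    ggplot2::theme_classic()
}

#' @export
autoplot.binned_ratio <- function(object, ...) {
  rank <- attr(object, "size_rank")
  df <- tibble::as_tibble(object)
  df$chrom <- factor(df$chrom, levels = rev(rank))
  ggplot2::ggplot(df[df$defined, ],
                  ggplot2::aes(.data$k + 0.5, .data$chrom, fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = sprintf("bin (x %d kb) relative to centromere",
                              attr(object, "bin") %/% 1000),
                  y = NULL, fill = "log2 FC") +
    ggplot2::theme_minimal()
}

#' Smoothed fold-change trend along a chromosome
#'
#' @param smoothed Output of [smooth_ratio()].
#' @param chrom Chromosome to show.
#' @return A ggplot of per-hotspot log2 fold changes with the smoothed trend.
#' @export
plot_smooth_ratio <- function(smoothed, chrom) {
  df <- smoothed[smoothed$chrom == chrom & smoothed$defined, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$midpoint / 1000, .data$log2fc)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = paste0(chrom, " position (kb)"),
                  y = "log2 fold change (NormHpM)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
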
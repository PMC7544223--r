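#' Visualize a bitome region
#'
#' Tile plot of the matrix over a genomic range: rows are feature row
#' keys, columns genomic positions, filled where the bit is set — the
#' standard region view for inspecting how features stack at a locus.
#'
#' @param object a `bitome`.
#' @param start,end 0-based half-open range to show (default: whole
#'   genome, sensible only for small genomes).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bitome <- function(object, start = 0L, end = ncol(object$matrix), ...) {
  sub <- bitome_extract(object, start, end)
  Mt <- methods::as(sub$matrix, "TsparseMatrix")
  df <- tibble(position = Mt@j + start,
               row = factor(sub$row_keys$row_label[Mt@i + 1L],
                            levels = rev(sub$row_keys$row_label)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$row)) +
    ggplot2::geom_tile(fill = "black") +
    ggplot2::labs(x = "genomic position (bp)", y = NULL) +
    ggplot2::theme_minimal(base_size = 8)
}

#' Plot a moving-density profile
#'
#' Line plot of bits/bp across the genome with dashed mean +/- 2 sd bands.
#'
#' @param profile tibble from [moving_density()].
#' @return a ggplot object.
#' @export
plot_density_profile <- function(profile) {
  m <- attr(profile, "mean"); s <- attr(profile, "sd")
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$start, y = .data$density)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = m, linetype = "dashed", color = "grey40") +
    ggplot2::geom_hline(yintercept = c(m - 2 * s, m + 2 * s),
                        linetype = "dashed", color = "grey70") +
    ggplot2::labs(x = "window start (bp)",
                  y = sprintf("bit density (bits/bp, %d bp windows)",
                              attr(profile, "window"))) +
    ggplot2::theme_minimal()
}

#' Plot promoter element geometry
#'
#' Overlaid histograms of the -10 and -35 box center-to-TSS distances,
#' with median lines.
#'
#' @param geometry tibble from [promoter_geometry()].
#' @return a ggplot object.
#' @export
plot_promoter_geometry <- function(geometry) {
  long <- tidyr::pivot_longer(
    geometry[, c("minus10_distance", "minus35_distance")],
    dplyr::everything(), names_to = "element", values_to = "distance")
  med <- long %>% dplyr::group_by(.data$element) %>%
    dplyr::summarise(m = stats::median(.data$distance), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$distance, fill = .data$element)) +
    ggplot2::geom_histogram(binwidth = 1, alpha = 0.6, position = "identity") +
    ggplot2::geom_vline(data = med,
                        ggplot2::aes(xintercept = .data$m, color = .data$element),
                        linetype = "dashed") +
    ggplot2::labs(x = "element center to TSS (bp)", y = "promoters") +
    ggplot2::theme_minimal()
}

#' Plot per-amino-acid SNP mutation frequencies
#'
#' Bar chart of SNP frequency per amino acid with the genome-wide baseline
#' as a dashed line.
#'
#' @param freqs tibble from [aa_mutation_frequencies()].
#' @return a ggplot object.
#' @export
plot_aa_mutation_frequencies <- function(freqs) {
  ggplot2::ggplot(freqs, ggplot2::aes(
    x = stats::reorder(.data$amino_acid, -.data$frequency),
    y = .data$frequency)) +
    ggplot2::geom_col(fill = "firebrick", alpha = 0.8) +
    ggplot2::geom_hline(yintercept = attr(freqs, "baseline"),
                        linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = NULL, y = "SNPs per covered bp") +
    ggplot2::theme_minimal()
}

#' Plot a normalized confusion matrix
#'
#' Tile plot of the per-true-class normalized confusion matrix of an
#' evaluation report.
#'
#' @param object a `bitome_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bitome_eval <- function(object, ...) {
  cm <- object$confusion
  df <- tibble(truth = rep(rownames(cm) %||% c("0", "1"), 2),
               predicted = rep(colnames(cm) %||% c("0", "1"), each = 2),
               value = as.vector(cm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       color = "white") +
    ggplot2::scale_fill_gradient(low = "grey70", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "predicted class", y = "true class",
                  fill = "accuracy") +
    ggplot2::theme_minimal()
}
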
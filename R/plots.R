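#' Plot a variant k-mer coverage profile
#'
#' Per-base coverage of the informative (variant-spanning) k-mers: a SNP
#' peaks at k on one base, a junction plateaus at k - 1 over two bases, an
#' insertion plateaus at k over the inserted bases.
#'
#' @param object A `coverage_profile` from [variant_coverage_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coverage_profile
#' @export
autoplot.coverage_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$coverage)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = attr(object, "k"), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "position in variant context (bp)",
                  y = "informative k-mer coverage",
                  title = sprintf("k = %d, %d informative k-mers",
                                  attr(object, "k"), attr(object, "n_informative"))) +
    ggplot2::theme_minimal()
}

#' Plot the genome size vs k-mer diversity relationship
#'
#' Points for every genome, the fitted line over IR-bearing genomes
#' (dashed), and the 1:1 line (solid) that IR-less genomes track.
#'
#' @param object A `diversity_fit` from [diversity_regression()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot diversity_fit
#' @export
autoplot.diversity_fit <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$genome_size, y = .data$distinct_kmers,
                                    colour = .data$has_ir)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "black") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed", colour = "blue") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
                                 name = "inverted repeat") +
    ggplot2::labs(x = "genome size (bp)", y = "distinct canonical k-mers") +
    ggplot2::theme_minimal()
}

#' Contig length distribution by class label
#'
#' Histogram of localized contig lengths, filled by classification label;
#' the single-feature mode near twice the read length and the long-contig
#' tail (hot-spots) are the features of interest.
#'
#' @param contigs Classified contig tibble ([classify_contigs()]).
#' @param binwidth Histogram bin width in bases.
#' @return A ggplot.
#' @export
plot_contig_lengths <- function(contigs, binwidth = 10) {
  ggplot2::ggplot(contigs, ggplot2::aes(x = .data$length, fill = .data$label)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::labs(x = "contig length (bp)", y = "contigs") +
    ggplot2::theme_minimal()
}
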
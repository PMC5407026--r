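#' Plot allelic kinetic estimates of an allelic bursting fit
#'
#' Scatterplots of the allele-A versus allele-B burst frequency and burst
#' size for all biallelic bursty genes, on log scales, coloured by whether the
#' corresponding differential test is FDR-significant. Points on the diagonal
#' have equal allelic kinetics.
#'
#' @param object An [allelic_bursting()] object.
#' @param ... Unused.
#' @return A ggplot object (two facets: burst frequency, burst size).
#' @method autoplot allelic_bursting
#' @export
autoplot.allelic_bursting <- function(object, ...) {
  r <- object$results
  r <- r[!is.na(r$burst_frequency_a) & !is.na(r$burst_frequency_b), ]
  if (!nrow(r)) stop("No genes with estimable kinetics to plot.", call. = FALSE)
  d <- dplyr::bind_rows(
    tibble::tibble(gene = r$gene, what = "burst frequency",
                   a = r$burst_frequency_a, b = r$burst_frequency_b,
                   significant = r$sig_freq),
    tibble::tibble(gene = r$gene, what = "burst size",
                   a = r$burst_size_a, b = r$burst_size_b,
                   significant = r$sig_size)
  )
  d <- d[d$a > 0 & d$b > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b,
                                  colour = .data$significant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~what, scales = "free") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 na.value = "grey70") +
    ggplot2::labs(x = "allele A", y = "allele B",
                  colour = "FDR-significant") +
    ggplot2::theme_bw()
}

#' Per-cell allelic counts for one gene
#'
#' Scatterplot of allele-A versus allele-B read counts across cells for a
#' single gene, the standard visual for bursting patterns: cells near the
#' origin express neither allele, cells on an axis express one, and cells in
#' the interior express both.
#'
#' @param counts Tibble with columns `gene`, `cell`, `count_a`, `count_b`.
#' @param gene Gene identifier to plot.
#' @return A ggplot object.
#' @export
plot_gene_counts <- function(counts, gene) {
  counts <- validate_counts(counts)
  d <- counts[counts$gene == gene, ]
  if (!nrow(d)) stop("Gene `", gene, "` not found.", call. = FALSE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$count_a, y = .data$count_b)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(title = gene, x = "allele A reads", y = "allele B reads") +
    ggplot2::theme_bw()
}

#' Plot a repiled true-expression histogram
#'
#' Bar plot of the deconvolved true-expression weights (including the zero
#' pile) against the observed-count histogram, visualising what the repiling
#' step recovered.
#'
#' @param hist A [repile_histogram()] result.
#' @param q Optional observed counts to overlay.
#' @return A ggplot object.
#' @export
plot_repiled_histogram <- function(hist, q = NULL) {
  stopifnot(inherits(hist, "repiled_histogram"))
  d <- tibble::tibble(y = c(0, hist$support),
                      weight = c(hist$n_zero, hist$weights),
                      which = "repiled (true expression)")
  if (!is.null(q)) {
    tq <- table(q)
    d <- dplyr::bind_rows(d, tibble::tibble(
      y = as.numeric(names(tq)), weight = as.numeric(tq),
      which = "observed counts"))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$y, y = .data$weight,
                                  fill = .data$which)) +
    ggplot2::geom_col(position = "identity", alpha = 0.5, width = 0.9) +
    ggplot2::labs(x = "expression", y = "cells (weight)", fill = NULL) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
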
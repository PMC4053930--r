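#' Tidy an assembly into its contig table
#'
#' @param x A `hetasm_assembly` from [assemble_genome()].
#' @param ... Unused.
#' @return The contig tibble (`id`, `sequence`, `length`,
#'   `mean_kmer_coverage`).
#' @export
tidy.hetasm_assembly <- function(x, ...) {
  tibble::as_tibble(x$contigs)
}

#' One-row assembly summary
#'
#' @param x A `hetasm_assembly`.
#' @param ... Unused.
#' @return Tibble with `n_contigs`, `total_bp`, `n50`, `longest`,
#'   `mean_coverage`, and popped-bubble counts by rule.
#' @export
glance.hetasm_assembly <- function(x, ...) {
  p <- x$popped
  tibble(n_contigs = nrow(x$contigs),
         total_bp = sum(x$contigs$length),
         n50 = n50(x$contigs$length),
         longest = max(x$contigs$length),
         mean_coverage = mean(x$contigs$mean_kmer_coverage, na.rm = TRUE),
         popped_short = sum(p$rule == "short_two_snv"),
         popped_long = sum(p$rule == "long_identity"),
         popped_complex = sum(p$rule == "complex_span"))
}

#' Plot per-scaffold SNV density against scaffold length
#'
#' Hemizygous candidates separate from the diploid background as a
#' near-zero-density band.
#'
#' @param summaries A classified [scaffold_snv_density()] tibble.
#' @return A ggplot object.
#' @export
plot_snv_density <- function(summaries) {
  if (!"classification" %in% names(summaries))
    summaries$classification <- "unclassified"
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$length, y = .data$density,
                               colour = .data$classification)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "scaffold length (bp, log scale)",
                  y = "SNV density (SNVs/kbp)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-region SNP density
#'
#' @param report The `report` tibble from [annotate_regions()].
#' @return A ggplot object.
#' @export
plot_region_density <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$region, y = .data$density)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "SNP density (SNPs/kbp)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hetasm_assembly <- function(object, ...) {
  ggplot2::ggplot(object$contigs, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "contig length (bp, log scale)", y = "contigs") +
    ggplot2::theme_minimal()
}
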
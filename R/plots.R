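#' Plot a k-mer spectrum
#'
#' Species count against depth, with the detected error cutoff and peaks
#' marked.
#'
#' @param object A `kmer_histogram`.
#' @param peaks Optional `spectrum_peaks` to annotate.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot kmer_histogram
#' @export
autoplot.kmer_histogram <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$depth, y = .data$count)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "k-mer depth", y = "distinct k-mer species",
                  title = sprintf("%d-mer spectrum", attr(object, "k"))) +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    marks <- tibble::tibble(
      depth = c(peaks$error_cutoff, peaks$het_peak, peaks$hom_peak),
      what = c("error cutoff", "het peak", "hom peak"))
    marks <- marks[!is.na(marks$depth), ]
    p <- p + ggplot2::geom_vline(data = marks,
                                 ggplot2::aes(xintercept = .data$depth,
                                              colour = .data$what),
                                 linetype = "dashed") +
      ggplot2::labs(colour = NULL)
  }
  p
}

#' Expression heatmap in dendrogram order
#'
#' Tiles of log10(value + 1) with genes ordered by the average-linkage
#' clustering of their profiles.
#'
#' @param mat Wide expression tibble (`gene_id` + stage columns).
#' @param clustering Optional `profile_clustering`; computed if missing.
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(mat, clustering = NULL) {
  if (is.null(clustering)) clustering <- hcluster_profiles(mat)
  st <- stage_cols(mat)
  long <- tidyr::pivot_longer(mat, dplyr::all_of(st),
                              names_to = "stage", values_to = "value")
  long$stage <- factor(long$stage, levels = st)
  long$gene_id <- factor(long$gene_id, levels = clustering$leaf_order)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$gene_id,
                                     fill = log10(.data$value + 1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10(FPKM+1)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot correspondence-analysis axes against CAI
#'
#' @param object A `codon_ca`.
#' @param cai_values Per-gene CAI in the row order of `object`.
#' @param axis Axis number to plot (default: the most CAI-correlated).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot codon_ca
#' @export
autoplot.codon_ca <- function(object, cai_values, axis = NULL, ...) {
  if (is.null(axis)) axis <- cai_axis(object, cai_values)$axis[1]
  df <- tibble::tibble(coordinate = object$row_coords[, axis],
                       cai = cai_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coordinate, y = .data$cai)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = sprintf("CA axis %d (%.1f%% inertia)", axis,
                              100 * object$inertia_share[axis]),
                  y = "CAI") +
    ggplot2::theme_minimal()
}

#' Nx curve of an assembly
#'
#' @param object An `assembly_metrics`.
#' @param ... Ignored.
#' @return A ggplot object showing Nx against x.
#' @method autoplot assembly_metrics
#' @export
autoplot.assembly_metrics <- function(object, ...) {
  xs <- 1:100
  df <- tibble::tibble(x = xs,
                       nx = vapply(xs, function(p) nx(object$lengths, p),
                                   numeric(1)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$nx)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "cumulative length threshold (%)",
                  y = "Nx (bp)") +
    ggplot2::theme_minimal()
}
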
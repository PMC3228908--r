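#' Ordered log2 AEI distribution plot for one gene
#'
#' Paired gDNA/cDNA bars per sample, sorted by the cDNA log2 AEI ratio
#' from most negative to most positive, with the significance
#' thresholds drawn as horizontal lines. This is the canonical display
#' in which uniphasic, skewed and biphasic patterns are read off.
#'
#' @param aei an [AEITable-class] with corrected records.
#' @param gene gene name.
#' @param threshold significance threshold (default 0.29).
#' @return a ggplot object, or `NULL` (with a warning) if the gene has
#'   no cDNA records.
#' @export
plotDistribution <- function(aei, gene, threshold = 0.29) {
  rec <- aeiRecords(aei)
  rec <- rec[rec$gene == gene, , drop = FALSE]
  cd <- rec[rec$template == "cDNA", , drop = FALSE]
  if (!nrow(cd)) {
    warning("no cDNA records for gene ", gene, "; skipped")
    return(NULL)
  }
  ord <- cd$sample_id[order(cd$log2_ratio)]
  rec$sample_id <- factor(rec$sample_id, levels = ord)
  rec <- rec[!is.na(rec$sample_id), , drop = FALSE]
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$sample_id,
                                    y = .data$log2_ratio,
                                    fill = .data$template)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(gDNA = "#c23b22",
                                          cDNA = "#2b6cb0")) +
    ggplot2::labs(x = "sample (ordered by cDNA log2 AEI)",
                  y = "log2 AEI ratio", title = gene) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Render a distribution plot to an SVG file
#'
#' @param aei an [AEITable-class].
#' @param gene gene name.
#' @param file output path (`.svg`).
#' @param threshold significance threshold.
#' @param width,height device size in inches.
#' @return the path, invisibly (`NULL` if the gene was skipped).
#' @export
renderDistribution <- function(aei, gene, file, threshold = 0.29,
                               width = 7, height = 4) {
  p <- plotDistribution(aei, gene, threshold)
  if (is.null(p)) return(invisible(NULL))
  grDevices::svg(file, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(file)
}
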
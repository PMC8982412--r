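#' Plot an edge image with optional blob overlay
#'
#' Renders the binned count image of one gene pair as a raster (darker =
#' more samples) and, when a blob tibble is supplied, overlays each detected
#' subpopulation as a circle of radius `sqrt(2) * sigma` bins (`sigma` for
#' DoH), colored by detector.
#'
#' @param object An `edge_image` from [bin_edge()].
#' @param blobs Optional blob tibble from [detect_blobs()] /
#'   [detect_all_blobs()].
#' @param log_compress Display intensities after `log1p` compression.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot edge_image
#' @export
autoplot.edge_image <- function(object, blobs = NULL, log_compress = FALSE, ...) {
  norm <- normalize_image(object, log_compress = log_compress)
  df <- tidyr::expand_grid(
    row = seq_len(nrow(norm)) - 1L,
    col = seq_len(ncol(norm)) - 1L
  )
  df$intensity <- norm[cbind(df$row + 1L, df$col + 1L)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "white", high = "black") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "gene A bin", y = "gene B bin", fill = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(blobs) && nrow(blobs) > 0) {
    ang <- seq(0, 2 * pi, length.out = 90)
    circ <- purrr::pmap_dfr(
      list(blobs$row, blobs$col, blobs$sigma, blobs$method,
           seq_len(nrow(blobs))),
      function(r, c, s, m, id) {
        rad <- if (m == "doh") s else sqrt(2) * s
        tibble::tibble(row = r + rad * sin(ang), col = c + rad * cos(ang),
                       method = m, blob = id)
      }
    )
    p <- p + ggplot2::geom_path(
      data = circ,
      ggplot2::aes(x = .data$col, y = .data$row, group = .data$blob,
                   colour = .data$method),
      linewidth = 0.6
    ) +
      ggplot2::labs(colour = "detector")
  }
  p
}

#' Diagnostic plot of one gene pair
#'
#' Convenience wrapper: bins the pair on the matrix-wide grid, detects blobs
#' with all three detectors, and returns the annotated image plot.
#'
#' @param gem GEM matrix.
#' @param gene_a,gene_b Gene identifiers.
#' @param resolution Bin width (default 0.5).
#' @param cfg A [detector_config()].
#' @param log_compress Intensity compression, see [normalize_image()].
#' @return A ggplot object.
#' @export
plot_edge <- function(gem, gene_a, gene_b, resolution = 0.5,
                      cfg = detector_config(), log_compress = FALSE) {
  grid <- bin_grid_from_gem(gem, resolution)
  img <- bin_edge(gem[gene_a, ], gem[gene_b, ], grid)
  norm <- normalize_image(img, log_compress = log_compress)
  blobs <- detect_all_blobs(norm, cfg)
  autoplot.edge_image(img, blobs = blobs, log_compress = log_compress) +
    ggplot2::labs(x = paste(gene_a, "bin"), y = paste(gene_b, "bin"))
}

#' Export an edge image as a TSV matrix
#'
#' Debug helper: writes the raw bin counts (or normalized intensities) as a
#' square tab-separated matrix, rows being gene-B bins from lowest
#' expression.
#'
#' @param img An `edge_image`.
#' @param path Output path.
#' @param normalized Write normalized `[0, 1]` intensities instead of counts.
#' @return `path`, invisibly.
#' @export
write_edge_image <- function(img, path, normalized = FALSE) {
  m <- if (normalized) normalize_image(img) else img$counts
  utils::write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
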
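#' Plot the active-cell percentage over time
#'
#' @param activity an [active_percentage()] result.
#' @return A ggplot object.
#' @export
plot_activity <- function(activity) {
  stopifnot(inherits(activity, "activity_trace"))
  df <- data.frame(time_s = activity$time_s, percent = activity$percent_active)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$percent)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "Time (s)", y = "Active cells (%)") +
    ggplot2::theme_minimal()
}

#' Raster plot of the binarized activity
#'
#' Rows (cells) are ordered by the dendrogram leaf order when a cluster
#' ordering is supplied, grouping co-active cells.
#'
#' @param b a `binary_raster`.
#' @param cluster optional [cluster_traces()] result for row ordering.
#' @return A ggplot object.
#' @export
plot_raster <- function(b, cluster = NULL) {
  stopifnot(inherits(b, "binary_raster"))
  ord <- if (is.null(cluster)) seq_len(nrow(b$values)) else cluster$ordering
  x <- b$values[ord, , drop = FALSE]
  act <- which(x == 1L, arr.ind = TRUE)
  df <- data.frame(
    time_s = (act[, 2L] - 1) * b$frame_interval_s,
    row = act[, 1L])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$row)) +
    ggplot2::geom_tile(width = b$frame_interval_s, height = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Time (s)", y = "Cell (cluster order)") +
    ggplot2::theme_minimal()
}

#' Draw the functional network at the cell coordinates
#'
#' Nodes sit at their image coordinates, colored (and optionally numbered)
#' by community membership when communities have been assigned; edges are
#' the thresholded functional connections.
#'
#' @param g a `functional_graph` whose nodes carry `x`/`y` attributes.
#' @param cell_id `"cell"` to annotate nodes with cell ids, `"communities"`
#'   to annotate with community indices, `"none"` for no annotation.
#' @param label logical; draw the annotations (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_network_graph <- function(g, cell_id = c("none", "cell", "communities"),
                               label = FALSE) {
  stopifnot(inherits(g, "functional_graph"))
  cell_id <- match.arg(cell_id)
  vx <- igraph::V(g$graph)$x
  vy <- igraph::V(g$graph)$y
  if (is.null(vx) || is.null(vy))
    stop("graph nodes carry no coordinates; pass a cell table to build_graph()",
         call. = FALSE)
  comm <- igraph::V(g$graph)$community
  nodes <- data.frame(x = vx, y = vy,
                      name = igraph::V(g$graph)$name,
                      community = if (is.null(comm)) 1L else comm)
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (igraph::ecount(g$graph) > 0L) {
    ends <- igraph::as_edgelist(g$graph, names = FALSE)
    edges <- data.frame(x = vx[ends[, 1L]], y = vy[ends[, 1L]],
                        xend = vx[ends[, 2L]], yend = vy[ends[, 2L]])
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      linewidth = 0.2, alpha = 0.4, color = "grey40")
  }
  p <- p + ggplot2::geom_point(
    ggplot2::aes(color = factor(.data$community)), size = 2) +
    ggplot2::labs(x = "X", y = "Y", color = "Community") +
    ggplot2::theme_minimal()
  if (label && cell_id != "none") {
    nodes$text <- if (cell_id == "cell") nodes$name else nodes$community
    p <- p + ggplot2::geom_text(data = nodes,
                                ggplot2::aes(label = .data$text),
                                size = 2, vjust = -1)
  }
  p
}

#' Scree plot with the five-component marker
#'
#' @param pca a [pca_traces()] result.
#' @return A ggplot object; a vertical line marks the five leading
#'   components summarized by `top5_percent`.
#' @export
plot_scree <- function(pca) {
  stopifnot(inherits(pca, "pca_result"))
  df <- data.frame(component = seq_along(pca$explained_ratio),
                   percent = 100 * pca$explained_ratio)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Principal component", y = "Variance explained (%)") +
    ggplot2::theme_minimal()
  if (pca$n_components >= 5L)
    p <- p + ggplot2::geom_vline(xintercept = 5.5, color = "red",
                                 linetype = "dashed")
  p
}

#' Power spectral density plot
#'
#' One line per cell plus the population mean spectrum.
#'
#' @param psd a [welch_psd()] result.
#' @return A ggplot object.
#' @export
plot_psd <- function(psd) {
  stopifnot(inherits(psd, "psd_result"))
  cells <- rownames(psd$power)
  if (is.null(cells)) cells <- as.character(seq_len(nrow(psd$power)))
  df <- data.frame(
    freq_hz = rep(psd$freqs_hz, each = nrow(psd$power)),
    power = as.vector(psd$power),
    cell = rep(cells, times = length(psd$freqs_hz)))
  mean_df <- data.frame(freq_hz = psd$freqs_hz, power = colMeans(psd$power))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$power,
                                   group = .data$cell)) +
    ggplot2::geom_line(alpha = 0.15, linewidth = 0.2) +
    ggplot2::geom_line(data = mean_df, ggplot2::aes(group = NULL),
                       color = "red", linewidth = 0.6) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power spectral density") +
    ggplot2::theme_minimal()
}

#' Render the pipeline figures to files
#'
#' Writes (a) the population-activity trace, (b) the clustered raster,
#' (c) the network plot at spatial coordinates with community coding,
#' (d) the scree plot and (e) the PSD plot, in each requested device
#' format. The network figure is skipped (with a message) when the graph
#' carries no coordinates.
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @param formats any of `"png"`, `"svg"`.
#' @param cell_id,label forwarded to [plot_network_graph()].
#' @param dendrogram reserved flag for adding the dendrogram margin to the
#'   raster; currently the raster rows are ordered by the dendrogram and the
#'   tree itself is not drawn.
#' @return Invisibly, a character vector of the files written.
#' @export
render_figures <- function(report, out_dir, formats = c("png", "svg"),
                           cell_id = "none", label = FALSE,
                           dendrogram = FALSE) {
  stopifnot(inherits(report, "pipeline_report"))
  formats <- match.arg(formats, c("png", "svg"), several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  it <- report$intermediates
  if (is.null(it$activity))
    stop("pipeline report is missing the 'activity' artifact", call. = FALSE)
  plots <- list(activity = plot_activity(it$activity),
                raster = plot_raster(it$raster, it$cluster),
                scree = plot_scree(it$pca),
                psd = plot_psd(it$psd))
  has_coords <- !is.null(igraph::V(it$graph$graph)$x)
  if (has_coords) {
    plots$network <- plot_network_graph(it$graph, cell_id = cell_id,
                                        label = label)
  } else message("graph has no coordinates; skipping the network figure")
  written <- character(0)
  for (nm in names(plots)) {
    for (fmt in formats) {
      path <- file.path(out_dir, paste0(nm, ".", fmt))
      dev <- switch(fmt,
                    png = function(f) grDevices::png(f, width = 1200,
                                                     height = 800, res = 150),
                    svg = function(f) grDevices::svg(f, width = 8, height = 5.5))
      dev(path)
      print(plots[[nm]])
      grDevices::dev.off()
      written <- c(written, path)
    }
  }
  invisible(written)
}
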
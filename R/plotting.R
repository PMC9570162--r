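#' Display options for dot plots
#'
#' Collects the rendering options: labels, strand colours, optional
#' per-query colours, marker and line sizes (printer points) and the image
#' format. Forward-strand matches are drawn as ascending diagonals in
#' `forward_color` (default blue), reverse-strand matches as descending
#' diagonals in `reverse_color` (default red), following the usual dot-plot
#' convention.
#'
#' @param title Plot title.
#' @param xlabel,ylabel Axis labels.
#' @param show_legend Draw a strand legend (default `TRUE`).
#' @param point_size Size of segment endpoint markers, in points; `0`
#'   suppresses markers.
#' @param line_width Segment line width, in points.
#' @param forward_color,reverse_color Strand colours.
#' @param per_query_colors Optional named vector/list, query id -> colour;
#'   used in `rearranged` mode to colour whole queries instead of strands.
#' @param format One of `"pdf"` (default), `"png"`, `"ps"`, `"svg"`.
#' @return An object of class `plot_spec`.
#' @export
plot_spec <- function(title = "", xlabel = "Reference position (bp)",
                      ylabel = "Query position (bp)", show_legend = TRUE,
                      point_size = 2, line_width = 1.5,
                      forward_color = "blue", reverse_color = "red",
                      per_query_colors = NULL,
                      format = c("pdf", "png", "ps", "svg")) {
  if (is.character(format) && length(format) == 1L &&
      !format %in% c("pdf", "png", "ps", "svg"))
    stop_param("unsupported image format '%s' (use pdf, png, ps or svg)",
               format)
  format <- match.arg(format)
  if (!is.numeric(point_size) || point_size < 0)
    stop_param("point_size must be >= 0")
  if (!is.numeric(line_width) || line_width <= 0)
    stop_param("line_width must be > 0")
  structure(
    list(title = title, xlabel = xlabel, ylabel = ylabel,
         show_legend = isTRUE(show_legend), point_size = point_size,
         line_width = line_width, forward_color = forward_color,
         reverse_color = reverse_color,
         per_query_colors = per_query_colors, format = format),
    class = "plot_spec"
  )
}

#' Stack queries along the y axis
#'
#' Multiple queries share one dot plot by stacking: each query occupies a
#' horizontal band whose height is its length, and `offsets` gives the
#' y-axis origin of each band (prefix sums of query lengths in stacking
#' order).
#'
#' @param results List of `query_result` objects.
#' @param order Character vector: a permutation of the result query ids,
#'   bottom band first. Defaults to input order.
#' @return An object of class `stack_layout`: list with `order`, `offsets`
#'   (named numeric, bp) and `total_height` (bp).
#' @export
layout_queries <- function(results,
                           order = vapply(results, function(r) r$query$id, "")) {
  results <- check_results(results)
  ids <- vapply(results, function(r) r$query$id, "")
  if (length(order) != length(ids) || !setequal(order, ids) ||
      anyDuplicated(order))
    stop_usage("order must be a permutation of the query ids")
  lens <- vapply(results, function(r) r$query$length, 0)[match(order, ids)]
  offsets <- cumsum(c(0, lens[-length(lens)]))
  names(offsets) <- order
  structure(
    list(order = order, offsets = offsets, total_height = sum(lens)),
    class = "stack_layout"
  )
}

#' Render a dot plot of the alignment
#'
#' Draws one diagonal line per matched segment: x spans the reference
#' interval, y spans the query interval inside the query's stacked band.
#' Forward-strand segments ascend, reverse-strand segments descend. Mode
#' `basic` plots every merged segment; `optimal` and `rearranged` plot only
#' the tiled (non-overlapping) segments, the latter conventionally with a
#' similarity-ranked layout. Thin horizontal separators mark query band
#' boundaries. The file format is taken from `spec$format`.
#'
#' @param results List of `query_result` objects.
#' @param layout A [layout_queries()] result covering the same queries.
#' @param mode `"basic"`, `"optimal"` or `"rearranged"`.
#' @param spec A [plot_spec()].
#' @param path Output image path.
#' @return `path`, invisibly.
#' @export
render_dotplot <- function(results, layout,
                           mode = c("basic", "optimal", "rearranged"),
                           spec = plot_spec(), path) {
  results <- check_results(results)
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "stack_layout"), inherits(spec, "plot_spec"))
  ids <- vapply(results, function(r) r$query$id, "")
  if (!setequal(layout$order, ids))
    stop_usage("layout does not cover the result query ids")
  if (!dir.exists(dirname(path)))
    stop_io("directory does not exist: %s", dirname(path))

  open_device(spec$format, path)
  on.exit(grDevices::dev.off(), add = TRUE)

  ref_length <- results[[1L]]$ref_length
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, ref_length),
                        ylim = c(0, layout$total_height),
                        xaxs = "i", yaxs = "i")
  graphics::axis(1); graphics::axis(2)
  graphics::title(main = spec$title, xlab = spec$xlabel, ylab = spec$ylabel)
  graphics::box()
  if (length(layout$offsets) > 1L)
    graphics::abline(h = layout$offsets[-1L], col = "grey75", lty = 3)

  for (r in results) {
    segs <- if (mode == "basic") r$basic_segments else r$tiling$segments
    if (nrow(segs) == 0L) next
    off <- layout$offsets[[r$query$id]]
    fwd <- segs$strand == "forward"
    col <- ifelse(fwd, spec$forward_color, spec$reverse_color)
    if (mode == "rearranged" && !is.null(spec$per_query_colors) &&
        r$query$id %in% names(spec$per_query_colors))
      col <- rep(spec$per_query_colors[[r$query$id]], nrow(segs))
    y0 <- off + ifelse(fwd, segs$query_start, segs$query_end)
    y1 <- off + ifelse(fwd, segs$query_end, segs$query_start)
    graphics::segments(segs$ref_start, y0, segs$ref_end, y1,
                       col = col, lwd = spec$line_width)
    if (spec$point_size > 0)
      graphics::points(c(segs$ref_start, segs$ref_end), c(y0, y1),
                       col = col, pch = 20,
                       cex = spec$point_size / 12)
  }
  if (spec$show_legend)
    graphics::legend("topright",
                     legend = c("forward (5'->3')", "reverse (3'->5')"),
                     col = c(spec$forward_color, spec$reverse_color),
                     lwd = spec$line_width, bg = "white", cex = 0.8)
  invisible(path)
}

open_device <- function(format, path, width = 8, height = 6) {
  tryCatch(
    switch(format,
      pdf = grDevices::pdf(path, width = width, height = height),
      png = grDevices::png(path, width = width * 150, height = height * 150,
                           res = 150),
      ps = grDevices::postscript(path, width = width, height = height,
                                 paper = "special", horizontal = FALSE),
      svg = grDevices::svg(path, width = width, height = height),
      stop_param("unsupported image format '%s'", format)
    ),
    error = function(e) {
      if (inherits(e, "contigdot_error")) stop(e)
      stop_io("cannot open %s device for %s: %s", format, path,
              conditionMessage(e))
    }
  )
}
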
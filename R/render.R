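# Dot-plot rendering: layout -> drawn-primitive inventory -> multi-panel PDF

#' Dot-plot style
#'
#' Orientation colouring follows the MUMmer-plot convention: purple for
#' forward matches, cyan for reverse matches.
#'
#' @param forward_color,reverse_color Colours for forward / reverse
#'   segments; must differ.
#' @param lwd Line width of segment glyphs.
#' @return An object of class `plot_style`.
#' @export
plot_style <- function(forward_color = "purple", reverse_color = "cyan",
                       lwd = 1.5) {
  if (identical(forward_color, reverse_color)) {
    stop("forward and reverse colours must be distinct", call. = FALSE)
  }
  structure(list(forward_color = forward_color,
                 reverse_color = reverse_color, lwd = lwd),
            class = "plot_style")
}

#' Drawn-primitive inventory of a layout
#'
#' Deterministic mapping from a layout (plus style) to the line segments
#' that the PDF will contain: one row per segment with absolute plot
#' coordinates. The query axis concatenates the contigs in `contig_order`
#' (cumulative offsets); reverse segments run anti-diagonally (y decreasing
#' as x increases). Rendering draws exactly these primitives, so two
#' renders of the same inputs draw the same inventory.
#'
#' @param layout A `dotplot_layout` from [build_layout()].
#' @param style A [plot_style()] object.
#' @return Data frame: `panel`, `contig_id`, `x0`, `x1`, `y0`, `y1`,
#'   `orientation`, `color`.
#' @export
layout_primitives <- function(layout, style = plot_style()) {
  stopifnot(inherits(layout, "dotplot_layout"), inherits(style, "plot_style"))
  out <- lapply(layout$panels, function(p) {
    s <- p$segments
    if (nrow(s) == 0L) return(NULL)
    off <- layout$offsets[s$contig_id]
    fwd <- s$orientation == "forward"
    data.frame(panel = p$ref_id,
               contig_id = s$contig_id,
               x0 = off + s$q_start,
               x1 = off + s$q_end,
               y0 = ifelse(fwd, s$r_start, s$r_end),
               y1 = ifelse(fwd, s$r_end, s$r_start),
               orientation = s$orientation,
               color = ifelse(fwd, style$forward_color, style$reverse_color),
               stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  out <- if (length(out)) {
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  }
  if (is.null(out)) {
    out <- data.frame(panel = character(), contig_id = character(),
                      x0 = numeric(), x1 = numeric(), y0 = numeric(),
                      y1 = numeric(), orientation = character(),
                      color = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Render a dot-plot layout to a multi-panel PDF
#'
#' One panel per reference (query contigs concatenated on the x axis with
#' boundaries ticked, reference on the y axis), arranged on a near-square
#' grid. Forward segments are drawn in `style$forward_color`, reverse in
#' `style$reverse_color`; axis labels carry sequence ids and lengths.
#'
#' @param layout A `dotplot_layout`.
#' @param style A [plot_style()] object.
#' @param path Output PDF path.
#' @return `path`, invisibly.
#' @export
render_pdf <- function(layout, style = plot_style(), path) {
  stopifnot(inherits(layout, "dotplot_layout"))
  prims <- layout_primitives(layout, style)
  n <- max(1L, length(layout$panels))
  ncol <- ceiling(sqrt(n))
  nrow <- ceiling(n / ncol)
  total_q <- sum(layout$query_lengths)
  ok <- tryCatch({
    grDevices::pdf(path, width = 4.2 * ncol, height = 4.2 * nrow)
    TRUE
  }, error = function(e) {
    stop("cannot write PDF to ", path, " (", conditionMessage(e), ")",
         call. = FALSE)
  })
  on.exit(grDevices::dev.off(), add = TRUE)
  op <- graphics::par(mfrow = c(nrow, ncol), mar = c(4, 4, 2.5, 1))
  # restore par while the PDF device is still current, before dev.off()
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  bounds <- cumsum(as.numeric(layout$query_lengths[layout$contig_order]))
  for (p in layout$panels) {
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, max(total_q, 1)),
                          ylim = c(0, max(p$ref_len, 1)))
    graphics::box()
    graphics::axis(1, at = pretty(c(0, total_q)))
    graphics::axis(2, at = pretty(c(0, p$ref_len)))
    # tick contig boundaries along the query axis
    graphics::axis(1, at = c(0, bounds), labels = FALSE, tcl = 0.4,
                   col.ticks = "grey40")
    graphics::title(main = sprintf("%s (%d bp)", p$ref_id, p$ref_len),
                    xlab = sprintf("query contigs (%d, %d bp total)",
                                   length(layout$contig_order), total_q),
                    ylab = p$ref_id)
    pr <- prims[prims$panel == p$ref_id, , drop = FALSE]
    if (nrow(pr)) {
      graphics::segments(pr$x0, pr$y0, pr$x1, pr$y1, col = pr$color,
                         lwd = style$lwd)
    }
  }
  invisible(path)
}
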
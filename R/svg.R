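# Deterministic standalone SVG renderings of the presentation payloads.
# Styling lives in a config list (JSON-loadable) and is excluded from all
# correctness assertions; geometry is derived from the payload objects.

#' SVG style configuration
#'
#' Cosmetic parameters for [render_svg()]. `width`, `height` and `margin`
#' (pixels) also define the pixel mapping of the figure; the remaining
#' entries are purely cosmetic. `nomogram_ymax` is the ordinate (base-10
#' log-odds) clipped to the top/bottom of the nomogram panel.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of style settings.
#' @export
svg_style <- function(...) {
  style <- list(
    width = 480, height = 600, margin = 50,
    font_family = "Helvetica, Arial, sans-serif", font_size = 12,
    background = "#ffffff", axis_color = "#333333",
    overlay_color = "#d62728", positive_color = "#1f77b4",
    negative_color = "#2ca02c", box_fill = "#eef3f8", nomogram_ymax = 3)
  over <- list(...)
  unknown <- setdiff(names(over), names(style))
  if (length(unknown)) {
    stop("unknown style keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  style[names(over)] <- over
  style
}

#' Load an SVG style from a JSON file
#'
#' @param path Path to a JSON object of style overrides.
#' @return A style list as from [svg_style()].
#' @export
svg_style_from_json <- function(path) {
  do.call(svg_style, jsonlite::fromJSON(path, simplifyVector = TRUE))
}

# Fixed-precision coordinate formatting keeps output byte-deterministic.
px <- function(x) formatC(x, format = "f", digits = 2)

svg_open <- function(style) {
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            style$width, style$height, style$width, style$height),
    sprintf('<rect width="%d" height="%d" fill="%s"/>',
            style$width, style$height, style$background))
}

svg_text_el <- function(x, y, label, style, anchor = "middle", size = NULL) {
  sprintf('<text x="%s" y="%s" text-anchor="%s" font-family="%s" font-size="%d">%s</text>',
          px(x), px(y), anchor, style$font_family,
          if (is.null(size)) style$font_size else size, label)
}

svg_line_el <- function(x1, y1, x2, y2, color, width = 1, class = NULL) {
  sprintf('<line%s x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
          if (is.null(class)) "" else sprintf(' class="%s"', class),
          px(x1), px(y1), px(x2), px(y2), color, format(width))
}

#' Render a presentation payload as a standalone SVG document
#'
#' Output is deterministic: identical payload and style give byte-identical
#' SVG. The nomogram draws its three axes with ticks plus the overlay line;
#' the frequency tree draws labelled count boxes; the probability-modifying
#' plot draws both result curves; the text summary is wrapped into lines.
#'
#' @param payload Object built by [frequency_tree()], [nomogram_geometry()],
#'   [pmp_curves()] or [text_summary()].
#' @param file Optional path; when given the document is written there.
#' @param style A [svg_style()] list.
#' @param format Optional expected format (`"tree"`, `"nomogram"`, `"pmp"`,
#'   `"text"`); an error is raised if it does not match the payload class.
#' @return The SVG document as a single character string (invisibly when
#'   `file` is given).
#' @export
render_svg <- function(payload, file = NULL, style = svg_style(), format = NULL) {
  kind <- switch(class(payload)[1],
                 frequency_tree = "tree", nomogram_geometry = "nomogram",
                 pmp_curves = "pmp", text_summary = "text",
                 stop("unsupported payload: build it with frequency_tree(), ",
                      "nomogram_geometry(), pmp_curves() or text_summary()",
                      call. = FALSE))
  if (!is.null(format) && !identical(format, kind)) {
    stop("mismatched payload: expected format '", format, "' but payload is '",
         kind, "'", call. = FALSE)
  }
  body <- switch(kind,
                 tree = svg_tree(payload, style),
                 nomogram = svg_nomogram(payload, style),
                 pmp = svg_pmp(payload, style),
                 text = svg_textblock(payload, style))
  doc <- paste(c(svg_open(style), body, "</svg>"), collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

# Pixel mapping shared by nomogram drawing and its parse-back tests:
# x in [0, 1] -> margin + x * (width - 2 * margin)
# ordinate v  -> height / 2 - v * (height / 2 - margin) / nomogram_ymax
nomogram_px <- function(style) {
  list(x = function(u) style$margin + u * (style$width - 2 * style$margin),
       y = function(v) style$height / 2 -
         v * (style$height / 2 - style$margin) / style$nomogram_ymax)
}

svg_nomogram <- function(g, style) {
  map <- nomogram_px(style)
  ymax <- style$nomogram_ymax
  out <- character(0)
  axes <- list(list(x = 0, ticks = g$left_axis$ordinate,
                    labels = fmt_percent(g$left_axis$probability, 1),
                    title = "pre-test probability", anchor = "end", side = -6),
               list(x = 0.5, ticks = g$middle_axis$ordinate,
                    labels = vapply(g$middle_axis$lr, fmt_ratio, "", digits = 3),
                    title = "likelihood ratio", anchor = "start", side = 6),
               list(x = 1, ticks = g$right_axis$ordinate,
                    labels = fmt_percent(g$right_axis$probability, 1),
                    title = "post-test probability", anchor = "start", side = 6))
  for (ax in axes) {
    xp <- map$x(ax$x)
    out <- c(out, svg_line_el(xp, map$y(ymax), xp, map$y(-ymax), style$axis_color))
    keep <- abs(ax$ticks) <= ymax
    for (i in which(keep)) {
      yp <- map$y(ax$ticks[i])
      out <- c(out,
               svg_line_el(xp - 3, yp, xp + 3, yp, style$axis_color),
               svg_text_el(xp + ax$side, yp + 4, ax$labels[i], style,
                           anchor = ax$anchor, size = 9))
    }
    out <- c(out, svg_text_el(xp, style$margin - 20, ax$title, style, size = 11))
  }
  out <- c(out, svg_line_el(map$x(0), map$y(g$line[["left"]]),
                            map$x(1), map$y(g$line[["right"]]),
                            style$overlay_color, width = 2, class = "overlay"))
  out
}

svg_tree <- function(tree, style) {
  w <- style$width
  node <- function(x, y, count, label) {
    c(sprintf('<rect x="%s" y="%s" width="90" height="44" rx="6" fill="%s" stroke="%s"/>',
              px(x - 45), px(y - 22), style$box_fill, style$axis_color),
      svg_text_el(x, y - 2, count, style),
      svg_text_el(x, y + 14, label, style, size = 9))
  }
  edge <- function(x1, y1, x2, y2) {
    svg_line_el(x1, y1 + 22, x2, y2 - 22, style$axis_color)
  }
  y1 <- 80; y2 <- 250; y3 <- 430
  xs <- w * c(0.5, 0.27, 0.73, 0.14, 0.4, 0.6, 0.86)
  c(edge(xs[1], y1, xs[2], y2), edge(xs[1], y1, xs[3], y2),
    edge(xs[2], y2, xs[4], y3), edge(xs[2], y2, xs[5], y3),
    edge(xs[3], y2, xs[6], y3), edge(xs[3], y2, xs[7], y3),
    node(xs[1], y1, tree$total, "patients"),
    node(xs[2], y2, tree$diseased, "with disease"),
    node(xs[3], y2, tree$nondiseased, "without disease"),
    node(xs[4], y3, tree$tp, "test positive"),
    node(xs[5], y3, tree$fn, "test negative"),
    node(xs[6], y3, tree$fp, "test positive"),
    node(xs[7], y3, tree$tn, "test negative"))
}

svg_pmp <- function(pm, style) {
  m <- style$margin
  plot_w <- style$width - 2 * m
  plot_h <- style$height - 2 * m
  xpx <- function(p) m + p * plot_w
  ypx <- function(p) style$height - m - p * plot_h
  poly <- function(xs, ys, color) {
    pts <- paste(px(xpx(xs)), px(ypx(ys)), sep = ",", collapse = " ")
    sprintf('<polyline points="%s" fill="none" stroke="%s" stroke-width="2"/>',
            pts, color)
  }
  ticks <- seq(0, 1, by = 0.2)
  out <- c(svg_line_el(xpx(0), ypx(0), xpx(1), ypx(0), style$axis_color),
           svg_line_el(xpx(0), ypx(0), xpx(0), ypx(1), style$axis_color))
  for (t in ticks) {
    out <- c(out,
             svg_line_el(xpx(t), ypx(0), xpx(t), ypx(0) + 4, style$axis_color),
             svg_text_el(xpx(t), ypx(0) + 16, fmt_percent(t, 0), style, size = 9),
             svg_line_el(xpx(0) - 4, ypx(t), xpx(0), ypx(t), style$axis_color),
             svg_text_el(xpx(0) - 8, ypx(t) + 4, fmt_percent(t, 0), style,
                         anchor = "end", size = 9))
  }
  c(out,
    poly(pm$pretest_grid, pm$post_positive, style$positive_color),
    poly(pm$pretest_grid, pm$post_negative, style$negative_color),
    svg_text_el(style$width / 2, style$height - 12, "pre-test probability", style),
    svg_text_el(style$width / 2, 20, "post-test probability by test result", style))
}

svg_textblock <- function(ts, style) {
  lines <- strwrap(ts$text, width = 60)
  vapply(seq_along(lines), function(i) {
    svg_text_el(style$margin, style$margin + i * (style$font_size + 6),
                lines[i], style, anchor = "start")
  }, character(1))
}
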
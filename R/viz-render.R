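#' Chart specification for in-glyph data display
#'
#' Describes how mapped measurements are drawn inside node glyphs:
#' \code{bar} (one bar per condition, replicate means), \code{line}
#' (condition profile polyline), \code{pie} (share of positive means) or
#' \code{heatmap} (one colored cell per condition).
#'
#' @param kind chart kind.
#' @param palette fill colors cycled across conditions.
#' @export
chart_spec <- function(kind = c("bar", "line", "pie", "heatmap"),
                       palette = c("#4477aa", "#ee6677", "#228833", "#ccbb44",
                                   "#66ccee", "#aa3377")) {
  structure(list(kind = match.arg(kind), palette = palette),
            class = "omic_chart_spec")
}

node_box <- function(g, n) {
  c(x = as.numeric(og_get_attr(g, "node", n, "graphics.x", default = NA)),
    y = as.numeric(og_get_attr(g, "node", n, "graphics.y", default = NA)),
    w = as.numeric(og_get_attr(g, "node", n, "graphics.w", default = 60)),
    h = as.numeric(og_get_attr(g, "node", n, "graphics.h", default = 40)))
}

edge_thicknesses <- function(g, thickness_attr, t_range) {
  if (length(g$edge_id) == 0) return(numeric())
  if (is.null(thickness_attr)) {
    return(vapply(g$edge_id, function(e)
      as.numeric(og_get_attr(g, "edge", e, "graphics.thickness", default = 1)),
      numeric(1)))
  }
  v <- vapply(g$edge_id, function(e)
    as.numeric(og_get_attr(g, "edge", e, thickness_attr, default = 0)), numeric(1))
  vmax <- max(abs(v))
  if (vmax == 0) return(rep(t_range[1], length(v)))
  t_range[1] + (t_range[2] - t_range[1]) * abs(v) / vmax
}

#' Render a network as SVG or PNG
#'
#' Draws one glyph per node (shape by \code{sbgn_class}: ellipse for simple
#' chemicals, rounded rectangle for macromolecules, small square for
#' processes), an embedded chart of the mapped data ordered by condition,
#' and edges whose stroke width can be driven linearly by an attribute such
#' as a flux value: \code{width = t_min + (t_max - t_min)|v|/max|v|}.
#' Rendering is pure — the graph is not modified.  Nodes without
#' coordinates trigger an automatic force-directed fallback layout (with a
#' warning).
#'
#' @param g graph (layout present, or a fallback is applied).
#' @param path output file. @param format \code{"svg"} or \code{"png"}.
#' @param charts optional \code{\link{chart_spec}} drawn on mapped nodes.
#' @param thickness_attr optional edge attribute path driving stroke width.
#' @param t_range stroke-width range c(min, max) for the linear flux map.
#' @return the path, invisibly.
#' @export
render_network <- function(g, path, format = c("svg", "png"), charts = NULL,
                           thickness_attr = NULL, t_range = c(1, 8)) {
  check_graph(g)
  format <- match.arg(format)
  has_xy <- vapply(g$nodes, function(n)
    !is.null(og_get_attr(g, "node", n, "graphics.x")), logical(1))
  if (length(has_xy) && !all(has_xy)) {
    warn2("nodes without coordinates: applying force_directed fallback layout")
    g <- layout_network(g, "force_directed")
  }
  if (format == "svg") render_svg(g, path, charts, thickness_attr, t_range)
  else render_png(g, path, charts, thickness_attr, t_range)
  invisible(path)
}

svg_esc <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

render_svg <- function(g, path, charts, thickness_attr, t_range) {
  boxes <- lapply(g$nodes, function(n) node_box(g, n))
  names(boxes) <- g$nodes
  W <- max(c(200, vapply(boxes, function(b) b["x"] + b["w"], numeric(1))), na.rm = TRUE) + 60
  H <- max(c(200, vapply(boxes, function(b) b["y"] + b["h"], numeric(1))), na.rm = TRUE) + 60
  out <- c(sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                          "width=\"%.0f\" height=\"%.0f\" viewBox=\"0 0 %.0f %.0f\">"),
                   W, H, W, H),
           "<rect width=\"100%\" height=\"100%\" fill=\"white\"/>")
  thick <- edge_thicknesses(g, thickness_attr, t_range)
  for (i in seq_along(g$edge_id)) {
    b1 <- boxes[[g$edge_src[i]]]; b2 <- boxes[[g$edge_dst[i]]]
    col <- og_get_attr(g, "edge", g$edge_id[i], "graphics.fill", default = "#888888")
    out <- c(out, sprintf(
      "<line class=\"edge\" x1=\"%.1f\" y1=\"%.1f\" x2=\"%.1f\" y2=\"%.1f\" stroke=\"%s\" stroke-width=\"%.2f\"/>",
      b1["x"], b1["y"], b2["x"], b2["y"], col, thick[i]))
  }
  for (n in g$nodes) {
    b <- boxes[[n]]
    cls <- og_get_attr(g, "node", n, "sbgn_class", default = "unspecified")
    fill <- og_get_attr(g, "node", n, "graphics.fill",
                        default = sbgn_default_fill(cls))
    frame <- og_get_attr(g, "node", n, "graphics.frame", default = "#333333")
    out <- c(out, sprintf("<g class=\"node\" id=\"node-%s\">", svg_esc(n)))
    shape <- switch(cls,
      simple_chemical = sprintf(
        "<ellipse cx=\"%.1f\" cy=\"%.1f\" rx=\"%.1f\" ry=\"%.1f\" fill=\"%s\" stroke=\"%s\"/>",
        b["x"], b["y"], b["w"] / 2, b["h"] / 2, fill, frame),
      process = sprintf(
        "<rect x=\"%.1f\" y=\"%.1f\" width=\"12\" height=\"12\" fill=\"%s\" stroke=\"%s\"/>",
        b["x"] - 6, b["y"] - 6, fill, frame),
      sprintf(
        "<rect x=\"%.1f\" y=\"%.1f\" width=\"%.1f\" height=\"%.1f\" rx=\"%.1f\" fill=\"%s\" stroke=\"%s\"/>",
        b["x"] - b["w"] / 2, b["y"] - b["h"] / 2, b["w"], b["h"],
        if (cls == "macromolecule") 8 else 0, fill, frame))
    out <- c(out, shape)
    if (!is.null(charts)) {
      prof <- tryCatch(og_node_profile(g, n), error = function(e) NULL)
      if (!is.null(prof) && length(prof) > 0 && any(is.finite(prof)))
        out <- c(out, svg_chart(charts, prof, b))
    }
    lab <- og_label(g, n)
    out <- c(out, sprintf(
      "<text x=\"%.1f\" y=\"%.1f\" font-size=\"9\" text-anchor=\"middle\">%s</text>",
      b["x"], b["y"] + b["h"] / 2 + 10, svg_esc(lab)), "</g>")
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
}

svg_chart <- function(spec, prof, b) {
  prof[!is.finite(prof)] <- 0
  m <- length(prof)
  pal <- rep(spec$palette, length.out = m)
  x0 <- b["x"] - b["w"] / 2 + 2; y0 <- b["y"] - b["h"] / 2 + 2
  cw <- (b["w"] - 4); ch <- (b["h"] - 4)
  rng <- range(c(0, prof))
  lines <- "<g class=\"chart\">"
  if (spec$kind == "bar") {
    bw <- cw / m
    for (k in seq_len(m)) {
      frac <- if (diff(rng) == 0) 0.5 else (prof[k] - rng[1]) / diff(rng)
      hgt <- max(0.5, frac * ch)
      lines <- c(lines, sprintf(
        "<rect x=\"%.1f\" y=\"%.1f\" width=\"%.1f\" height=\"%.1f\" fill=\"%s\"/>",
        x0 + (k - 1) * bw, y0 + ch - hgt, bw * 0.85, hgt, pal[k]))
    }
  } else if (spec$kind == "line") {
    frac <- if (diff(rng) == 0) rep(0.5, m) else (prof - rng[1]) / diff(rng)
    pts <- paste(sprintf("%.1f,%.1f", x0 + (seq_len(m) - 0.5) / m * cw,
                         y0 + ch - frac * ch), collapse = " ")
    lines <- c(lines, sprintf(
      "<polyline points=\"%s\" fill=\"none\" stroke=\"%s\" stroke-width=\"1.2\"/>",
      pts, pal[1]))
  } else if (spec$kind == "pie") {
    tot <- sum(abs(prof))
    if (tot > 0) {
      cx <- b["x"]; cy <- b["y"]; r <- min(cw, ch) / 2
      a0 <- -pi / 2
      for (k in seq_len(m)) {
        a1 <- a0 + 2 * pi * abs(prof[k]) / tot
        large <- as.integer((a1 - a0) > pi)
        lines <- c(lines, sprintf(
          "<path d=\"M%.1f,%.1f L%.1f,%.1f A%.1f,%.1f 0 %d 1 %.1f,%.1f Z\" fill=\"%s\"/>",
          cx, cy, cx + r * cos(a0), cy + r * sin(a0), r, r, large,
          cx + r * cos(a1), cy + r * sin(a1), pal[k]))
        a0 <- a1
      }
    }
  } else if (spec$kind == "heatmap") {
    bw <- cw / m
    z <- if (diff(rng) == 0) rep(0, m) else 2 * (prof - rng[1]) / diff(rng) - 1
    for (k in seq_len(m)) {
      lines <- c(lines, sprintf(
        "<rect x=\"%.1f\" y=\"%.1f\" width=\"%.1f\" height=\"%.1f\" fill=\"%s\"/>",
        x0 + (k - 1) * bw, y0, bw, ch, correlation_color(z[k])))
    }
  }
  c(lines, "</g>")
}

render_png <- function(g, path, charts, thickness_attr, t_range) {
  boxes <- lapply(g$nodes, function(n) node_box(g, n))
  names(boxes) <- g$nodes
  W <- max(c(200, vapply(boxes, function(b) b["x"] + b["w"], numeric(1))), na.rm = TRUE) + 60
  H <- max(c(200, vapply(boxes, function(b) b["y"] + b["h"], numeric(1))), na.rm = TRUE) + 60
  grDevices::png(path, width = W, height = H, type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot(NULL, xlim = c(0, W), ylim = c(H, 0), asp = 1,
                 axes = FALSE, xlab = "", ylab = "")
  thick <- edge_thicknesses(g, thickness_attr, t_range)
  for (i in seq_along(g$edge_id)) {
    b1 <- boxes[[g$edge_src[i]]]; b2 <- boxes[[g$edge_dst[i]]]
    col <- og_get_attr(g, "edge", g$edge_id[i], "graphics.fill", default = "#888888")
    graphics::segments(b1["x"], b1["y"], b2["x"], b2["y"], col = col, lwd = thick[i])
  }
  for (n in g$nodes) {
    b <- boxes[[n]]
    cls <- og_get_attr(g, "node", n, "sbgn_class", default = "unspecified")
    fill <- og_get_attr(g, "node", n, "graphics.fill",
                        default = sbgn_default_fill(cls))
    if (cls == "simple_chemical")
      graphics::symbols(b["x"], b["y"], circles = b["w"] / 2, inches = FALSE,
                        add = TRUE, bg = fill, fg = "#333333")
    else
      graphics::rect(b["x"] - b["w"] / 2, b["y"] - b["h"] / 2,
                     b["x"] + b["w"] / 2, b["y"] + b["h"] / 2,
                     col = fill, border = "#333333")
    graphics::text(b["x"], b["y"] + b["h"] / 2 + 10, og_label(g, n), cex = 0.6)
  }
}

#' Export a clickable HTML image map
#'
#' Renders the network to an image and writes an \code{index.html} with one
#' client-side \code{<area>} region per node (covering the node's bounding
#' box); nodes carrying a \code{"url"} attribute become hyperlinks.
#'
#' @param g laid-out graph. @param dir output directory (created).
#' @return named list of written paths (\code{html}, \code{image}).
#' @export
export_html <- function(g, dir) {
  check_graph(g)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  use_png <- isTRUE(unname(capabilities("png")))
  img <- file.path(dir, if (use_png) "network.png" else "network.svg")
  render_network(g, img, if (use_png) "png" else "svg")
  areas <- character()
  for (n in g$nodes) {
    b <- node_box(g, n)
    if (!is.finite(b["x"])) next
    url <- og_get_attr(g, "node", n, "url")
    areas <- c(areas, sprintf(
      "<area shape=\"rect\" coords=\"%.0f,%.0f,%.0f,%.0f\" title=\"%s\"%s>",
      b["x"] - b["w"] / 2, b["y"] - b["h"] / 2,
      b["x"] + b["w"] / 2, b["y"] + b["h"] / 2,
      svg_esc(og_label(g, n)),
      if (is.null(url)) "" else sprintf(" href=\"%s\"", svg_esc(url))))
  }
  html <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
            "<title>network</title></head><body>",
            sprintf("<img src=\"%s\" usemap=\"#netmap\" alt=\"network\">",
                    basename(img)),
            "<map name=\"netmap\">", areas, "</map>", "</body></html>")
  hf <- file.path(dir, "index.html")
  writeLines(html, hf)
  list(html = hf, image = img)
}
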
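#' Automatic network layouts
#'
#' Writes \code{graphics.x}/\code{graphics.y} (screen convention: origin
#' top-left, y growing downward, node anchor = center) for every node.
#' Algorithms: \code{force_directed} (seeded Fruchterman-Reingold;
#' deterministic per seed, with a post-pass nudging exactly coincident
#' nodes apart), \code{circle}, \code{grid}, \code{tree} (directed input
#' must be acyclic), and \code{pathway_circles}, which places each
#' pathway's nodes (node attribute \code{"pathway"}) on its own circle and
#' the circles on an outer ring — the layout of the pathway-level
#' correlation-network figure.
#'
#' @param g graph.
#' @param algorithm layout algorithm.
#' @param seed RNG seed for force_directed.
#' @param spacing base spacing in screen units.
#' @return the graph with coordinates set.
#' @export
layout_network <- function(g, algorithm = c("force_directed", "circle", "grid",
                                            "tree", "pathway_circles"),
                           seed = 1, spacing = 100) {
  check_graph(g)
  algorithm <- match.arg(algorithm)
  n <- length(g$nodes)
  if (n == 0) return(g)
  xy <- switch(algorithm,
    circle = layout_circle_xy(n, spacing),
    grid = {
      k <- ceiling(sqrt(n))
      cbind(((seq_len(n) - 1) %% k) * spacing + spacing,
            ((seq_len(n) - 1) %/% k) * spacing + spacing)
    },
    tree = {
      ig <- as_igraph(g)
      if (g$directed && !igraph::is_dag(ig))
        stop2("tree layout requires an acyclic directed graph")
      if (!g$directed && length(find_cycles(g, cap = 1)$cycles) > 0)
        stop2("tree layout requires an acyclic graph")
      raw <- igraph::layout_as_tree(ig)
      cbind(raw[, 1] * spacing + spacing,
            (max(raw[, 2]) - raw[, 2]) * spacing + spacing)
    },
    force_directed = {
      ig <- as_igraph(g)
      raw <- with_seed(seed, igraph::layout_with_fr(ig))
      raw <- apply(raw, 2, function(c) c - min(c))
      scale <- spacing * max(1, sqrt(n)) / max(1e-9, max(raw))
      xy <- raw * scale + spacing
      jitter_coincident(xy)
    },
    pathway_circles = layout_pathway_circles(g, spacing))
  for (i in seq_len(n)) {
    g <- og_set_attr(g, "node", g$nodes[i], "graphics.x", round(xy[i, 1], 6))
    g <- og_set_attr(g, "node", g$nodes[i], "graphics.y", round(xy[i, 2], 6))
  }
  g
}

layout_circle_xy <- function(n, spacing, center = NULL) {
  r <- max(spacing, spacing * n / (2 * pi))
  if (is.null(center)) center <- c(r + spacing, r + spacing)
  th <- 2 * pi * (seq_len(n) - 1) / n - pi / 2
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

jitter_coincident <- function(xy) {
  key <- paste(round(xy[, 1], 6), round(xy[, 2], 6))
  dup <- duplicated(key)
  k <- 0L
  while (any(dup)) {
    for (i in which(dup)) { k <- k + 1L; xy[i, ] <- xy[i, ] + k * c(0.5, 0.25) }
    key <- paste(round(xy[, 1], 6), round(xy[, 2], 6))
    dup <- duplicated(key)
  }
  xy
}

layout_pathway_circles <- function(g, spacing) {
  pw <- vapply(g$nodes, function(n) {
    v <- og_get_attr(g, "node", n, "pathway")
    if (is.null(v)) NA_character_ else as.character(v)
  }, character(1))
  if (anyNA(pw))
    stop2("pathway_circles layout requires a 'pathway' attribute on every node")
  groups <- split(seq_along(g$nodes), pw)
  k <- length(groups)
  radii <- vapply(groups, function(idx)
    max(spacing * 0.6, spacing * 0.35 * length(idx) / (2 * pi) * 2), numeric(1))
  R <- max(2 * max(radii), (2 * max(radii) + spacing) * k / (2 * pi))
  cx <- R + max(radii) + spacing
  xy <- matrix(0, length(g$nodes), 2)
  for (ci in seq_along(groups)) {
    th <- 2 * pi * (ci - 1) / k - pi / 2
    center <- c(cx + R * cos(th), cx + R * sin(th))
    idx <- groups[[ci]]
    m <- length(idx)
    phi <- 2 * pi * (seq_len(m) - 1) / m - pi / 2
    xy[idx, ] <- cbind(center[1] + radii[ci] * cos(phi),
                       center[2] + radii[ci] * sin(phi))
  }
  xy
}
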
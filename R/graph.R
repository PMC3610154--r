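#' Attributed directed multigraph
#'
#' The universal substrate of the package: a directed (or undirected)
#' multigraph whose graph, nodes and edges each carry a flat map from dotted
#' hierarchical attribute paths (e.g. \code{"graphics.fill"}) to scalar
#' values (length-one character or numeric).  Biological entities such as
#' metabolites, enzymes and reactions are nodes; conversions, regulations and
#' correlations are edges.  Node identity is an opaque string id; display
#' labels live in the \code{"label"} attribute and may legally repeat
#' (pre-merge pathway copies, split cofactor clones).
#'
#' Well-known attribute paths used by the rest of the package:
#' \itemize{
#'   \item \code{label}, \code{alt_ids} (synonyms joined by \code{"|"}),
#'     \code{sbgn_class} (\code{simple_chemical}, \code{macromolecule},
#'     \code{process}, \code{compartment}, \code{unspecified})
#'   \item \code{graphics.x}, \code{graphics.y} (screen convention: origin
#'     top-left, y grows downward, node anchor at the center),
#'     \code{graphics.w}, \code{graphics.h}, \code{graphics.fill},
#'     \code{graphics.frame}
#'   \item edges: \code{weight} (stoichiometric coefficient),
#'     \code{interaction}, \code{graphics.thickness}, \code{graphics.fill}
#'   \item mapped data: \code{mapping.<substance>.<condition>.<time>.<rep>}
#' }
#'
#' @param directed logical; build a directed graph (the default).
#' @return an object of class \code{omic_graph}.
#' @export
og_graph <- function(directed = TRUE) {
  structure(list(
    directed = isTRUE(directed),
    nodes = character(),
    edge_id = character(), edge_src = character(), edge_dst = character(),
    gattr = list(),
    nattr = list(),
    eattr = list(),
    counter = 0L
  ), class = "omic_graph")
}

#' @export
print.omic_graph <- function(x, ...) {
  cat(sprintf("<omic_graph: %s, %d nodes, %d edges, %d graph attributes>\n",
              if (x$directed) "directed" else "undirected",
              length(x$nodes), length(x$edge_id), length(x$gattr)))
  invisible(x)
}

og_is_graph <- function(g) inherits(g, "omic_graph")

check_graph <- function(g) {
  if (!og_is_graph(g)) stop2("expected an omic_graph")
  g
}

fresh_id <- function(g, prefix) {
  repeat {
    g$counter <- g$counter + 1L
    id <- paste0(prefix, g$counter)
    if (!(id %in% g$nodes) && !(id %in% g$edge_id)) break
  }
  list(g = g, id = id)
}

#' Nodes and edges of a graph
#'
#' \code{og_nodes} returns the node id vector; \code{og_edges} a data frame
#' with columns \code{id}, \code{source}, \code{target}.
#' @param g an \code{omic_graph}.
#' @export
og_nodes <- function(g) check_graph(g)$nodes

#' @rdname og_nodes
#' @export
og_edges <- function(g) {
  check_graph(g)
  data.frame(id = g$edge_id, source = g$edge_src, target = g$edge_dst,
             stringsAsFactors = FALSE)
}

#' @rdname og_nodes
#' @export
og_node_count <- function(g) length(check_graph(g)$nodes)

#' @rdname og_nodes
#' @export
og_edge_count <- function(g) length(check_graph(g)$edge_id)

#' Add a node
#'
#' @param g graph.
#' @param id node id; autogenerated (\code{"n<k>"}) when \code{NULL}.
#' @param attrs named list of attribute path -> scalar value.
#' @return the modified graph; the id of the last added node is available as
#'   \code{attr(, "last_id")}.
#' @export
og_add_node <- function(g, id = NULL, attrs = list()) {
  check_graph(g)
  if (is.null(id)) { r <- fresh_id(g, "n"); g <- r$g; id <- r$id }
  id <- as.character(id)
  if (id %in% g$nodes) stop2("node id already present: ", id)
  g$nodes <- c(g$nodes, id)
  g$nattr[[id]] <- check_attrs(attrs)
  attr(g, "last_id") <- id
  g
}

#' Add an edge
#'
#' Parallel edges are allowed (multigraph); both endpoints must exist.
#' @inheritParams og_add_node
#' @param source,target endpoint node ids.
#' @export
og_add_edge <- function(g, source, target, attrs = list(), id = NULL) {
  check_graph(g)
  source <- as.character(source); target <- as.character(target)
  if (!(source %in% g$nodes)) stop2("unknown source node: ", source)
  if (!(target %in% g$nodes)) stop2("unknown target node: ", target)
  if (is.null(id)) { r <- fresh_id(g, "e"); g <- r$g; id <- r$id }
  id <- as.character(id)
  if (id %in% g$edge_id) stop2("edge id already present: ", id)
  g$edge_id <- c(g$edge_id, id)
  g$edge_src <- c(g$edge_src, source)
  g$edge_dst <- c(g$edge_dst, target)
  g$eattr[[id]] <- check_attrs(attrs)
  attr(g, "last_id") <- id
  g
}

check_attrs <- function(attrs) {
  if (length(attrs) == 0) return(list())
  nm <- names(attrs)
  if (is.null(nm) || any(nm == "")) stop2("attributes must be named")
  if (anyDuplicated(nm)) stop2("duplicate attribute paths")
  for (i in seq_along(attrs)) {
    v <- attrs[[i]]
    if (!(is.character(v) || is.numeric(v) || is.logical(v)) || length(v) != 1)
      stop2("attribute '", nm[i], "' must be a length-one scalar")
    if (is.logical(v)) attrs[[i]] <- as.numeric(v)
  }
  attrs
}

#' Remove a node (and its incident edges) or an edge
#' @param g graph.
#' @param id element id.
#' @export
og_remove_node <- function(g, id) {
  check_graph(g)
  if (!(id %in% g$nodes)) stop2("unknown node: ", id)
  inc <- g$edge_id[g$edge_src == id | g$edge_dst == id]
  for (e in inc) g <- og_remove_edge(g, e)
  g$nodes <- setdiff(g$nodes, id)
  g$nattr[[id]] <- NULL
  g
}

#' @rdname og_remove_node
#' @export
og_remove_edge <- function(g, id) {
  check_graph(g)
  k <- match(id, g$edge_id)
  if (is.na(k)) stop2("unknown edge: ", id)
  g$edge_id <- g$edge_id[-k]; g$edge_src <- g$edge_src[-k]; g$edge_dst <- g$edge_dst[-k]
  g$eattr[[id]] <- NULL
  g
}

#' Get or set attributes
#'
#' Attributes live under dotted hierarchical paths; values are length-one
#' character or numeric scalars.  \code{scope} is \code{"node"},
#' \code{"edge"} or \code{"graph"} (for which \code{id} is ignored).
#' Getting a path that is not set returns \code{NULL} (or \code{default}).
#'
#' @param g graph; \code{id} element id; \code{path} dotted attribute path.
#' @param default value returned when the path is unset.
#' @param value scalar to store; \code{NULL} deletes the path.
#' @param scope one of \code{"node"}, \code{"edge"}, \code{"graph"}.
#' @export
og_get_attr <- function(g, scope, id, path, default = NULL) {
  check_graph(g)
  tab <- switch(scope,
                node = g$nattr[[id]], edge = g$eattr[[id]], graph = g$gattr,
                stop2("bad scope: ", scope))
  v <- tab[[path]]
  if (is.null(v)) default else v
}

#' @rdname og_get_attr
#' @export
og_set_attr <- function(g, scope, id, path, value) {
  check_graph(g)
  if (scope %in% c("node", "edge")) {
    pool <- if (scope == "node") g$nodes else g$edge_id
    if (!(id %in% pool)) stop2("unknown ", scope, ": ", id)
  }
  if (!is.null(value)) value <- check_attrs(stats::setNames(list(value), path))[[1]]
  if (scope == "node") g$nattr[[id]][[path]] <- value
  else if (scope == "edge") g$eattr[[id]][[path]] <- value
  else if (scope == "graph") g$gattr[[path]] <- value
  else stop2("bad scope: ", scope)
  g
}

#' @rdname og_get_attr
#' @export
og_attr_paths <- function(g, scope, id = NULL) {
  check_graph(g)
  tab <- switch(scope,
                node = g$nattr[[id]], edge = g$eattr[[id]], graph = g$gattr,
                stop2("bad scope: ", scope))
  names(tab) %||% character()
}

#' Node label and synonym helpers
#'
#' Synonyms (\code{alt_ids}) are stored joined by \code{"|"} so that they
#' survive file-format round trips as one scalar attribute; these helpers
#' present them as a character vector with duplicates removed, order kept.
#' @param g graph; \code{id} node id; \code{ids} character vector of synonyms.
#' @export
og_label <- function(g, id) og_get_attr(g, "node", id, "label", default = id)

#' @rdname og_label
#' @export
og_alt_ids <- function(g, id) {
  v <- og_get_attr(g, "node", id, "alt_ids")
  if (is.null(v) || !nzchar(v)) character() else strsplit(v, "|", fixed = TRUE)[[1]]
}

#' @rdname og_label
#' @export
og_set_alt_ids <- function(g, id, ids) {
  ids <- unique(as.character(ids))
  ids <- ids[nzchar(ids)]
  og_set_attr(g, "node", id, "alt_ids",
              if (length(ids)) paste(ids, collapse = "|") else NULL)
}

#' Node degree
#' @param g graph; \code{id} node id (all nodes when NULL).
#' @param mode "all", "in" or "out" (directed graphs).
#' @export
og_degree <- function(g, id = NULL, mode = c("all", "in", "out")) {
  check_graph(g)
  mode <- match.arg(mode)
  ids <- id %||% g$nodes
  vapply(ids, function(n) {
    dout <- sum(g$edge_src == n); din <- sum(g$edge_dst == n)
    switch(mode, all = dout + din, `in` = din, out = dout)
  }, numeric(1))
}

edges_incident <- function(g, id) g$edge_id[g$edge_src == id | g$edge_dst == id]

#' Structural equality of two graphs
#'
#' Order-insensitive comparison: same node-id set, same multiset of
#' (source, target, sorted attribute map) edges, same attribute maps.
#' Numeric attribute values compare within \code{tol}.
#' @param a,b graphs. @param tol numeric tolerance.
#' @export
og_identical <- function(a, b, tol = 1e-9) {
  check_graph(a); check_graph(b)
  if (a$directed != b$directed) return(FALSE)
  if (!setequal(a$nodes, b$nodes)) return(FALSE)
  cmp_tab <- function(x, y) {
    x <- x %||% list(); y <- y %||% list()
    if (!setequal(names(x), names(y))) return(FALSE)
    for (k in names(x)) {
      vx <- x[[k]]; vy <- y[[k]]
      if (is.numeric(vx) != is.numeric(vy)) return(FALSE)
      ok <- if (is.numeric(vx)) isTRUE(abs(vx - vy) <= tol) else identical(vx, vy)
      if (!ok) return(FALSE)
    }
    TRUE
  }
  if (!cmp_tab(a$gattr, b$gattr)) return(FALSE)
  for (n in a$nodes) if (!cmp_tab(a$nattr[[n]], b$nattr[[n]])) return(FALSE)
  # edges: match as a multiset keyed by (src, dst, serialized attrs)
  ekey <- function(g, i) {
    at <- g$eattr[[g$edge_id[i]]] %||% list()
    if (length(at)) at <- at[order(names(at))]
    paste(g$edge_src[i], g$edge_dst[i],
          paste(names(at), vapply(at, function(v)
            if (is.numeric(v)) sprintf("%.9g", v) else v, character(1)),
            sep = "=", collapse = ";"), sep = "\r")
  }
  ka <- sort(vapply(seq_along(a$edge_id), function(i) ekey(a, i), character(1)))
  kb <- sort(vapply(seq_along(b$edge_id), function(i) ekey(b, i), character(1)))
  identical(ka, kb)
}
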
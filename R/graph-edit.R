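#' Merge networks by fusing nodes with identical key values
#'
#' Takes the disjoint union of the input graphs, then fuses every group of
#' nodes sharing an identical value under \code{key} (by default the display
#' label) into one node.  This is how individual pathway maps are connected
#' into one network: identical metabolite nodes become a single shared node.
#' The fused node inherits the union of all synonyms and all incident edges;
#' its other attributes come from the first member.  Fusion also applies
#' within a single input graph, which makes the operation idempotent.
#'
#' @param graphs a list of \code{omic_graph} objects (or a single graph).
#' @param key attribute path whose value identifies nodes to fuse
#'   (default \code{"label"}).
#' @param classes optional character vector of \code{sbgn_class} values;
#'   when given, only nodes of these classes are considered for fusion.
#' @return the merged \code{omic_graph}.
#' @export
merge_networks <- function(graphs, key = "label", classes = NULL) {
  if (og_is_graph(graphs)) graphs <- list(graphs)
  stopifnot(length(graphs) >= 1)
  directed <- graphs[[1]]$directed
  out <- og_graph(directed)
  # disjoint union with prefixed ids, remembering the original id
  remap <- list()
  for (gi in seq_along(graphs)) {
    g <- check_graph(graphs[[gi]])
    if (g$directed != directed) stop2("cannot merge directed with undirected graphs")
    for (n in g$nodes) {
      nid <- if (length(graphs) == 1) n else paste0("g", gi, ".", n)
      out <- og_add_node(out, nid, g$nattr[[n]] %||% list())
      remap[[paste0(gi, "\r", n)]] <- nid
    }
    for (i in seq_along(g$edge_id)) {
      out <- og_add_edge(out,
                         remap[[paste0(gi, "\r", g$edge_src[i])]],
                         remap[[paste0(gi, "\r", g$edge_dst[i])]],
                         g$eattr[[g$edge_id[i]]] %||% list())
    }
  }
  # group fusable nodes by key value
  keyval <- vapply(out$nodes, function(n) {
    v <- og_get_attr(out, "node", n, key)
    if (is.null(v)) NA_character_ else as.character(v)
  }, character(1))
  eligible <- !is.na(keyval)
  if (!is.null(classes)) {
    cls <- vapply(out$nodes, function(n)
      og_get_attr(out, "node", n, "sbgn_class", default = NA_character_), character(1))
    eligible <- eligible & cls %in% classes
  }
  groups <- split(out$nodes[eligible], keyval[eligible])
  groups <- groups[vapply(groups, length, integer(1)) > 1]
  for (grp in groups) {
    cls <- unique(stats::na.omit(vapply(grp, function(n)
      og_get_attr(out, "node", n, "sbgn_class", default = NA_character_), character(1))))
    if (length(cls) > 1)
      stop2("merge conflict: nodes {", paste(grp, collapse = ", "),
            "} share key but have sbgn_class values {", paste(cls, collapse = ", "), "}")
    keep <- grp[1]
    alt <- og_alt_ids(out, keep)
    for (n in grp[-1]) {
      alt <- union(alt, c(og_label(out, n), og_alt_ids(out, n)))
      # reattach incident edges
      for (e in edges_incident(out, n)) {
        k <- match(e, out$edge_id)
        if (out$edge_src[k] == n) out$edge_src[k] <- keep
        if (out$edge_dst[k] == n) out$edge_dst[k] <- keep
      }
      out$nodes <- setdiff(out$nodes, n)
      out$nattr[[n]] <- NULL
    }
    alt <- setdiff(alt, og_label(out, keep))
    out <- og_set_alt_ids(out, keep, alt)
  }
  out
}

#' Split a high-degree node into one clone per incident edge
#'
#' Frequently occurring currency metabolites such as ATP clutter a layout;
#' splitting replaces the node by degree-many clones, each attached to one of
#' the original incident edges.  Clones share the original's label, synonyms
#' and other attributes and record the clone multiplicity under
#' \code{"clone.count"} plus their origin under \code{"clone.of"}.
#' A self-loop yields a pair of clones joined by the former loop edge, which
#' preserves both the edge count and the total degree sum.
#'
#' @param g graph. @param node node id with degree >= 2 (degree < 2 is a
#'   warning no-op).
#' @export
split_node <- function(g, node) {
  check_graph(g)
  if (!(node %in% g$nodes)) stop2("unknown node: ", node)
  inc <- edges_incident(g, node)
  loops <- inc[g$edge_src[match(inc, g$edge_id)] == node &
               g$edge_dst[match(inc, g$edge_id)] == node]
  d <- length(inc) + length(loops)        # loops count twice toward degree
  if (d < 2) { warn2("split_node: degree < 2, nothing to split"); return(g) }
  base_attrs <- g$nattr[[node]] %||% list()
  n_clones <- d
  clone_ids <- character(0)
  for (i in seq_len(n_clones)) {
    r <- fresh_id(g, paste0(node, ".clone"))
    g <- r$g
    g <- og_add_node(g, r$id, base_attrs)
    g <- og_set_attr(g, "node", r$id, "clone.of", node)
    g <- og_set_attr(g, "node", r$id, "clone.count", n_clones)
    clone_ids <- c(clone_ids, r$id)
  }
  ci <- 1L
  for (e in inc) {
    k <- match(e, g$edge_id)
    if (g$edge_src[k] == node && g$edge_dst[k] == node) {
      g$edge_src[k] <- clone_ids[ci]; g$edge_dst[k] <- clone_ids[ci + 1L]
      ci <- ci + 2L
    } else if (g$edge_src[k] == node) {
      g$edge_src[k] <- clone_ids[ci]; ci <- ci + 1L
    } else {
      g$edge_dst[k] <- clone_ids[ci]; ci <- ci + 1L
    }
  }
  g$nodes <- setdiff(g$nodes, node)
  g$nattr[[node]] <- NULL
  g
}

#' Derive new element attributes from existing ones
#'
#' Aggregates, for every element in \code{scope}, the numeric values found at
#' \code{source} (the exact path plus every path below it, so a mapped
#' substance prefix like \code{"mapping.Glc"} covers all its replicate
#' values) and stores the result at \code{target}.  Elements where no numeric
#' source value resolves are skipped.  \code{expression = "degree"} ignores
#' \code{source} and writes the node degree.
#'
#' @param g graph. @param scope "node" or "edge".
#' @param expression one of \code{"mean"}, \code{"median"}, \code{"min"},
#'   \code{"max"}, \code{"degree"}.
#' @param source source attribute path (prefix). @param target target path.
#' @return list with the updated \code{graph} and \code{written}, the count
#'   of elements that received the target attribute.
#' @export
compute_attribute <- function(g, scope = c("node", "edge"),
                              expression = c("mean", "median", "min", "max", "degree"),
                              source = NULL, target) {
  check_graph(g)
  scope <- match.arg(scope)
  expression <- match.arg(expression)
  ids <- if (scope == "node") g$nodes else g$edge_id
  written <- 0L
  for (id in ids) {
    if (expression == "degree") {
      if (scope != "node") stop2("degree is a node expression")
      val <- unname(og_degree(g, id))
    } else {
      if (is.null(source)) stop2("source path required for ", expression)
      tab <- if (scope == "node") g$nattr[[id]] else g$eattr[[id]]
      keys <- names(tab) %||% character()
      hit <- keys[keys == source | startsWith(keys, paste0(source, "."))]
      vals <- unlist(lapply(tab[hit], function(v) if (is.numeric(v)) v else NULL))
      if (length(vals) == 0) next
      val <- switch(expression, mean = mean(vals), median = stats::median(vals),
                    min = min(vals), max = max(vals))
    }
    g <- og_set_attr(g, scope, id, target, val)
    written <- written + 1L
  }
  list(graph = g, written = written)
}
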
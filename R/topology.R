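#' Convert to an igraph object
#'
#' Bridge to the igraph algorithms used by the topology module; node ids
#' become vertex names, edge ids are kept in the edge attribute \code{eid}.
#' @param g an \code{omic_graph}.
#' @export
as_igraph <- function(g) {
  check_graph(g)
  if (length(g$edge_id)) {
    d <- data.frame(from = g$edge_src, to = g$edge_dst, eid = g$edge_id,
                    stringsAsFactors = FALSE)
    ig <- igraph::graph_from_data_frame(d, directed = g$directed,
                                        vertices = data.frame(name = g$nodes))
  } else {
    ig <- igraph::make_empty_graph(directed = g$directed) +
      igraph::vertices(g$nodes)
  }
  ig
}

#' Shortest paths
#'
#' Breadth-first search on unweighted graphs, Dijkstra with nonnegative
#' weights taken from the edge attribute named by \code{weight_attr}.
#' Unreachable targets get infinite length and are flagged.
#'
#' @param g graph. @param source source node id.
#' @param target optional target node id; when NULL, distances (and paths)
#'   to all nodes are returned.
#' @param weight_attr optional edge attribute path holding nonnegative
#'   weights; NULL = unweighted.
#' @return list: \code{lengths} (named numeric, Inf = unreachable),
#'   \code{paths} (named list of node-id vectors, empty when unreachable),
#'   \code{unreachable} (character).
#' @export
shortest_paths <- function(g, source, target = NULL, weight_attr = NULL) {
  check_graph(g)
  if (!(source %in% g$nodes)) stop2("unknown node: ", source)
  if (!is.null(target) && !(target %in% g$nodes)) stop2("unknown node: ", target)
  ig <- as_igraph(g)
  w <- NULL
  if (!is.null(weight_attr)) {
    w <- vapply(g$edge_id, function(e)
      as.numeric(og_get_attr(g, "edge", e, weight_attr, default = 1)), numeric(1))
    if (any(w < 0)) stop2("negative weights not supported")
    # align with igraph edge order via eid attribute
    w <- w[match(igraph::edge_attr(ig, "eid"), g$edge_id)]
  }
  to <- target %||% g$nodes
  sp <- suppressWarnings(
    igraph::shortest_paths(ig, from = source, to = to, weights = w,
                           mode = "out", output = "vpath"))
  d <- suppressWarnings(
    igraph::distances(ig, v = source, to = to, weights = w, mode = "out"))
  lengths <- stats::setNames(as.numeric(d[1, ]), to)
  paths <- stats::setNames(lapply(sp$vpath, function(v) igraph::as_ids(v)), to)
  list(lengths = lengths, paths = paths,
       unreachable = names(lengths)[!is.finite(lengths)])
}

#' Enumerate cycles
#'
#' Directed graphs: all elementary circuits, each reported once starting at
#' its smallest node (enumeration capped at \code{cap}, with a truncation
#' flag).  Undirected graphs: a cycle basis built from a spanning forest
#' (one cycle per non-tree edge).
#'
#' @param g graph. @param cap maximum number of cycles returned.
#' @return list: \code{cycles} (list of node-id vectors, cycle closed
#'   implicitly), \code{truncated} flag.
#' @export
find_cycles <- function(g, cap = 10000) {
  check_graph(g)
  n <- length(g$nodes)
  idx <- stats::setNames(seq_len(n), g$nodes)
  if (g$directed) {
    adj <- lapply(seq_len(n), function(i) sort(unique(idx[g$edge_dst[g$edge_src == g$nodes[i]]])))
    cycles <- list(); truncated <- FALSE
    # canonical enumeration: circuits whose minimal node is the DFS root
    for (s in seq_len(n)) {
      if (truncated) break
      path <- integer(); onpath <- logical(n)
      dfs <- function(v) {
        if (truncated) return()
        path[length(path) + 1L] <<- v; onpath[v] <<- TRUE
        for (w in adj[[v]]) {
          if (w == s) {
            if (length(cycles) >= cap) { truncated <<- TRUE; break }
            cycles[[length(cycles) + 1L]] <<- g$nodes[path]
          } else if (w > s && !onpath[w]) dfs(w)
        }
        onpath[path[length(path)]] <<- FALSE
        path <<- path[-length(path)]
      }
      dfs(s)
    }
    list(cycles = cycles, truncated = truncated)
  } else {
    # spanning-forest cycle basis
    parent <- rep(NA_integer_, n); depth <- rep(NA_integer_, n)
    tree_edge <- rep(NA_integer_, n)
    used <- logical(length(g$edge_id))
    esrc <- idx[g$edge_src]; edst <- idx[g$edge_dst]
    for (root in seq_len(n)) {
      if (!is.na(depth[root])) next
      depth[root] <- 0L
      queue <- root
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        inc <- which((esrc == v | edst == v) & !used)
        for (ei in inc) {
          w <- if (esrc[ei] == v) edst[ei] else esrc[ei]
          if (is.na(depth[w])) {
            used[ei] <- TRUE; parent[w] <- v; depth[w] <- depth[v] + 1L
            tree_edge[w] <- ei
            queue <- c(queue, w)
          }
        }
      }
    }
    cycles <- list(); truncated <- FALSE
    for (ei in which(!used)) {
      if (length(cycles) >= cap) { truncated <- TRUE; break }
      u <- esrc[ei]; v <- edst[ei]
      if (u == v) { cycles[[length(cycles) + 1L]] <- g$nodes[u]; next }
      pu <- u; pv <- v; pa <- integer(); pb <- integer()
      while (depth[pu] > depth[pv]) { pa <- c(pa, pu); pu <- parent[pu] }
      while (depth[pv] > depth[pu]) { pb <- c(pb, pv); pv <- parent[pv] }
      while (pu != pv) { pa <- c(pa, pu); pu <- parent[pu]
                         pb <- c(pb, pv); pv <- parent[pv] }
      cycles[[length(cycles) + 1L]] <- g$nodes[c(pa, pu, rev(pb))]
    }
    list(cycles = cycles, truncated = truncated)
  }
}

#' Motif search by subgraph isomorphism
#'
#' Finds all injective mappings of a small pattern graph (e.g. the
#' feed-forward loop A->B, A->C, B->C) into \code{g}.  Non-induced by
#' default: every pattern edge must be realized in the stated orientation;
#' induced mode additionally forbids extra edges between matched nodes.
#' Pattern nodes carrying an \code{sbgn_class} attribute constrain their
#' image to the same class.  Matches are deduplicated modulo the pattern's
#' automorphisms, so each occurrence is reported once as an ordered tuple
#' aligned with \code{og_nodes(pattern)}.
#'
#' @param g target graph. @param pattern connected pattern graph, <= 8 nodes.
#' @param induced require induced subgraph isomorphism.
#' @param use_classes honor sbgn_class constraints on pattern nodes.
#' @return list of character vectors (matched node ids, pattern order).
#' @export
find_motifs <- function(g, pattern, induced = FALSE, use_classes = TRUE) {
  check_graph(g); check_graph(pattern)
  if (og_node_count(pattern) > 8) stop2("pattern larger than 8 nodes")
  if (og_node_count(pattern) > og_node_count(g)) return(list())
  matches <- subiso_matches(g, pattern, induced, use_classes)
  if (length(matches) == 0) return(list())
  autos <- subiso_matches(pattern, pattern, induced = TRUE, use_classes = use_classes)
  pn <- pattern$nodes
  perms <- lapply(autos, function(a) match(a, pn))
  seen <- character(); out <- list()
  for (m in matches) {
    key <- min(vapply(perms, function(p) paste(m[p], collapse = "\r"), character(1)))
    if (!(key %in% seen)) { seen <- c(seen, key); out[[length(out) + 1L]] <- m }
  }
  out
}

# backtracking injective matcher; returns list of node-id vectors in pattern
# node order
subiso_matches <- function(g, pattern, induced, use_classes) {
  pn <- pattern$nodes; gn <- g$nodes
  np <- length(pn)
  ecount <- function(gr, s, t) sum(gr$edge_src == s & gr$edge_dst == t) +
    if (!gr$directed) sum(gr$edge_src == t & gr$edge_dst == s & s != t) else 0
  pcls <- vapply(pn, function(n)
    og_get_attr(pattern, "node", n, "sbgn_class", default = NA_character_), character(1))
  gcls <- vapply(gn, function(n)
    og_get_attr(g, "node", n, "sbgn_class", default = NA_character_), character(1))
  pdeg <- og_degree(pattern)
  gdeg <- og_degree(g)
  # order pattern nodes: connected expansion, highest degree first
  order_p <- order(-pdeg)
  cand0 <- lapply(seq_len(np), function(i)
    which(gdeg >= pdeg[i] &
            (!use_classes | is.na(pcls[i]) | (!is.na(gcls) & gcls == pcls[i]))))
  results <- list()
  assign_v <- rep(NA_integer_, np)
  bt <- function(pos) {
    if (pos > np) {
      if (induced) {
        for (a in seq_len(np)) for (b in seq_len(np)) {
          if (a == b && g$directed) next
          if (ecount(pattern, pn[a], pn[b]) != ecount(g, gn[assign_v[a]], gn[assign_v[b]]))
            return()
        }
      }
      results[[length(results) + 1L]] <<- gn[assign_v]
      return()
    }
    i <- order_p[pos]
    for (c in cand0[[i]]) {
      if (c %in% assign_v) next
      ok <- TRUE
      for (posj in seq_len(pos - 1L)) {
        j <- order_p[posj]
        if (ecount(pattern, pn[i], pn[j]) > ecount(g, gn[c], gn[assign_v[j]]) ||
            ecount(pattern, pn[j], pn[i]) > ecount(g, gn[assign_v[j]], gn[c])) {
          ok <- FALSE; break
        }
      }
      if (ecount(pattern, pn[i], pn[i]) > ecount(g, gn[c], gn[c])) ok <- FALSE
      if (ok) { assign_v[i] <<- c; bt(pos + 1L); assign_v[i] <<- NA_integer_ }
    }
  }
  bt(1L)
  results
}

#' Node centralities
#'
#' Computes a subset of the classical centrality measures and stores each
#' under the node attribute \code{"centrality.<measure>"}.  Conventions:
#' closeness is the harmonic variant (sum of reciprocal distances), well
#' defined on disconnected graphs; eccentricity and eigenvector centrality
#' ignore edge direction; betweenness (Brandes) counts unnormalized
#' dependent pairs and respects direction; Katz centrality is
#' \eqn{x = ((I - \alpha A^T)^{-1} - I)\mathbf{1}} with attenuation
#' \code{alpha}.  Eigenvector centrality uses power iteration (tolerance
#' 1e-10, at most 10^4 iterations, max-normalized) and errors when it fails
#' to converge.
#'
#' @param g graph.
#' @param which measures: subset of degree, degree_in, degree_out,
#'   closeness, eccentricity, betweenness, eigenvector, katz.
#' @param alpha Katz attenuation factor (must satisfy alpha < 1/lambda_max).
#' @return list: \code{graph} (annotated) and \code{values}
#'   (nodes x measures matrix).
#' @export
centralities <- function(g, which = c("degree", "betweenness"), alpha = 0.1) {
  check_graph(g)
  allm <- c("degree", "degree_in", "degree_out", "closeness", "eccentricity",
            "betweenness", "eigenvector", "katz")
  which <- match.arg(which, allm, several.ok = TRUE)
  ig <- as_igraph(g)
  n <- length(g$nodes)
  vals <- matrix(NA_real_, n, length(which), dimnames = list(g$nodes, which))
  for (m in which) {
    v <- switch(m,
      degree = og_degree(g),
      degree_in = og_degree(g, mode = "in"),
      degree_out = og_degree(g, mode = "out"),
      closeness = igraph::harmonic_centrality(ig, mode = "out", normalized = FALSE),
      eccentricity = igraph::eccentricity(ig, mode = "all"),
      betweenness = igraph::betweenness(ig, directed = g$directed),
      eigenvector = eigen_power(g),
      katz = katz_centrality(g, alpha))
    vals[, m] <- as.numeric(v)
    for (i in seq_len(n))
      g <- og_set_attr(g, "node", g$nodes[i], paste0("centrality.", m), vals[i, m])
  }
  list(graph = g, values = vals)
}

adjacency_matrix <- function(g, symmetric = FALSE) {
  n <- length(g$nodes)
  A <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  for (i in seq_along(g$edge_id)) {
    A[g$edge_src[i], g$edge_dst[i]] <- A[g$edge_src[i], g$edge_dst[i]] + 1
    if (!g$directed || symmetric)
      A[g$edge_dst[i], g$edge_src[i]] <- A[g$edge_dst[i], g$edge_src[i]] + 1
  }
  A
}

eigen_power <- function(g, tol = 1e-10, max_iter = 1e4) {
  A <- adjacency_matrix(g, symmetric = TRUE)
  n <- nrow(A)
  if (n == 0) return(numeric())
  diag(A) <- diag(A) + 1   # spectral shift: kills bipartite oscillation,
  x <- rep(1, n)           # leaves the dominant eigenvector unchanged
  for (it in seq_len(max_iter)) {
    y <- as.vector(A %*% x)
    if (max(abs(y)) == 0) return(rep(0, n))   # empty graph
    y <- y / max(abs(y))
    if (max(abs(y - x)) < tol) return(y)
    x <- y
  }
  stop2("eigenvector centrality did not converge after ", max_iter, " iterations")
}

katz_centrality <- function(g, alpha) {
  A <- adjacency_matrix(g)
  n <- nrow(A)
  lam <- if (n > 0) max(abs(eigen(A, only.values = TRUE)$values)) else 0
  if (lam > 0 && alpha >= 1 / lam)
    stop2("Katz alpha must be < 1/lambda_max = ", format(1 / lam))
  as.vector(solve(diag(n) - alpha * t(A), rep(1, n))) - 1
}
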
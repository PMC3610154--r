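#' Enrich network nodes with alternative identifiers
#'
#' For every node whose label or existing synonyms match a primary name in
#' the mapping table (exact match, case-insensitive and whitespace-trimmed
#' unless \code{strict}), all synonyms of that row are appended to the
#' node's \code{alt_ids} (deduplicated).  Rows matching no node are counted
#' and reported via a message.
#'
#' @param g graph. @param table an \code{\link{read_mapping_table}} result.
#' @param strict logical; exact case-sensitive matching.
#' @export
enrich_identifiers <- function(g, table, strict = FALSE) {
  check_graph(g)
  stopifnot(inherits(table, "omic_mapping_table"))
  used <- logical(length(table$primary))
  prim <- norm_id(table$primary, strict)
  for (n in g$nodes) {
    ids <- norm_id(c(og_label(g, n), og_alt_ids(g, n)), strict)
    hit <- which(prim %in% ids)
    if (length(hit) == 0) next
    used[hit] <- TRUE
    syn <- unique(unlist(table$synonyms[hit]))
    add <- syn[!(norm_id(syn, strict) %in% ids)]
    if (length(add))
      g <- og_set_alt_ids(g, n, c(og_alt_ids(g, n), add))
  }
  if (any(!used))
    message(sum(!used), " mapping-table row(s) matched no node")
  g
}

#' Map an experiment onto a network
#'
#' Attaches the measurement tensor to network nodes by identifier matching:
#' a substance maps to a node iff its name or any synonym equals the node's
#' label or any alt id (case-insensitive, trimmed unless \code{strict})
#' \emph{and} the node's \code{sbgn_class} equals \code{class_rule[kind]} —
#' so metabolite data lands on simple-chemical glyphs and enzyme activities
#' on macromolecule glyphs.  A substance matching several admissible nodes
#' (e.g. split cofactor clones) is mapped to all of them and reported as
#' ambiguous.  Unmatched substances become new isolated nodes when
#' \code{create_missing} (morphological parameters enter the network this
#' way).  Values are stored under
#' \code{"mapping.<substance>.<condition>.<time>.<replicate>"}; dots inside
#' names are replaced by \code{_} to keep paths unambiguous.
#'
#' @param g graph. @param e experiment.
#' @param class_rule named character vector kind -> sbgn_class; must cover
#'   every kind present in \code{e}.
#' @param create_missing create isolated nodes for unmatched substances.
#' @param strict exact case-sensitive matching.
#' @return list with \code{graph} and \code{report} (a
#'   \code{MappingReport}: \code{mapped} data frame substance/node,
#'   \code{unmapped} substances, \code{created} node ids, \code{ambiguous}
#'   named list substance -> candidate nodes).
#' @export
map_experiment <- function(g, e,
                           class_rule = c(metabolite = "simple_chemical",
                                          enzyme = "macromolecule",
                                          morphological = "unspecified",
                                          gene = "macromolecule",
                                          other = "unspecified"),
                           create_missing = TRUE, strict = FALSE) {
  check_graph(g); stopifnot(exp_is(e))
  kinds <- unique(e$substances$kind)
  if (!all(kinds %in% names(class_rule)))
    stop2("class_rule must cover kind(s): ",
          paste(setdiff(kinds, names(class_rule)), collapse = ", "))
  nodes0 <- g$nodes   # snapshot: created nodes never capture later substances
  node_ids <- lapply(nodes0, function(n)
    norm_id(c(og_label(g, n), og_alt_ids(g, n)), strict))
  node_cls <- vapply(nodes0, function(n)
    og_get_attr(g, "node", n, "sbgn_class", default = "unspecified"), character(1))
  mapped <- list(); unmapped <- character(); created <- character()
  ambiguous <- list()
  # deterministic, substance-order-independent: process in sorted name order
  for (s in sort(e$substances$name)) {
    si <- match(s, e$substances$name)
    kind <- e$substances$kind[si]
    want_cls <- class_rule[[kind]]
    keys <- norm_id(c(s, exp_alt_ids(e, s)), strict)
    cand <- nodes0[vapply(seq_along(nodes0), function(i)
      node_cls[i] == want_cls && any(keys %in% node_ids[[i]]), logical(1))]
    if (length(cand) == 0) {
      if (create_missing) {
        r <- fresh_id(g, "sub")
        g <- r$g
        g <- og_add_node(g, r$id, list(label = s, sbgn_class = want_cls))
        alt <- exp_alt_ids(e, s)
        if (length(alt)) g <- og_set_alt_ids(g, r$id, alt)
        created <- c(created, r$id)
        cand <- r$id
      } else {
        unmapped <- c(unmapped, s)
        next
      }
    }
    if (length(cand) > 1) ambiguous[[s]] <- cand
    for (n in cand) {
      mapped[[length(mapped) + 1L]] <- data.frame(substance = s, node = n,
                                                  stringsAsFactors = FALSE)
      g <- write_mapping_attrs(g, n, e, si)
    }
  }
  mapped_df <- if (length(mapped)) do.call(rbind, mapped)
               else data.frame(substance = character(), node = character())
  # drop created nodes from "mapped" bookkeeping: the report partitions
  # substances into mapped-to-existing / created / unmapped
  created_subs <- vapply(created, function(n) og_label(g, n), character(1))
  mapped_df <- mapped_df[!(mapped_df$substance %in% created_subs), , drop = FALSE]
  rownames(mapped_df) <- NULL
  report <- structure(list(mapped = mapped_df, unmapped = unmapped,
                           created = created, ambiguous = ambiguous),
                      class = "omic_mapping_report")
  list(graph = g, report = report)
}

path_seg <- function(x) gsub(".", "_", as.character(x), fixed = TRUE)

# batch write: one list merge per (node, substance) instead of one
# og_set_attr per measurement
write_mapping_attrs <- function(g, node, e, si) {
  s <- path_seg(e$substances$name[si])
  keep <- which(!is.na(e$values[si, ]))
  paths <- paste("mapping", s, path_seg(e$samples$condition[keep]),
                 path_seg(e$samples$time[keep]), e$samples$replicate[keep],
                 sep = ".")
  new <- stats::setNames(as.list(e$values[si, keep]), paths)
  new[[paste("mapping", s, "kind", sep = ".")]] <- e$substances$kind[si]
  new[[paste("mapping", s, "unit", sep = ".")]] <- e$substances$unit[si]
  tab <- g$nattr[[node]] %||% list()
  tab[names(new)] <- new
  g$nattr[[node]] <- tab
  g
}

#' @export
print.omic_mapping_report <- function(x, ...) {
  cat(sprintf("<mapping report: %d mapped, %d created, %d unmapped, %d ambiguous>\n",
              length(unique(x$mapped$substance)), length(x$created),
              length(x$unmapped), length(x$ambiguous)))
  invisible(x)
}

#' Substances mapped on a node
#' @param g graph. @param node node id.
#' @return character vector of substance names (path-sanitized form).
#' @export
og_mapped_substances <- function(g, node) {
  keys <- og_attr_paths(g, "node", node)
  keys <- keys[startsWith(keys, "mapping.")]
  unique(vapply(strsplit(keys, ".", fixed = TRUE), `[`, character(1), 2))
}

#' Per-condition mean profile of the data mapped on a node
#'
#' Averages all replicate/time values per condition over every substance
#' mapped on the node; pairwise missing conditions stay NA.
#' @param g graph. @param node node id.
#' @param conditions condition order (path-sanitized names); defaults to the
#'   sorted set present on the node.
#' @export
og_node_profile <- function(g, node, conditions = NULL) {
  keys <- og_attr_paths(g, "node", node)
  keys <- keys[startsWith(keys, "mapping.")]
  parts <- strsplit(keys, ".", fixed = TRUE)
  meas <- vapply(parts, function(p) length(p) == 5, logical(1))
  keys <- keys[meas]; parts <- parts[meas]
  conds <- vapply(parts, `[`, character(1), 3)
  vals <- vapply(keys, function(k) as.numeric(og_get_attr(g, "node", node, k)),
                 numeric(1))
  if (is.null(conditions)) conditions <- sort(unique(conds))
  out <- stats::setNames(rep(NA_real_, length(conditions)), conditions)
  agg <- tapply(vals, conds, mean)
  out[intersect(names(agg), conditions)] <- agg[intersect(names(agg), conditions)]
  out
}

#' All mapped nodes of a graph
#' @param g graph.
#' @export
og_mapped_nodes <- function(g) {
  g$nodes[vapply(g$nodes, function(n)
    any(startsWith(og_attr_paths(g, "node", n), "mapping.")), logical(1))]
}

#' Export mapped data back to a flat table
#'
#' One row per (node, substance, condition, time, replicate) measurement
#' carried on the graph; the file re-imports via \code{\link{read_csv_long}}.
#' @param g graph with mapped data. @param path output CSV path.
#' @return the path, invisibly; the file has a header even when empty.
#' @export
export_mapped_data <- function(g, path) {
  check_graph(g)
  rows <- list()
  for (n in g$nodes) {
    tab <- g$nattr[[n]] %||% list()
    keys <- names(tab) %||% character()
    keys <- keys[startsWith(keys, "mapping.")]
    if (length(keys) == 0) next
    parts <- strsplit(keys, ".", fixed = TRUE)
    meas <- lengths(parts) == 5
    if (!any(meas)) next
    pm <- do.call(rbind, parts[meas])
    rows[[length(rows) + 1L]] <- data.frame(
      node = n, substance = pm[, 2], condition = pm[, 3],
      time = as.numeric(pm[, 4]), replicate = as.integer(pm[, 5]),
      value = as.numeric(unlist(tab[keys[meas]], use.names = FALSE)),
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(node = character(), substance = character(),
                        condition = character(), time = numeric(),
                        replicate = integer(), value = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
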
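# GraphML: XML with typed <key> declarations; attribute paths become
# attr.name, values <data> elements.  Types: numeric attributes are declared
# "double", everything else "string", so a round trip preserves both the
# value and its R storage class.

graphml_ns <- "http://graphml.graphdrawing.org/xmlns"

write_graphml <- function(g, path) {
  # collect (scope, path, type) key table; hashed env — attribute families
  # like mapped measurements can reach tens of thousands of distinct paths
  # one key per (scope, path, type): the same path may carry numbers on one
  # element and strings on another, and both must round-trip with their type
  keys <- new.env(parent = emptyenv())
  add_keys <- function(tabs, scope) {
    for (tab in tabs) for (p in names(tab)) {
      type <- if (is.numeric(tab[[p]])) "double" else "string"
      assign(paste(scope, type, p, sep = "\r"), TRUE, envir = keys)
    }
  }
  add_keys(list(g$gattr), "graph")
  add_keys(g$nattr, "node")
  add_keys(g$eattr, "edge")
  knames <- sort(ls(keys))
  kid <- new.env(parent = emptyenv())
  for (i in seq_along(knames)) assign(knames[i], paste0("k", i), envir = kid)

  xesc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    s <- gsub(">", "&gt;", s, fixed = TRUE)
    gsub("\"", "&quot;", s, fixed = TRUE)
  }
  chunks <- vector("list", 2L * (length(g$nodes) + length(g$edge_id)) + 8L)
  ci <- 0L
  put <- function(x) { ci <<- ci + 1L; chunks[[ci]] <<- x }
  kparts <- strsplit(knames, "\r", fixed = TRUE)
  put(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
        paste0("<graphml xmlns=\"", graphml_ns, "\">"),
        vapply(seq_along(knames), function(i) paste0(
          "  <key id=\"", get(knames[i], envir = kid), "\" for=\"",
          kparts[[i]][1], "\" attr.name=\"", xesc(kparts[[i]][3]),
          "\" attr.type=\"", kparts[[i]][2], "\"/>"), character(1)),
        paste0("  <graph id=\"G\" edgedefault=\"",
               if (g$directed) "directed" else "undirected", "\">")))
  emit_data <- function(tab, scope, pad) {
    ps <- sort(names(tab))
    vapply(ps, function(p) {
      v <- tab[[p]]
      type <- if (is.numeric(v)) "double" else "string"
      paste0(pad, "<data key=\"",
             get(paste(scope, type, p, sep = "\r"), envir = kid),
             "\">", xesc(if (is.numeric(v)) sprintf("%.17g", v) else v),
             "</data>")
    }, character(1), USE.NAMES = FALSE)
  }
  put(emit_data(g$gattr, "graph", "    "))
  for (n in g$nodes) {
    tab <- g$nattr[[n]] %||% list()
    if (length(tab) == 0) put(paste0("    <node id=\"", xesc(n), "\"/>"))
    else put(c(paste0("    <node id=\"", xesc(n), "\">"),
               emit_data(tab, "node", "      "), "    </node>"))
  }
  for (i in seq_along(g$edge_id)) {
    hdr <- paste0("    <edge id=\"", xesc(g$edge_id[i]), "\" source=\"",
                  xesc(g$edge_src[i]), "\" target=\"", xesc(g$edge_dst[i]), "\"")
    tab <- g$eattr[[g$edge_id[i]]] %||% list()
    if (length(tab) == 0) put(paste0(hdr, "/>"))
    else put(c(paste0(hdr, ">"), emit_data(tab, "edge", "      "), "    </edge>"))
  }
  put(c("  </graph>", "</graphml>"))
  writeLines(unlist(chunks[seq_len(ci)]), path)
  invisible(path)
}

read_graphml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop2("GraphML parse error: ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  ktab <- new.env(parent = emptyenv())
  for (k in keys) {
    nm <- xml2::xml_attr(k, "attr.name")
    ty <- xml2::xml_attr(k, "attr.type")
    assign(xml2::xml_attr(k, "id"),
           list(path = if (is.na(nm)) xml2::xml_attr(k, "id") else nm,
                type = if (is.na(ty)) "string" else ty),
           envir = ktab)
  }
  grn <- xml2::xml_find_first(doc, ".//graph")
  if (inherits(grn, "xml_missing")) stop2("GraphML parse error: no <graph> element")
  directed <- identical(xml2::xml_attr(grn, "edgedefault"), "directed")
  g <- og_graph(directed)
  read_data <- function(el) {
    ds <- xml2::xml_find_all(el, "./data")
    if (length(ds) == 0) return(list())
    ids <- xml2::xml_attr(ds, "key")
    txts <- xml2::xml_text(ds)
    out <- vector("list", length(ds))
    nms <- character(length(ds))
    for (i in seq_along(ds)) {
      ki <- if (exists(ids[i], envir = ktab, inherits = FALSE))
              get(ids[i], envir = ktab) else NULL
      if (is.null(ki)) next
      nms[i] <- ki$path
      out[[i]] <- if (ki$type %in% c("double", "float", "int", "long"))
                    as.numeric(txts[i]) else txts[i]
    }
    keep <- nzchar(nms)
    stats::setNames(out[keep], nms[keep])
  }
  g$gattr <- read_data(grn)
  for (nd in xml2::xml_find_all(grn, "./node")) {
    id <- xml2::xml_attr(nd, "id")
    if (is.na(id)) stop2("GraphML parse error: <node> without id")
    g <- og_add_node(g, id, read_data(nd))
  }
  for (ed in xml2::xml_find_all(grn, "./edge")) {
    s <- xml2::xml_attr(ed, "source"); t <- xml2::xml_attr(ed, "target")
    if (is.na(s) || is.na(t)) stop2("GraphML parse error: <edge> without endpoints")
    eid <- xml2::xml_attr(ed, "id")
    g <- og_add_edge(g, s, t, read_data(ed), id = if (is.na(eid)) NULL else eid)
  }
  g
}
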
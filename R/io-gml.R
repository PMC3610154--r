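# GML: ASCII nested key-value blocks.  Dotted attribute paths map to nested
# records (graphics.fill -> graphics [ fill "..." ]) and back.  Internal node
# ids are carried in the conventional "name" key; the numeric "id" key is a
# file-local index.  Unknown keys round-trip verbatim as attribute paths.

gml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  gsub("\"", "&quot;", s, fixed = TRUE)
}
gml_unescape <- function(s) {
  s <- gsub("&quot;", "\"", s, fixed = TRUE)
  gsub("&amp;", "&", s, fixed = TRUE)
}

gml_value <- function(v) {
  if (is.numeric(v)) sprintf("%.17g", v) else paste0("\"", gml_escape(v), "\"")
}

# flat dotted map -> nested emission lines
gml_emit_attrs <- function(tab, indent) {
  if (length(tab) == 0) return(character())
  tab <- tab[order(names(tab))]
  paths <- strsplit(names(tab), ".", fixed = TRUE)
  emit_level <- function(idx, depth, pad) {
    out <- character()
    heads <- vapply(idx, function(i) paths[[i]][depth], character(1))
    for (h in unique(heads)) {
      sub <- idx[heads == h]
      leaf <- sub[vapply(sub, function(i) length(paths[[i]]) == depth, logical(1))]
      deep <- setdiff(sub, leaf)
      for (i in leaf)
        out <- c(out, paste0(pad, h, " ", gml_value(tab[[i]])))
      if (length(deep))
        out <- c(out, paste0(pad, h, " ["),
                 emit_level(deep, depth + 1L, paste0(pad, "  ")),
                 paste0(pad, "]"))
    }
    out
  }
  emit_level(seq_along(tab), 1L, indent)
}

write_gml <- function(g, path) {
  lines <- c("graph [", paste0("  directed ", as.integer(g$directed)),
             gml_emit_attrs(g$gattr, "  "))
  idx <- stats::setNames(seq_along(g$nodes) - 1L, g$nodes)
  for (n in g$nodes) {
    lines <- c(lines, "  node [",
               paste0("    id ", idx[[n]]),
               paste0("    name \"", gml_escape(n), "\""),
               gml_emit_attrs(g$nattr[[n]] %||% list(), "    "),
               "  ]")
  }
  for (i in seq_along(g$edge_id)) {
    lines <- c(lines, "  edge [",
               paste0("    source ", idx[[g$edge_src[i]]]),
               paste0("    target ", idx[[g$edge_dst[i]]]),
               paste0("    name \"", gml_escape(g$edge_id[i]), "\""),
               gml_emit_attrs(g$eattr[[g$edge_id[i]]] %||% list(), "    "),
               "  ]")
  }
  lines <- c(lines, "]")
  writeLines(lines, path)
  invisible(path)
}

gml_tokenize <- function(text) {
  toks <- list(); n <- nchar(text); i <- 1L
  line <- 1L
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == "#") { while (i <= n && substr(text, i, i) != "\n") i <- i + 1L; next }
    if (ch == "[" || ch == "]") {
      toks[[length(toks) + 1L]] <- list(t = ch, line = line); i <- i + 1L; next
    }
    if (ch == "\"") {
      j <- i + 1L
      while (j <= n && substr(text, j, j) != "\"") j <- j + 1L
      if (j > n) stop2("GML parse error at line ", line, ": unterminated string")
      toks[[length(toks) + 1L]] <- list(t = "str",
                                        v = gml_unescape(substr(text, i + 1L, j - 1L)),
                                        line = line)
      i <- j + 1L; next
    }
    j <- i
    while (j <= n && !grepl("^[][:space:]\\[]$", substr(text, j, j))) j <- j + 1L
    word <- substr(text, i, j - 1L)
    toks[[length(toks) + 1L]] <-
      if (grepl("^[-+]?[0-9.][0-9.eE+-]*$", word))
        list(t = "num", v = as.numeric(word), raw = word, line = line)
      else list(t = "key", v = word, line = line)
    i <- j
  }
  toks
}

# parse a block of key/value pairs; returns list(entries=list of (key, value)),
# value is scalar or nested block list
gml_parse_block <- function(toks, pos, need_close = FALSE) {
  entries <- list()
  while (pos <= length(toks)) {
    tk <- toks[[pos]]
    if (tk$t == "]") return(list(entries = entries, pos = pos + 1L))
    # purely numeric key segments are legal in this dialect (replicate
    # indices, time points inside mapped-data paths)
    key <- if (tk$t == "key") tk$v
           else if (tk$t == "num") tk$raw
           else stop2("GML parse error at line ", tk$line,
                      ": expected key, got '", tk$t, "'")
    pos <- pos + 1L
    if (pos > length(toks)) stop2("GML parse error: value missing for '", key, "'")
    vt <- toks[[pos]]
    if (vt$t == "[") {
      r <- gml_parse_block(toks, pos + 1L, need_close = TRUE)
      entries[[length(entries) + 1L]] <- list(key = key, value = r$entries, block = TRUE)
      pos <- r$pos
    } else if (vt$t %in% c("num", "str")) {
      entries[[length(entries) + 1L]] <- list(key = key, value = vt$v, block = FALSE)
      pos <- pos + 1L
    } else stop2("GML parse error at line ", vt$line, ": bad value for '", key, "'")
  }
  if (need_close) stop2("GML parse error: unterminated block at end of file")
  list(entries = entries, pos = pos)
}

gml_flatten <- function(entries, prefix = "") {
  out <- list()
  for (e in entries) {
    p <- if (nzchar(prefix)) paste0(prefix, ".", e$key) else e$key
    if (e$block) out <- c(out, gml_flatten(e$value, p))
    else out[[p]] <- e$value
  }
  out
}

read_gml <- function(path) {
  toks <- gml_tokenize(paste(readLines(path, warn = FALSE), collapse = "\n"))
  # find top-level 'graph ['
  pos <- 1L
  while (pos <= length(toks) &&
         !(toks[[pos]]$t == "key" && toks[[pos]]$v == "graph")) pos <- pos + 1L
  if (pos > length(toks) || pos + 1L > length(toks) || toks[[pos + 1L]]$t != "[")
    stop2("GML parse error: no 'graph [' block found")
  r <- gml_parse_block(toks, pos + 2L, need_close = TRUE)
  directed <- TRUE
  gattr <- list(); nodes <- list(); edges <- list()
  for (e in r$entries) {
    if (e$key == "node" && e$block) nodes[[length(nodes) + 1L]] <- gml_flatten(e$value)
    else if (e$key == "edge" && e$block) edges[[length(edges) + 1L]] <- gml_flatten(e$value)
    else if (e$key == "directed" && !e$block) directed <- e$value != 0
    else if (e$block) gattr <- c(gattr, gml_flatten(e$value, e$key))
    else gattr[[e$key]] <- e$value
  }
  g <- og_graph(directed)
  g$gattr <- gattr
  idmap <- character()
  for (nd in nodes) {
    fid <- nd[["id"]]
    if (is.null(fid)) stop2("GML parse error: node without id")
    nid <- nd[["name"]] %||% paste0("n", format(fid, scientific = FALSE))
    nd[["id"]] <- NULL; nd[["name"]] <- NULL
    g <- og_add_node(g, nid, nd)
    idmap[[as.character(fid)]] <- nid
  }
  for (ed in edges) {
    s <- idmap[[as.character(ed[["source"]])]]
    t <- idmap[[as.character(ed[["target"]])]]
    if (is.null(s) || is.null(t) || is.na(s) || is.na(t))
      stop2("GML parse error: edge references unknown node id")
    eid <- ed[["name"]]
    ed[["source"]] <- NULL; ed[["target"]] <- NULL; ed[["name"]] <- NULL
    g <- og_add_edge(g, s, t, ed, id = eid)
  }
  g
}
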
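# SIF: one interaction per line, "source relation target [target2 ...]",
# whitespace- or tab-separated.  Node names double as ids; only the
# interaction type survives as an edge attribute.

read_sif <- function(path) {
  g <- og_graph(TRUE)
  lines <- readLines(path, warn = FALSE)
  seen <- character()
  ensure <- function(g, name) {
    if (!(name %in% og_nodes(g)))
      g <- og_add_node(g, name, list(label = name))
    g
  }
  for (li in seq_along(lines)) {
    ln <- trimws(lines[li])
    if (!nzchar(ln)) next
    parts <- strsplit(ln, "[ \t]+")[[1]]
    if (length(parts) == 1) { g <- ensure(g, parts[1]); next }  # isolated node
    if (length(parts) < 3)
      stop2("SIF parse error at line ", li, ": expected 'source relation target'")
    src <- parts[1]; rel <- parts[2]
    g <- ensure(g, src)
    for (dst in parts[-(1:2)]) {
      g <- ensure(g, dst)
      g <- og_add_edge(g, src, dst, list(interaction = rel))
    }
  }
  g
}

write_sif <- function(g, path) {
  lines <- character()
  touched <- character()
  for (i in seq_along(g$edge_id)) {
    rel <- og_get_attr(g, "edge", g$edge_id[i], "interaction", default = "i")
    lines <- c(lines, paste(g$edge_src[i], rel, g$edge_dst[i], sep = "\t"))
    touched <- c(touched, g$edge_src[i], g$edge_dst[i])
  }
  for (n in setdiff(g$nodes, touched)) lines <- c(lines, n)
  writeLines(lines, path)
  invisible(path)
}
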
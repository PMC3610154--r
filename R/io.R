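#' Read a network file
#'
#' Supported dialects: GML (ASCII nested key-value blocks), GraphML (XML with
#' typed key declarations), SIF (one "source relation target" line per
#' interaction) and the SBML Level 2/3 core topology subset (species,
#' reactions, stoichiometry; expanded into a bipartite species/process
#' graph).  All recognized and unrecognized attributes are loaded verbatim
#' under their dotted paths for GML/GraphML.
#'
#' @param path file path.
#' @param format one of \code{"gml"}, \code{"graphml"}, \code{"sif"},
#'   \code{"sbml"}; inferred from the file extension when missing
#'   (\code{.xml} and \code{.sbml} both mean SBML).
#' @return an \code{\link{og_graph}}.
#' @export
read_network <- function(path, format = NULL) {
  if (!file.exists(path)) stop2("file not found: ", path)
  format <- format %||% infer_format(path)
  switch(match.arg(format, c("gml", "graphml", "sif", "sbml")),
         gml = read_gml(path), graphml = read_graphml(path),
         sif = read_sif(path), sbml = read_sbml(path))
}

#' Write a network file
#'
#' GML and GraphML are the native formats: a write/read round trip
#' reproduces the graph exactly, including all attributes (order
#' insensitive).  SIF keeps only topology plus the interaction type.
#'
#' @param g an \code{\link{og_graph}}.
#' @inheritParams read_network
#' @export
write_network <- function(g, path, format = NULL) {
  check_graph(g)
  format <- format %||% infer_format(path)
  switch(match.arg(format, c("gml", "graphml", "sif")),
         gml = write_gml(g, path), graphml = write_graphml(g, path),
         sif = write_sif(g, path))
  invisible(path)
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         gml = "gml", graphml = "graphml", sif = "sif",
         sbml = "sbml", xml = "sbml",
         stop2("cannot infer network format from extension: '", ext,
               "' (use the format argument)"))
}
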
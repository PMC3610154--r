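# SBML Level 2/3 core, topology subset: species, reactions, stoichiometry,
# reversibility.  The reaction network is expanded into a bipartite graph:
# one simple_chemical node per species, one process node per reaction,
# reactant edges species -> process and product edges process -> species,
# with the stoichiometric coefficient on the edge "weight" attribute.
# Kinetic laws, rules, events and compartment geometry are ignored.

read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop2("SBML parse error: ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop2("SBML parse error: no <model> element")
  g <- og_graph(TRUE)
  for (sp in xml2::xml_find_all(model, ".//listOfSpecies/species")) {
    id <- xml2::xml_attr(sp, "id")
    if (is.na(id)) stop2("SBML parse error: species without id")
    attrs <- list(label = xml2::xml_attr(sp, "name") %||% id,
                  sbgn_class = "simple_chemical")
    if (is.na(attrs$label)) attrs$label <- id
    comp <- xml2::xml_attr(sp, "compartment")
    if (!is.na(comp)) attrs[["sbml.compartment"]] <- comp
    bc <- xml2::xml_attr(sp, "boundaryCondition")
    if (identical(bc, "true")) attrs[["boundary"]] <- 1
    g <- og_add_node(g, id, attrs)
  }
  for (rx in xml2::xml_find_all(model, ".//listOfReactions/reaction")) {
    rid <- xml2::xml_attr(rx, "id")
    if (is.na(rid)) stop2("SBML parse error: reaction without id")
    rev <- xml2::xml_attr(rx, "reversible")
    g <- og_add_node(g, rid, list(
      label = { nm <- xml2::xml_attr(rx, "name"); if (is.na(nm)) rid else nm },
      sbgn_class = "process",
      reversible = as.numeric(identical(rev, "true"))))
    refs <- function(xp) xml2::xml_find_all(rx, xp)
    for (sr in refs("./listOfReactants/speciesReference")) {
      sp <- xml2::xml_attr(sr, "species")
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
      if (is.na(st)) st <- 1
      g <- og_add_edge(g, sp, rid, list(weight = st))
    }
    for (sr in refs("./listOfProducts/speciesReference")) {
      sp <- xml2::xml_attr(sr, "species")
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
      if (is.na(st)) st <- 1
      g <- og_add_edge(g, rid, sp, list(weight = st))
    }
  }
  g
}
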
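#' End-to-end synthetic integration workflow
#'
#' Reproduces the full data-integration pipeline on synthetic inputs:
#' generate the block-correlated ecotype experiment, build and merge the
#' pathway networks, enrich identifiers from a mapping table, map the
#' experiment onto the network, run the 1:n correlation against the
#' morphological target and the thresholded n:n correlation network, lay
#' the result out as pathway circles, render an SVG figure, and export the
#' mapped data and a clickable HTML site.  Every stage logs a message;
#' a stage failure aborts with the stage name.
#'
#' @param config named list (or path to a JSON file) overriding defaults:
#'   \code{out_dir}, \code{seed}, \code{noise_sd}, \code{missing_rate},
#'   \code{conf_min}, \code{r_min}, \code{method}, \code{target},
#'   \code{rho} (uniform block loading), \code{n_conditions},
#'   \code{n_replicates}.
#' @return named list of artifact paths plus \code{result} (the n:n
#'   \code{CorrelationResult}) and \code{truth}.
#' @export
run_workflow <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(list(out_dir = tempfile("omicnet_run"), seed = 1,
                                noise_sd = 0.25, missing_rate = 0,
                                conf_min = 0.95, r_min = 0.6,
                                method = "pearson", target = "FW",
                                rho = 0.9, n_conditions = 50, n_replicates = 3),
                           as.list(config))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[workflow] ", name)
    tryCatch(expr, error = function(e)
      stop2("workflow stage '", name, "' failed: ", conditionMessage(e)))
  }
  paths <- list()

  blocks <- if (!is.null(cfg$blocks)) as.data.frame(cfg$blocks) else default_blocks()
  blocks$rho <- cfg$rho
  gen <- stage("generate experiment", {
    generate_experiment(synth_spec(n_conditions = cfg$n_conditions,
                                   n_replicates = cfg$n_replicates,
                                   blocks = blocks,
                                   noise_sd = cfg$noise_sd,
                                   missing_rate = cfg$missing_rate,
                                   seed = cfg$seed))
  })
  e <- gen$experiment
  paths$template <- file.path(cfg$out_dir, "experiment.csv")
  write_template(e, paths$template)
  paths$truth_json <- file.path(cfg$out_dir, "truth.json")
  jsonlite::write_json(gen$truth, paths$truth_json, auto_unbox = TRUE, digits = NA)

  net <- stage("merge pathway networks", {
    merge_networks(generate_pathway_networks(gen$truth))
  })

  net <- stage("enrich identifiers", {
    tab <- file.path(cfg$out_dir, "mapping_table.csv")
    subs <- e$substances$name
    writeLines(paste(subs, paste0("SYN_", subs), sep = ","), tab)
    paths$mapping_table <- tab
    enrich_identifiers(net, read_mapping_table(tab))
  })

  mp <- stage("map experiment", map_experiment(net, e, create_missing = TRUE))
  g <- mp$graph
  # created morphological nodes join the layout as their own pathway ring
  for (n in mp$report$created)
    g <- og_set_attr(g, "node", n, "pathway", "Morphology")
  paths$mapped <- file.path(cfg$out_dir, "mapped.graphml")
  write_network(g, paths$mapped, "graphml")
  paths$mapped_data <- file.path(cfg$out_dir, "mapped_data.csv")
  export_mapped_data(g, paths$mapped_data)

  g1 <- stage("1:n correlation", correlate_one_to_n(g, cfg$target, cfg$method))
  paths$corr_1n <- file.path(cfg$out_dir, "corr_1n.graphml")
  write_network(g1, paths$corr_1n, "graphml")

  nn <- stage("n:n correlation", {
    correlate_n_to_n(g, cfg$method, conf_min = cfg$conf_min, r_min = cfg$r_min)
  })
  paths$corr_nn_csv <- file.path(cfg$out_dir, "corr_nn.csv")
  write_correlation_csv(nn$result, paths$corr_nn_csv)

  gnn <- stage("pathway-circles layout", layout_network(nn$graph, "pathway_circles"))
  paths$corr_nn <- file.path(cfg$out_dir, "corr_nn.graphml")
  write_network(gnn, paths$corr_nn, "graphml")

  stage("render figure", {
    paths$figure <- file.path(cfg$out_dir, "figure.svg")
    render_network(gnn, paths$figure, "svg", charts = chart_spec("bar"))
  })
  stage("export html", {
    site <- export_html(gnn, file.path(cfg$out_dir, "site"))
    paths$html <- site$html
  })
  c(paths, list(result = nn$result, truth = gen$truth, graph = gnn))
}
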
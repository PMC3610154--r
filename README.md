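# omicnet

Network-based integration and analysis of omics data, as a headless,
scriptable R package.

Systems-biology studies routinely produce structured measurement panels —
metabolite levels, enzyme activities, morphological parameters across
genotypes, ecotypes, treatments and time — whose interpretation depends on
seeing them *on* the biochemical network they belong to. omicnet is for
scientists and pipeline authors who want that integration reproducible and
automatable rather than clicked together in a GUI: every step, from file
parsing to the final figure, is an ordinary R function call.

## What it does

* **Attributed graphs** (`og_graph`): a directed multigraph with dotted
  hierarchical attributes on graph, nodes and edges; readers/writers for
  GML, GraphML (lossless round trip, all attributes), SIF, and the SBML
  Level 2/3 core topology subset (bipartite species/process expansion with
  stoichiometric edge weights). Structural editing: merging pathway maps by
  fusing shared metabolite nodes, splitting cofactor hubs such as ATP,
  derived attributes.
* **Experiment data** (`experiment`, `read_template`, `read_csv_long`,
  `read_mapping_table`): a substances × conditions × times × replicates
  tensor with per-substance kind and unit; missing cells stay missing.
* **Data mapping** (`map_experiment`, `enrich_identifiers`): identifier-
  based matching of substances onto nodes, constrained by SBGN class
  (metabolite data onto simple-chemical glyphs, enzyme activities onto
  macromolecules), new nodes for unmatched parameters, full mapping report.
* **Statistics** (`correlate`, `correlate_one_to_n`, `correlate_n_to_n`,
  `t_test`, `grubbs_test`, `david_quicktest`, `enrichment`): Pearson /
  Spearman correlation with 1:n and thresholded n:n correlation networks
  (defaults: confidence ≥ 0.95, |r| ≥ 0.6), pooled/Welch/Mann-Whitney
  two-sample tests (exact small-sample enumeration), Grubbs outlier test,
  David quicktest for normality, hypergeometric category enrichment.
* **SOM clustering** (`train_som`, `assign_clusters`): seeded,
  deterministic self-organizing-map quantization of mapped profiles with
  cluster attributes written back to the network.
* **Topology** (`shortest_paths`, `find_cycles`, `find_motifs`,
  `centralities`): BFS/Dijkstra paths, elementary circuits and cycle
  bases, subgraph-isomorphism motif search (e.g. feed-forward loops) with
  class constraints, eight centrality measures.
* **Petri nets** (`to_petri_net`, `fire`, `simulate_petri`, `invariants`,
  `reachability`, PNML I/O): discrete token-game semantics, minimal-support
  P/T-invariants by exact-integer Farkas elimination
  (xᵀC = 0 / Cx = 0), capped reachability graphs.
* **Constraint-based analysis** (`from_graph`, `fba`, `fva`, `knockout`,
  `robustness`): flux balance analysis max cᵀv s.t. Sv = 0, lb ≤ v ≤ ub,
  flux variability at an optimum fraction, knockout and robustness scans.
* **Visualization** (`layout_network`, `render_network`, `export_html`):
  force-directed / circle / grid / tree / pathway-circles layouts, SVG and
  PNG rendering with in-glyph bar/line/pie/heatmap charts of the mapped
  data, correlation color coding (red = negative, blue = positive), linear
  flux-to-thickness edge scaling, clickable HTML image maps.
* **Synthetic data + workflow** (`generate_experiment`,
  `generate_network`, `run_workflow`): a block-correlated ecotype-panel
  generator (64 metabolites / 37 enzymes / morphological target across 50
  ecotypes by default) with ground-truth labels, and a one-call pipeline
  import → merge → enrich → map → 1:n → n:n → layout → render → export.

A thin command-line interface wraps the same functions:
`inst/cli/omicnet convert|import|map|correlate|som|topology|petri|fba|render|workflow`.

## Worked example

Map an experiment onto a small network and build the thresholded
correlation network:

```r
library(omicnet)

g <- og_graph()
g <- og_add_node(g, "glc", list(label = "Glc", sbgn_class = "simple_chemical"))
g <- og_add_node(g, "hxk", list(label = "HXK", sbgn_class = "macromolecule"))

# a mapping table teaches the Glc node its synonym "Glucose"
tab <- tempfile(fileext = ".csv"); writeLines("Glc,Glucose", tab)
g <- enrich_identifiers(g, read_mapping_table(tab))

# synthetic panel: two correlated pathway blocks over 20 ecotypes
gen <- generate_experiment(synth_spec(n_conditions = 20, n_replicates = 3,
  blocks = data.frame(name = c("Sugars", "EnzSugar"), size = c(4, 3),
                      kind = c("metabolite", "enzyme"), rho = 0.9),
  target_coupling = c(Met01 = 0.9), seed = 1))
e <- gen$experiment
e$substances$name[1] <- "Glucose"   # align two substances with the network
e$substances$name[5] <- "HXK"

r <- map_experiment(g, e)
r$report
#> <mapping report: 2 mapped, 6 created, 0 unmapped, 0 ambiguous>
```

Glucose landed on the simple-chemical node, the HXK activity on the
macromolecule node, and the six remaining substances became new nodes.
Now the n:n correlation network at the default thresholds:

```r
nn <- correlate_n_to_n(r$graph, conf_min = 0.95, r_min = 0.6)
nn$result
#> <correlation result (pearson): 28 pairs tested, 7 edges at conf>=0.95, |r|>=0.6>
head(nn$result$edges[, c("i", "j", "r", "p", "n")], 3)
#>      i    j         r            p  n
#> 1  hxk sub1 0.8455125 2.678827e-06 20
#> 2  hxk sub2 0.9026264 5.225202e-08 20
#> 3 sub1 sub2 0.8419898 3.237289e-06 20
```

All 28 node pairs were tested; 7 passed both thresholds — the within-block
pairs of the planted ρ = 0.9 blocks. Each edge records the coefficient,
its p-value and the pairwise-complete sample size, and is colored by sign
and magnitude. Replicate summaries are one call:

```r
summarize_experiment(e, "Glucose", "Eco01")
#>   time time_unit n    mean       sd       sem
#> 1    0         d 3 7.04444 0.393408 0.2271342
```

For the full pipeline (pathway-circle figure, HTML site, exports):

```r
res <- run_workflow(list(out_dir = "runs/demo", seed = 1))
# runs/demo/: experiment.csv, mapped.graphml, corr_1n.graphml,
#             corr_nn.graphml, corr_nn.csv, figure.svg, site/index.html, ...
```

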
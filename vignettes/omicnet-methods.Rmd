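---
title: "omicnet: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{omicnet: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

omicnet is a headless toolkit for network-based integration of omics data:
it loads biological networks and structured experiment data, attaches
measurements to network elements by identifier matching, and runs the
downstream analyses that make such integrated networks useful —
correlation networks, clustering, structural analysis, discrete Petri-net
simulation and constraint-based flux analysis — with publication-ready
SVG/PNG/HTML output. This vignette documents the models, the conventions
and the design decisions; the README shows a worked example.

## The attributed graph

Everything operates on one substrate, `og_graph()`: a directed multigraph
whose graph, nodes and edges carry flat maps from *dotted attribute paths*
(`"graphics.fill"`, `"mapping.Glc.Eco01.0.1"`) to scalar values. Design
choices worth knowing:

* **Node identity is an opaque id; labels are attributes.** Duplicate
  labels are legal and meaningful — pre-merge pathway copies and split
  cofactor clones both rely on them. Operations key on labels only where
  stated (`merge_networks`, data mapping).
* **Coordinates use the screen convention**: origin top-left, y grows
  downward, the node anchor is its center. This matches what typical
  graph editors emit in GML and keeps SVG output trivial.
* **Edge multiplicity is allowed** so that split/merge cycles never lose
  parallel connections.
* Synonym lists (`alt_ids`) are stored as one `|`-joined scalar so they
  survive any format round trip unchanged.

### File formats

GML and GraphML are the native formats: a write/read round trip
reproduces the graph exactly, attributes included. Dotted paths map to
nested GML records and to typed GraphML `<key>` declarations; unknown
attributes round-trip verbatim. Two quirks are deliberate:

* In GML, purely numeric key segments (replicate indices, time points)
  are accepted by the reader even though classic GML grammar would not —
  mapped-data paths need them.
* In GraphML one key is declared per `(scope, path, type)` triple, so a
  path that is numeric on one element and textual on another keeps both
  storage types.

SIF carries topology plus the interaction type only. SBML import covers
the Level 2/3 core topology subset — species, reactions, stoichiometry,
reversibility — expanded into a bipartite graph (species nodes + process
nodes, stoichiometric coefficients as edge weights). Kinetics, rules and
compartment geometry are ignored; that is a scope decision, not a
roadmap gap.

### Editing

`merge_networks` fuses nodes sharing a key value (label by default),
optionally restricted to SBGN classes; fusion applies within a single
input too, which makes the operation idempotent. Conflicting SBGN classes
in a fuse group are an error rather than a guess. `split_node` replaces a
hub such as ATP with one clone per incident edge (a self-loop becomes a
clone pair), preserving edge count and total degree. `compute_attribute`
aggregates numeric values below a source path (mean/median/min/max) or
writes node degrees.

## Experiment data

`experiment()` stores a substances × samples matrix with per-substance
kind (metabolite, enzyme, morphological, gene, other) and unit, and a
sample axis of (condition, time, time unit, replicate). Missing cells are
`NA`, never zeros, and are never imputed: every downstream statistic uses
pairwise-complete observations, because natural-accession panels are
ragged.

The template dialect is self-defined (a deterministic parse was the
goal): a plain-text CSV whose first four body rows declare condition /
time / time unit / replicate per measurement column, with substance name,
kind and unit in the first three columns and `#meta` header lines on top.
An `.xlsx` workbook with `meta` and `data` sheets in the same layout is
accepted when readxl is installed; the write path is CSV. Long-format CSV
import (`read_csv_long`) folds one-measurement-per-row tables into the
same structure, with defaults standing in for meta-data the format lacks.

## Data mapping

`map_experiment` attaches measurements to nodes when substance name or
any synonym equals the node label or any alt id — case-insensitive and
whitespace-trimmed by default (a strict mode exists) — **and** the node's
SBGN class agrees with the substance kind under the class rule
(metabolite → simple chemical, enzyme → macromolecule, ...). Two
decisions here:

* **Ambiguity maps to all admissible nodes** and is reported. Split
  cofactor clones legitimately repeat a label and all of them should
  receive the data.
* **Unmatched substances become new isolated nodes** when
  `create_missing` — this is how morphological parameters such as fresh
  weight enter a metabolic network.

Values live under `mapping.<substance>.<condition>.<time>.<replicate>`
(dots inside names become `_`), so mapped graphs round-trip bit-exactly
through GML/GraphML, and `export_mapped_data` can always reconstruct a
flat re-importable table.

## Correlation analyses

Profiles are per-condition replicate means — one value per ecotype — from
`og_profile_matrix`. `correlate` implements Pearson's product-moment
formula with the two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, and Spearman on
mid-ranks; for Spearman below $n = 10$ an exact permutation p-value
replaces the t approximation. At least 3 complete pairs are required;
zero variance is an error, not a silent `NA`.

`correlate_one_to_n` annotates every mapped node with (r, p, n) against a
target profile and colors nodes on the diverging scale.
`correlate_n_to_n` tests all unordered pairs and inserts a correlation
edge when confidence ≥ `conf_min` and |r| ≥ `r_min`, defaults 0.95 and
0.6. The confidence phrasing is intentional: the workflow this reproduces
states its threshold as *p* ≥ 0.95 alongside "strong correlation", which
is only coherent as confidence = 1 − p-value; a literal p-value ≥ 0.95
would select the *non*-significant pairs. No multiple-testing correction
is applied by default (the thresholds are raw by design); Benjamini-
Hochberg is available via `adjust = "BH"`.

## Statistical tests

* `t_test` — pooled and Welch variants delegate to `stats::t.test`; the
  Mann-Whitney variant is implemented here with an exact two-sided
  p-value by complete enumeration of group labelings when
  $n_a + n_b \le 12$ (ties handled with half-counts), and the
  tie-corrected normal approximation with continuity correction above.
* `grubbs_test` — $G = \max_i |x_i - \bar x| / s$ against the closed-form
  critical value $\frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}$, $t$ the upper
  $\alpha/(2n)$ Student quantile with $n-2$ df. Constant samples are
  degenerate (no outlier), not an error.
* `david_quicktest` — the studentized range $q = \mathrm{range}/s$
  against two-sided critical bounds for $n \in [3, 100]$,
  $\alpha \in \{0.05, 0.01\}$. The bounds shipped in
  `inst/extdata/david_quicktest_bounds.csv` are quantiles of the null
  distribution of $q$ obtained from a seeded Monte-Carlo simulation
  (5×10⁵ standard-normal samples per n); the test suite confirms the
  resulting rejection rate is calibrated at α.
* `enrichment` — hypergeometric upper tail
  $P(X \ge k)$ with $N$ = universe, $K$ = term members in the universe,
  $n$ = query size (equivalently the one-sided Fisher exact tail, which
  the tests verify), with optional BH adjustment.

## SOM clustering

`train_som` quantizes profile rows with a 1×k chain of prototype units by
default — the interface asks for a target cluster count, and a chain is
the faithful geometry for that; 2-D grids are available through `grid`.
Schedule: prototypes initialized from seeded draws of the data rows
(scale-free and reproducible), per epoch a seeded shuffle of rows, each
sample pulling its best-matching unit and neighbors with a Gaussian
neighborhood; learning rate (initial 0.5) and radius (initial half the
grid span) decay exponentially to ~5% over the epochs. Rows are z-scored
by default because metabolite, enzyme and morphological units are not
commensurable; missing cells are row-mean imputed and flagged.
Everything is deterministic given the seed, ties in assignment break
toward the lowest unit index, and assignment is row-order invariant.

## Topology

`shortest_paths` is BFS, or Dijkstra under a nonnegative weight
attribute. `find_cycles` enumerates elementary circuits of directed
graphs as node sequences (each circuit once, rooted at its smallest
node; parallel arcs do not multiply circuits) with a configurable cap,
and returns a spanning-forest cycle basis for undirected graphs.
`find_motifs` is an authored backtracking subgraph-isomorphism matcher:
non-induced by default, injective on nodes, honoring SBGN-class
constraints on pattern nodes, with matches deduplicated modulo pattern
automorphisms. `centralities` implements eight measures; conventions:
closeness is the harmonic variant (finite on disconnected graphs),
eccentricity and eigenvector centrality ignore direction, betweenness
(Brandes, via igraph) counts unnormalized dependent pairs, eigenvector
centrality is a power iteration on the (shifted) adjacency — the shift
suppresses the oscillation bipartite graphs would otherwise cause — with
tolerance 1e-10 and at most 10⁴ iterations, and Katz centrality solves
$x = ((I - \alpha A^T)^{-1} - I)\mathbf 1$ with a check that
$\alpha < 1/\lambda_{\max}$.

## Petri nets

`to_petri_net` maps simple chemicals to places and processes to
transitions; an edge between two same-class nodes is a structure error
(the batch analogue of an interactive fix-up). Reversible processes
expand into opposing transition pairs. The default marking is zero —
tokens must be set explicitly, which prevents accidentally unbounded
exploration. Invariants use the Farkas/Fourier-Motzkin elimination on the
incidence matrix in exact integer arithmetic, with gcd normalization and
minimal-support pruning after every eliminated column; place invariants
satisfy $x^T C = 0$, transition invariants $C x = 0$, both asserted
exactly in the tests. `reachability` is a BFS with a state cap
(default 10⁵) and a truncation flag; `simulate_petri` offers a seeded
random single-firing policy and a deterministic maximal policy (index
order scan, firing every transition found enabled).

## Constraint-based analysis

`from_graph` builds the stoichiometric matrix from edge weights (consumed
negative, produced positive). Metabolites flagged `boundary` have their
balance rows dropped — equivalent to an unconstrained exchange reaction,
chosen over synthesizing explicit exchange columns to keep toy models
minimal. `fba` maximizes $c^T v$ subject to $S v = 0$ and bounds through
an LP wrapper around `pracma::linprog` (variables shifted to nonnegative
form, equalities as paired inequalities). Degenerate alternate optima
return one solver-chosen vertex; uniqueness claims belong to `fva`, which
re-solves two LPs per reaction under $c^T v \ge f z^*$ (fraction
`f = 1` by default, i.e. at the optimum). `knockout` fixes a reaction to
zero; `robustness` scans a reaction across its *feasible* range (the
`f = 0` FVA interval) at `n_steps = 20` grid points, recording the
re-optimized objective — concave for LP models, which the tests check by
second differences.

## Rendering

Layouts write center-anchored screen coordinates: circle, grid, tree
(acyclic input required), seeded force-directed (deterministic per seed,
with a nudge pass guaranteeing distinct coordinates), and
`pathway_circles`, which places each pathway's nodes on its own circle
and the circles on an outer ring — the layout of the pathway-level
correlation figure. SVG is emitted as plain markup (one `<g
class="node">` per glyph, one `<g class="chart">` per mapped node), which
makes the output directly assertable in tests; PNG goes through the
cairo device. Glyph shapes approximate SBGN: ellipse for simple
chemicals, rounded rectangle for macromolecules, small square for
processes — no SBGN-ML conformance is claimed. The correlation color
scale is linear red-white-blue on [−1, 1], clamped, odd-symmetric. Flux
edge thickness is the linear transfer
$t_{\min} + (t_{\max}-t_{\min})\,|v|/\max|v|$; the transfer function is a
documented choice, not a reproduction of any particular tool's pixels.
`export_html` renders an image plus a client-side image map with one
region per node and hyperlinks from `url` attributes.

## The synthetic generator

`generate_experiment` emulates the structure of a published ecotype
panel: 64 metabolites and 37 enzyme activities organized in pathway
blocks, one morphological target ("FW"), 50 conditions. Neither the
replicate count nor the block sizes of the original dataset are printed
anywhere accessible to this package, so the defaults are a scientist's
plausible choice, fixed once: 3 replicates, eight metabolite pathways of
8 and four enzyme groups of 9–10, uniform within-block loading ρ = 0.9,
a per-substance scale whose sd is 15% of its mean, replicate noise with
sd 0.25 × that scale sd, and one planted coupling (Met01 ↔ FW, r = 0.9).

The construction makes exactness statements possible: block factors are
*exactly* orthogonal, mean-zero, unit-sd per condition panel (centered
Gram-Schmidt), and substance profiles are
$\rho z_b + \sqrt{1-\rho^2}\,\varepsilon_s$ before an affine scale into
realistic units. With ρ = 1 and zero replicate noise the empirical
within-block correlation is exactly 1 and across-block exactly 0, so the
n:n network at the workflow thresholds equals the planted block graph
with precision = recall = 1 — the property the acceptance suite measures.
Ground truth travels in a sidecar list, never inside the `experiment`,
to keep pipeline stages honest.

What the generator does **not** emulate: the real panel's missingness
pattern (a uniform `missing_rate` knob stands in), lognormal
concentration tails, batch or run-order effects, and condition-dependent
replicate variance. Passing tests therefore demonstrate correctness of
the machinery under a clean factor model, not robustness to every
artifact of real measurement campaigns.

## Problem sizes and runtime

The test suite and acceptance script run at deliberately modest sizes —
the full 102-substance × 50-ecotype workflow for the recovery checks,
30-profile panels for correlation oracles, ≤5-place random nets for
Petri oracles, 100 random graphs for round trips, 5000 simulations for
test calibration — chosen so the whole suite completes in well under a
minute on one CPU while still exercising every code path at the scale
the emulated study uses.

## Known limitations

* GML numeric keys and the CSV template dialect are this package's own
  documented conventions; no bit-compatibility with any external tool's
  files is claimed beyond standard GML/GraphML/SIF/SBML parsing.
* The LP backend is a dense tableau simplex — fine for pathway-scale
  models, not for genome-scale reconstructions.
* Elementary-circuit enumeration and motif matching are exponential in
  the worst case; both are capped/intended for the small patterns and
  networks they are specified for.
* Continuous Petri nets, kinetic SBML simulation, BioPAX/KGML import and
  live database connectivity are out of scope.
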
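#' Specification for the synthetic ecotype-panel generator
#'
#' Describes a block-correlated measurement panel shaped like the
#' supplementary dataset the package workflow emulates: 64 metabolites and
#' 37 enzyme activities organised in pathway blocks, one morphological
#' target parameter (fresh weight, "FW"), profiles across 50 ecotype
#' conditions with replicated measurements.  Within a block every substance
#' follows the block's latent factor with correlation loading \code{rho};
#' block factors are mutually orthogonal (exactly, by construction), so with
#' \code{rho = 1} and zero replicate noise the empirical within-block
#' correlation is exactly 1 and the across-block correlation exactly 0.
#'
#' @param n_conditions ecotype count.
#' @param n_replicates replicates per condition.
#' @param blocks data frame (name, size, kind, rho) partitioning the
#'   metabolite and enzyme substances into pathway blocks.
#' @param target_coupling named numeric vector: substance -> planted
#'   correlation with the morphological target profile.
#' @param noise_sd replicate noise, as a fraction of each substance's scale.
#' @param missing_rate probability that a single measurement is absent.
#' @param seed generator seed.
#' @export
synth_spec <- function(n_conditions = 50, n_replicates = 3,
                       blocks = default_blocks(),
                       target_coupling = c(Met01 = 0.9),
                       noise_sd = 0.25, missing_rate = 0, seed = 1) {
  blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "size", "kind", "rho") %in% names(blocks)))
  if (any(abs(blocks$rho) > 1)) stop2("|rho| must be <= 1")
  if (n_conditions <= nrow(blocks) + 2)
    stop2("need more conditions than blocks for orthogonal factors")
  structure(list(n_conditions = n_conditions, n_replicates = n_replicates,
                 blocks = blocks, target_coupling = target_coupling,
                 noise_sd = noise_sd, missing_rate = missing_rate, seed = seed),
            class = "omic_synth_spec")
}

#' @rdname synth_spec
#' @export
default_blocks <- function() {
  data.frame(
    name = c("Glycolysis", "TCA_cycle", "AminoAcids", "Sugars", "Nucleotides",
             "Lipids", "SecondaryMet", "CellWall",
             "EnzGlycolysis", "EnzTCA", "EnzSugarMet", "EnzAminoAcid"),
    size = c(8, 8, 8, 8, 8, 8, 8, 8, 9, 9, 9, 10),
    kind = c(rep("metabolite", 8), rep("enzyme", 4)),
    rho = 0.9,
    stringsAsFactors = FALSE)
}

synth_substances <- function(spec) {
  met_i <- 0L; enz_i <- 0L
  rows <- list()
  for (b in seq_len(nrow(spec$blocks))) {
    for (k in seq_len(spec$blocks$size[b])) {
      if (spec$blocks$kind[b] == "metabolite") {
        met_i <- met_i + 1L
        nm <- sprintf("Met%02d", met_i); unit <- "nmol/gFW"
      } else {
        enz_i <- enz_i + 1L
        nm <- sprintf("Enz%02d", enz_i); unit <- "nmol/min/gFW"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, kind = spec$blocks$kind[b], unit = unit,
        block = spec$blocks$name[b], stringsAsFactors = FALSE)
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(name = "FW", kind = "morphological",
                                          unit = "g", block = "Morphology",
                                          stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

# centered Gram-Schmidt: columns exactly mean-zero, mutually orthogonal,
# unit sd
ortho_factors <- function(n, k) {
  L <- matrix(stats::rnorm(n * k), n, k)
  L <- sweep(L, 2, colMeans(L))
  for (j in seq_len(k)) {
    if (j > 1) {
      prev <- L[, seq_len(j - 1), drop = FALSE]
      L[, j] <- L[, j] - prev %*% solve(crossprod(prev), crossprod(prev, L[, j]))
    }
    L[, j] <- L[, j] / stats::sd(L[, j])
  }
  L
}

#' Generate a synthetic block-correlated experiment
#'
#' Draws per-condition latent factors (one per pathway block plus one for
#' the morphological target, exactly orthogonal and standardized), builds
#' substance profiles \eqn{\rho z_b + \sqrt{1-\rho^2}\,\epsilon_s}, plants
#' the requested substance-target correlations, applies a per-substance
#' affine scale (realistic units) and adds i.i.d. replicate noise.  Fully
#' reproducible from the spec's seed.  Ground-truth block memberships and
#' couplings are returned alongside the experiment, never inside it.
#'
#' @param spec a \code{\link{synth_spec}}.
#' @return list: \code{experiment} (an \code{omic_experiment}) and
#'   \code{truth} (list: \code{membership} data frame substance/block/kind,
#'   \code{target}, \code{coupling}).
#' @export
generate_experiment <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "omic_synth_spec"))
  subs <- synth_substances(spec)
  nb <- nrow(spec$blocks)
  with_seed(spec$seed, {
    L <- ortho_factors(spec$n_conditions, nb + 1L)  # last column: target factor
    tgt <- L[, nb + 1L]
    profiles <- matrix(NA_real_, nrow(subs), spec$n_conditions)
    for (i in seq_len(nrow(subs))) {
      if (subs$kind[i] == "morphological") { profiles[i, ] <- tgt; next }
      b <- match(subs$block[i], spec$blocks$name)
      rho <- spec$blocks$rho[b]
      eps <- stats::rnorm(spec$n_conditions)
      eps <- (eps - mean(eps)) / stats::sd(eps)
      profiles[i, ] <- rho * L[, b] + sqrt(1 - rho^2) * eps
    }
    for (s in names(spec$target_coupling)) {
      i <- match(s, subs$name)
      if (is.na(i)) stop2("target_coupling names unknown substance: ", s)
      r <- spec$target_coupling[[s]]
      eps <- stats::rnorm(spec$n_conditions)
      eps <- (eps - mean(eps)) / stats::sd(eps)
      profiles[i, ] <- r * tgt + sqrt(1 - r^2) * eps
    }
    scale_mu <- stats::runif(nrow(subs), 5, 50)
    scale_sd <- 0.15 * scale_mu
    conds <- sprintf("Eco%02d", seq_len(spec$n_conditions))
    samples <- data.frame(
      condition = rep(conds, each = spec$n_replicates),
      time = 0, time_unit = "d",
      replicate = rep(seq_len(spec$n_replicates), spec$n_conditions),
      stringsAsFactors = FALSE)
    vals <- matrix(NA_real_, nrow(subs), nrow(samples))
    for (i in seq_len(nrow(subs))) {
      base <- scale_mu[i] + scale_sd[i] * profiles[i, ]
      noise <- matrix(stats::rnorm(length(base) * spec$n_replicates,
                                   sd = spec$noise_sd * scale_sd[i]),
                      spec$n_replicates, length(base))
      vals[i, ] <- as.vector(sweep(noise, 2, base, `+`))
    }
    if (spec$missing_rate > 0) {
      drop <- stats::runif(length(vals)) < spec$missing_rate
      vals[drop] <- NA_real_
    }
    e <- experiment(subs[, c("name", "kind", "unit")], samples, vals,
                    meta = list(name = "synthetic ecotype panel",
                                coordinator = "omicnet generator",
                                seed = spec$seed))
    truth <- list(membership = subs[, c("name", "block", "kind")],
                  target = "FW", coupling = spec$target_coupling)
    list(experiment = e, truth = truth)
  })
}

#' Generate small metabolic test networks
#'
#' Bipartite SBGN-style graphs (simple_chemical metabolite nodes joined by
#' process nodes, stoichiometry 1): a linear \code{chain}, a closed
#' \code{cycle}, a \code{branched} pathway (one branch point, two product
#' arms), or \code{two_pathways} — a list of two chains sharing exactly one
#' metabolite label ("Pyruvate"), ready to be fused by
#' \code{\link{merge_networks}}.
#'
#' @param kind network family. @param size number of metabolites (>= 2).
#' @return an \code{omic_graph}, or a list of two for \code{two_pathways}.
#' @export
generate_network <- function(kind = c("chain", "cycle", "branched",
                                      "two_pathways"), size = 4) {
  kind <- match.arg(kind)
  if (size < 2) stop2("size must be >= 2")
  mk_chain <- function(labels, prefix, pathway = NULL) {
    g <- og_graph()
    for (i in seq_along(labels)) {
      at <- list(label = labels[i], sbgn_class = "simple_chemical")
      if (!is.null(pathway)) at$pathway <- pathway
      g <- og_add_node(g, paste0(prefix, "m", i), at)
      if (i > 1) {
        at <- list(label = paste0(prefix, "r", i - 1), sbgn_class = "process")
        if (!is.null(pathway)) at$pathway <- pathway
        g <- og_add_node(g, paste0(prefix, "r", i - 1), at)
        g <- og_add_edge(g, paste0(prefix, "m", i - 1), paste0(prefix, "r", i - 1),
                         list(weight = 1))
        g <- og_add_edge(g, paste0(prefix, "r", i - 1), paste0(prefix, "m", i),
                         list(weight = 1))
      }
    }
    g
  }
  switch(kind,
    chain = mk_chain(paste0("M", seq_len(size)), "c"),
    cycle = {
      g <- mk_chain(paste0("M", seq_len(size)), "c")
      g <- og_add_node(g, paste0("cr", size),
                       list(label = paste0("cr", size), sbgn_class = "process"))
      g <- og_add_edge(g, paste0("cm", size), paste0("cr", size), list(weight = 1))
      og_add_edge(g, paste0("cr", size), "cm1", list(weight = 1))
    },
    branched = {
      stem <- max(2, size - 2)
      g <- mk_chain(paste0("M", seq_len(stem)), "c")
      for (arm in c("A", "B")) {
        g <- og_add_node(g, paste0("r", arm),
                         list(label = paste0("r", arm), sbgn_class = "process"))
        g <- og_add_node(g, paste0("m", arm),
                         list(label = paste0("M", arm), sbgn_class = "simple_chemical"))
        g <- og_add_edge(g, paste0("cm", stem), paste0("r", arm), list(weight = 1))
        g <- og_add_edge(g, paste0("r", arm), paste0("m", arm), list(weight = 1))
      }
      g
    },
    two_pathways = list(
      mk_chain(c(paste0("A", seq_len(size - 1)), "Pyruvate"), "p1", "PathwayA"),
      mk_chain(c("Pyruvate", paste0("B", seq_len(size - 1))), "p2", "PathwayB")))
}

#' Pathway display networks matching a synthetic experiment
#'
#' One graph per ground-truth block: metabolite blocks become linear
#' pathway chains whose simple-chemical nodes are labeled by the member
#' substances; enzyme blocks become groups of macromolecule nodes.  Every
#' node carries the \code{"pathway"} attribute, so the merged network is
#' ready for data mapping and the pathway-circles layout.
#'
#' @param truth the \code{truth} component of
#'   \code{\link{generate_experiment}}'s result.
#' @return list of \code{omic_graph}s.
#' @export
generate_pathway_networks <- function(truth) {
  blocks <- split(truth$membership,
                  factor(truth$membership$block,
                         levels = unique(truth$membership$block)))
  out <- list()
  for (bn in names(blocks)) {
    mem <- blocks[[bn]]
    if (bn == "Morphology") next
    g <- og_graph()
    if (all(mem$kind == "metabolite")) {
      for (i in seq_len(nrow(mem))) {
        g <- og_add_node(g, paste0(bn, ".m", i),
                         list(label = mem$name[i], sbgn_class = "simple_chemical",
                              pathway = bn))
        if (i > 1) {
          rid <- paste0(bn, ".r", i - 1)
          g <- og_add_node(g, rid, list(label = rid, sbgn_class = "process",
                                        pathway = bn))
          g <- og_add_edge(g, paste0(bn, ".m", i - 1), rid, list(weight = 1))
          g <- og_add_edge(g, rid, paste0(bn, ".m", i), list(weight = 1))
        }
      }
    } else {
      for (i in seq_len(nrow(mem)))
        g <- og_add_node(g, paste0(bn, ".e", i),
                         list(label = mem$name[i], sbgn_class = "macromolecule",
                              pathway = bn))
    }
    out[[bn]] <- g
  }
  out
}
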
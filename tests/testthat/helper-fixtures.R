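# fixtures are built in code at test time

# random attributed multigraph with dotted attribute paths on all scopes
random_graph <- function(n_nodes = sample(2:10, 1), p_edge = 0.3,
                         directed = TRUE) {
  g <- og_graph(directed)
  paths <- c("label", "graphics.x", "graphics.y", "graphics.fill",
             "sbgn_class", "mapping.Glc.Eco1.0.1", "note.deep.nested.key")
  rand_attrs <- function() {
    k <- sample(0:4, 1)
    if (k == 0) return(list())
    ps <- sample(paths, k)
    stats::setNames(lapply(ps, function(p) {
      if (runif(1) < 0.5) round(runif(1, -100, 100), 4)
      else paste0(sample(c(letters, " ", "&", "\""), 6, TRUE), collapse = "")
    }), ps)
  }
  ids <- paste0("v", seq_len(n_nodes))
  for (id in ids) g <- og_add_node(g, id, rand_attrs())
  for (a in ids) for (b in ids) {
    if (a == b) next
    if (runif(1) < p_edge)
      g <- og_add_edge(g, a, b, rand_attrs())
  }
  g
}

# small bipartite metabolic chain M1 -> r1 -> M2 -> ... with markings
chain_graph <- function(k, marking1 = 0) {
  g <- og_graph()
  for (i in seq_len(k)) {
    at <- list(label = paste0("M", i), sbgn_class = "simple_chemical")
    if (i == 1 && marking1 > 0) at$marking <- marking1
    g <- og_add_node(g, paste0("m", i), at)
    if (i > 1) {
      g <- og_add_node(g, paste0("r", i - 1),
                       list(label = paste0("r", i - 1), sbgn_class = "process"))
      g <- og_add_edge(g, paste0("m", i - 1), paste0("r", i - 1), list(weight = 1))
      g <- og_add_edge(g, paste0("r", i - 1), paste0("m", i), list(weight = 1))
    }
  }
  g
}

# tiny experiment: substances x (conditions x replicates), all filled
small_experiment <- function(n_sub = 3, conds = c("C1", "C2"), n_rep = 3,
                             kinds = NULL, seed = 1) {
  set.seed(seed)
  subs <- data.frame(name = paste0("S", seq_len(n_sub)),
                     kind = kinds %||% rep("metabolite", n_sub),
                     unit = "u", stringsAsFactors = FALSE)
  samples <- data.frame(condition = rep(conds, each = n_rep), time = 0,
                        time_unit = "d", replicate = rep(seq_len(n_rep),
                                                         length(conds)),
                        stringsAsFactors = FALSE)
  experiment(subs, samples, matrix(rnorm(n_sub * nrow(samples)), n_sub),
             meta = list(name = "fixture"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
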
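path_graph <- function(labels = c("A", "B", "C"), directed = TRUE) {
  g <- og_graph(directed)
  for (l in labels) g <- og_add_node(g, l, list(label = l))
  for (i in seq_len(length(labels) - 1))
    g <- og_add_edge(g, labels[i], labels[i + 1])
  g
}

cycle_graph <- function(n, directed = TRUE) {
  g <- og_graph(directed)
  ids <- paste0("c", seq_len(n))
  for (id in ids) g <- og_add_node(g, id)
  for (i in seq_len(n)) g <- og_add_edge(g, ids[i], ids[i %% n + 1])
  g
}

test_that("shortest paths: path graph, unreachable pairs, weighted mode", {
  g <- path_graph()
  sp <- shortest_paths(g, "A", "C")
  expect_equal(unname(sp$lengths), 2)
  expect_equal(sp$paths[["C"]], c("A", "B", "C"))
  # direction matters: C cannot reach A
  back <- shortest_paths(g, "C", "A")
  expect_equal(unname(back$lengths), Inf)
  expect_equal(back$unreachable, "A")
  # weighted: long direct edge loses to the two-hop route
  g2 <- og_add_edge(g, "A", "C", list(weight = 10))
  ed <- og_edges(g2)
  for (e in ed$id[1:2]) g2 <- og_set_attr(g2, "edge", e, "weight", 1)
  spw <- shortest_paths(g2, "A", "C", weight_attr = "weight")
  expect_equal(unname(spw$lengths), 2)
  expect_error(shortest_paths(g, "zz"), "unknown node")
})

test_that("all-pairs distances equal a Floyd-Warshall oracle on random graphs", {
  set.seed(51)
  for (rep in 1:3) {
    n <- 30
    g <- og_graph()
    ids <- paste0("v", 1:n)
    for (id in ids) g <- og_add_node(g, id)
    for (a in ids) for (b in ids)
      if (a != b && runif(1) < 0.08) g <- og_add_edge(g, a, b)
    # oracle: textbook Floyd-Warshall on the adjacency structure
    D <- matrix(Inf, n, n, dimnames = list(ids, ids)); diag(D) <- 0
    ed <- og_edges(g)
    for (i in seq_len(nrow(ed))) D[ed$source[i], ed$target[i]] <- 1
    for (k in 1:n) for (i in 1:n) {
      nd <- D[i, k] + D[k, ]
      lower <- nd < D[i, ]
      D[i, lower] <- nd[lower]
    }
    for (s in sample(ids, 5)) {
      sp <- shortest_paths(g, s)
      expect_equal(unname(sp$lengths[ids]), unname(D[s, ids]))
    }
  }
})

test_that("cycle enumeration: directed circuits and undirected basis", {
  expect_length(find_cycles(cycle_graph(3))$cycles, 1)
  # DAG: none
  expect_length(find_cycles(path_graph())$cycles, 0)
  # two fused triangles sharing an edge: brute-force count is 3 circuits
  # (each triangle plus the outer 4-cycle through both)
  g <- og_graph()
  for (id in c("a", "b", "c", "d")) g <- og_add_node(g, id)
  for (e in list(c("a", "b"), c("b", "c"), c("c", "a"),
                 c("b", "d"), c("d", "c")))
    g <- og_add_edge(g, e[1], e[2])
  # exhaustive oracle on <= 6 nodes: every simple vertex sequence starting at
  # its lexicographically smallest member counts each circuit exactly once
  perms_of <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x))
      for (p in perms_of(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
    out
  }
  ids <- og_nodes(g)
  has_edge <- function(x, y) any(og_edges(g)$source == x & og_edges(g)$target == y)
  count <- 0
  for (len in 2:4) {
    for (set in utils::combn(ids, len, simplify = FALSE)) {
      for (rest in perms_of(setdiff(set, min(set)))) {
        cyc <- c(min(set), rest)
        ok <- all(vapply(seq_along(cyc), function(i)
          has_edge(cyc[i], cyc[i %% length(cyc) + 1]), logical(1)))
        if (ok) count <- count + 1
      }
    }
  }
  expect_equal(length(find_cycles(g)$cycles), count)
  # undirected cycle basis of the fused triangles: |E| - |V| + components = 2
  gu <- og_graph(FALSE)
  for (id in c("a", "b", "c", "d")) gu <- og_add_node(gu, id)
  for (e in list(c("a", "b"), c("b", "c"), c("c", "a"),
                 c("b", "d"), c("d", "c")))
    gu <- og_add_edge(gu, e[1], e[2])
  expect_length(find_cycles(gu)$cycles, 2)
  # cap triggers the truncation flag (two circuits: c1-c2 and c1-c2-c3)
  big <- cycle_graph(3)
  big <- og_add_edge(big, "c2", "c1")
  capped <- find_cycles(big, cap = 1)
  expect_true(capped$truncated)
  expect_length(capped$cycles, 1)
})

# minimal permutation helper for the oracle above
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in combinat_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
  out
}

test_that("motif search: feed-forward loop semantics", {
  ffl <- og_graph()
  for (id in c("a", "b", "c")) ffl <- og_add_node(ffl, id)
  ffl <- og_add_edge(ffl, "a", "b")
  ffl <- og_add_edge(ffl, "a", "c")
  ffl <- og_add_edge(ffl, "b", "c")
  expect_length(find_motifs(ffl, ffl), 1)
  # 3-cycle contains no FFL: all six orderings lack one required arc
  expect_length(find_motifs(cycle_graph(3), ffl), 0)
  # pattern larger than graph: empty
  expect_length(find_motifs(path_graph(c("x", "y")), ffl), 0)
})

test_that("motif counts equal an exhaustive tuple oracle on random digraphs", {
  set.seed(53)
  pat <- og_graph()   # directed path of length 2: u -> v -> w
  for (id in c("u", "v", "w")) pat <- og_add_node(pat, id)
  pat <- og_add_edge(pat, "u", "v"); pat <- og_add_edge(pat, "v", "w")
  for (rep in 1:3) {
    n <- 12
    g <- og_graph()
    ids <- paste0("v", 1:n)
    for (id in ids) g <- og_add_node(g, id)
    for (a in ids) for (b in ids)
      if (a != b && runif(1) < 0.12) g <- og_add_edge(g, a, b)
    has <- function(x, y) any(og_edges(g)$source == x & og_edges(g)$target == y)
    count <- 0
    for (u in ids) for (v in ids) for (w in ids) {
      if (u == v || v == w || u == w) next
      if (has(u, v) && has(v, w)) count <- count + 1
    }
    # the path pattern has no nontrivial automorphism: every tuple distinct
    expect_equal(length(find_motifs(g, pat)), count)
  }
})

test_that("induced mode forbids extra arcs between matched nodes", {
  pat <- og_graph()
  for (id in c("u", "v")) pat <- og_add_node(pat, id)
  pat <- og_add_edge(pat, "u", "v")
  g <- og_graph()
  for (id in c("a", "b")) g <- og_add_node(g, id)
  g <- og_add_edge(g, "a", "b"); g <- og_add_edge(g, "b", "a")
  expect_length(find_motifs(g, pat, induced = FALSE), 2)
  expect_length(find_motifs(g, pat, induced = TRUE), 0)
})

test_that("class constraints restrict motif matches", {
  pat <- og_graph()
  pat <- og_add_node(pat, "m", list(sbgn_class = "simple_chemical"))
  pat <- og_add_node(pat, "p", list(sbgn_class = "process"))
  pat <- og_add_edge(pat, "m", "p")
  g <- chain_graph(3)   # M1 -> r1 -> M2 -> r2 -> M3
  expect_length(find_motifs(g, pat), 2)        # M1->r1, M2->r2
  expect_length(find_motifs(g, pat, use_classes = FALSE), 4)
})

test_that("centralities match closed forms on canonical graphs", {
  # star S6: center degree 6
  st <- og_graph(FALSE)
  st <- og_add_node(st, "c")
  for (i in 1:6) { st <- og_add_node(st, paste0("l", i))
                   st <- og_add_edge(st, "c", paste0("l", i)) }
  r <- centralities(st, c("degree", "eigenvector"))
  expect_equal(unname(r$values["c", "degree"]), 6)
  expect_equal(unname(r$values["c", "eigenvector"]), 1)  # max-normalized
  # path A-B-C undirected: betweenness(B)=1, endpoints 0
  p <- path_graph(directed = FALSE)
  rb <- centralities(p, "betweenness")
  expect_equal(unname(rb$values[, "betweenness"]), c(0, 1, 0))
  # C5: all eccentricities 2
  c5 <- cycle_graph(5, directed = FALSE)
  re <- centralities(c5, "eccentricity")
  expect_true(all(re$values[, "eccentricity"] == 2))
  # attributes are written
  expect_equal(og_get_attr(rb$graph, "node", "B", "centrality.betweenness"), 1)
})

test_that("betweenness satisfies the dependent-pairs identity on random graphs", {
  set.seed(55)
  for (rep in 1:3) {
    n <- 12
    g <- og_graph(FALSE)
    ids <- paste0("v", 1:n)
    for (id in ids) g <- og_add_node(g, id)
    for (a in seq_len(n - 1)) for (b in (a + 1):n)
      if (runif(1) < 0.25) g <- og_add_edge(g, ids[a], ids[b])
    r <- centralities(g, "betweenness")
    sp <- lapply(ids, function(s) shortest_paths(g, s)$lengths)
    D <- do.call(rbind, sp)
    finite <- is.finite(D) & D >= 1
    # undirected: each unordered pair counted once; interior length d - 1
    expected <- sum(D[finite] - 1) / 2
    expect_equal(sum(r$values[, "betweenness"]), expected, tolerance = 1e-9)
  }
})

test_that("centralities are invariant under graph isomorphism", {
  set.seed(56)
  g <- og_graph()
  ids <- paste0("v", 1:10)
  for (id in ids) g <- og_add_node(g, id)
  for (a in ids) for (b in ids)
    if (a != b && runif(1) < 0.2) g <- og_add_edge(g, a, b)
  measures <- c("degree", "degree_in", "closeness", "betweenness", "katz")
  r1 <- centralities(g, measures)
  # relabel nodes by permutation
  perm <- sample(ids)
  names(perm) <- ids
  g2 <- og_graph()
  for (id in ids) g2 <- og_add_node(g2, perm[[id]])
  ed <- og_edges(g)
  for (i in seq_len(nrow(ed)))
    g2 <- og_add_edge(g2, perm[[ed$source[i]]], perm[[ed$target[i]]])
  r2 <- centralities(g2, measures)
  for (m in measures)
    expect_equal(unname(r2$values[unname(perm[ids]), m]),
                 unname(r1$values[ids, m]), tolerance = 1e-8, info = m)
})

test_that("harmonic closeness handles disconnected graphs", {
  g <- og_graph()
  for (id in c("a", "b", "x")) g <- og_add_node(g, id)
  g <- og_add_edge(g, "a", "b")
  r <- centralities(g, "closeness")
  expect_equal(unname(r$values["a", "closeness"]), 1)  # reaches b at distance 1
  expect_equal(unname(r$values["x", "closeness"]), 0)  # isolated
})
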
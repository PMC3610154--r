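rev_pair_net <- function(marking = c(1, 0)) {
  petri_net(c("A", "B"), c("t1", "t2"),
            pre = matrix(c(1, 0, 0, 1), 2), post = matrix(c(0, 1, 1, 0), 2),
            marking = marking)
}

test_that("graph-to-net translation: arcs, stoichiometry, reversibility", {
  # A -(r1)-> B
  g <- chain_graph(2)
  net <- to_petri_net(g)
  expect_equal(net$places, c("m1", "m2"))
  expect_length(net$transitions, 1)
  expect_equal(unname(net$C[, 1]), c(-1, 1))
  # 2A -> B: pre-arc weight 2, C column (-2, 1)
  g2 <- og_graph()
  g2 <- og_add_node(g2, "A", list(sbgn_class = "simple_chemical"))
  g2 <- og_add_node(g2, "r", list(sbgn_class = "process"))
  g2 <- og_add_node(g2, "B", list(sbgn_class = "simple_chemical"))
  g2 <- og_add_edge(g2, "A", "r", list(weight = 2))
  g2 <- og_add_edge(g2, "r", "B")
  n2 <- to_petri_net(g2)
  expect_equal(unname(n2$pre["A", ]), 2)
  expect_equal(unname(n2$C[, 1]), c(-2, 1))
  # reversible process expands into two opposing transitions
  g3 <- og_set_attr(g2, "node", "r", "reversible", 1)
  n3 <- to_petri_net(g3)
  expect_equal(n3$transitions, c("r__f", "r__b"))
  expect_equal(unname(n3$C[, "r__b"]), -unname(n3$C[, "r__f"]))
  # same-class edge is a structure error
  g4 <- og_add_edge(g2, "A", "B")
  expect_error(to_petri_net(g4), "same class")
})

test_that("firing rule: token flow and disabled transitions", {
  n <- petri_net(c("P1", "P2"), "t", matrix(c(1, 0), 2), matrix(c(0, 1), 2),
                 c(1, 0))
  n2 <- fire(n, "t")
  expect_equal(n2$marking, c(0L, 1L))
  expect_error(fire(n2, "t"), "not enabled")
  expect_equal(enabled_transitions(n), "t")
  expect_length(enabled_transitions(n2), 0)
})

test_that("token sum is conserved along any trace of a conservative net", {
  net <- rev_pair_net(c(3, 2))
  sim <- simulate_petri(net, 25, "random_seeded", seed = 9)
  expect_true(all(rowSums(sim$trace) == 5))
  # seeded runs are reproducible
  sim2 <- simulate_petri(net, 25, "random_seeded", seed = 9)
  expect_identical(sim$trace, sim2$trace)
  expect_identical(sim$fired, sim2$fired)
  # maximal policy also conserves
  simm <- simulate_petri(net, 10, "maximal")
  expect_true(all(rowSums(simm$trace) == 5))
})

test_that("invariants of the reversible pair: (1,1) on both sides", {
  net <- rev_pair_net()
  pi <- invariants(net, "place")
  expect_length(pi, 1)
  expect_equal(unname(pi[[1]]), c(1L, 1L))
  ti <- invariants(net, "transition")
  expect_length(ti, 1)
  expect_equal(unname(ti[[1]]), c(1L, 1L))
})

test_that("invariants satisfy the kernel equations exactly and match brute force", {
  brute <- function(C, side, bound = 3) {
    # exhaustive bounded search for minimal-support gcd-normalized vectors
    n <- if (side == "place") nrow(C) else ncol(C)
    ok <- list()
    grid <- as.matrix(do.call(expand.grid, rep(list(0:bound), n)))
    for (i in seq_len(nrow(grid))) {
      x <- grid[i, ]
      if (all(x == 0)) next
      res <- if (side == "place") as.vector(x %*% C) else as.vector(C %*% x)
      if (all(res == 0)) ok[[length(ok) + 1]] <- x
    }
    # keep minimal-support, gcd-reduced, unique
    gcd1 <- Filter(function(x) {
      g <- Reduce(function(a, b) if (b == 0) a else Recall(b, a %% b),
                  x[x > 0])
      g == 1
    }, ok)
    keep <- Filter(function(x) {
      sx <- x > 0
      !any(vapply(gcd1, function(y) {
        sy <- y > 0
        !identical(unname(sx), unname(sy)) && all(sy <= sx)
      }, logical(1)))
    }, gcd1)
    unique(lapply(keep, unname))
  }
  set.seed(61)
  for (rep in 1:6) {
    pre <- matrix(sample(0:2, 12, TRUE), 3)
    post <- matrix(sample(0:2, 12, TRUE), 3)
    net <- petri_net(paste0("p", 1:3), paste0("t", 1:4), pre, post)
    for (side in c("place", "transition")) {
      inv <- invariants(net, side)
      for (x in inv) {
        res <- if (side == "place") as.vector(x %*% net$C)
               else as.vector(net$C %*% x)
        expect_true(all(res == 0))
        expect_true(all(x >= 0))
      }
      # set equality with the bounded oracle (oracle bound covers these nets)
      bf <- vapply(brute(net$C, side), paste, character(1), collapse = ",")
      small <- Filter(function(x) all(x <= 3), lapply(inv, unname))
      got <- vapply(small, paste, character(1), collapse = ",")
      expect_setequal(got, bf)
    }
  }
})

test_that("reachability: hand-computed BFS and truncation", {
  n <- petri_net(c("P1", "P2"), "t", matrix(c(1, 0), 2), matrix(c(0, 1), 2),
                 c(2, 0))
  rg <- reachability(n)
  expect_equal(nrow(rg$states), 3)
  expect_setequal(apply(rg$states, 1, paste, collapse = ","),
                  c("2,0", "1,1", "0,2"))
  expect_equal(nrow(rg$arcs), 2)
  expect_false(rg$truncated)
  # dead initial marking
  rg0 <- reachability(petri_net(c("P1"), "t", matrix(1), matrix(0), 0))
  expect_equal(nrow(rg0$states), 1)
  expect_equal(nrow(rg0$arcs), 0)
  # unbounded net hits the cap
  src <- petri_net("P", "t", matrix(0), matrix(1), 0)
  rgc <- reachability(src, max_states = 5)
  expect_true(rgc$truncated)
  expect_equal(nrow(rgc$states), 5)
})

test_that("reachability equals brute-force BFS and conserves P-invariants", {
  set.seed(62)
  for (rep in 1:5) {
    np <- sample(2:4, 1); nt <- sample(2:3, 1)
    pre <- matrix(sample(0:1, np * nt, TRUE), np)
    post <- matrix(sample(0:1, np * nt, TRUE), np)
    m0 <- sample(0:2, np, TRUE)
    net <- petri_net(paste0("p", 1:np), paste0("t", 1:nt), pre, post, m0)
    rg <- reachability(net, max_states = 500)
    if (rg$truncated) next
    # independent BFS oracle
    seen <- new.env(parent = emptyenv())
    assign(paste(m0, collapse = ","), TRUE, envir = seen)
    queue <- list(m0)
    while (length(queue)) {
      M <- queue[[1]]; queue <- queue[-1]
      for (j in seq_len(nt)) {
        if (!all(M >= pre[, j])) next
        M2 <- M + post[, j] - pre[, j]
        k <- paste(M2, collapse = ",")
        if (!exists(k, envir = seen, inherits = FALSE)) {
          assign(k, TRUE, envir = seen)
          queue[[length(queue) + 1]] <- M2
        }
      }
    }
    expect_setequal(apply(rg$states, 1, paste, collapse = ","), ls(seen))
    # every arc satisfies the firing rule
    for (i in seq_len(nrow(rg$arcs))) {
      a <- rg$arcs[i, ]
      j <- match(a$transition, net$transitions)
      expect_true(all(rg$states[a$from, ] >= pre[, j]))
      expect_equal(unname(rg$states[a$to, ]),
                   unname(rg$states[a$from, ] + net$C[, j]))
    }
    # weighted token count constant for every P-invariant
    for (x in invariants(net, "place")) {
      tot <- as.vector(rg$states %*% x)
      expect_true(all(tot == tot[1]))
    }
  }
})

test_that("simulation traces stay inside the reachability state set", {
  net <- rev_pair_net(c(2, 1))
  rg <- reachability(net)
  keys <- apply(rg$states, 1, paste, collapse = ",")
  sim <- simulate_petri(net, 30, "random_seeded", seed = 3)
  expect_true(all(apply(sim$trace, 1, paste, collapse = ",") %in% keys))
})

test_that("cycle networks translate to conservative nets (all-ones invariant)", {
  g <- generate_network("cycle", 4)
  net <- to_petri_net(g)
  pi <- invariants(net, "place")
  expect_true(any(vapply(pi, function(x) all(x == 1), logical(1))))
})

test_that("PNML round-trips the basic place/transition subset", {
  net <- petri_net(c("A", "B"), c("t1", "t2"),
                   pre = matrix(c(2, 0, 0, 1), 2), post = matrix(c(0, 1, 2, 0), 2),
                   marking = c(3, 1))
  f <- tempfile(fileext = ".pnml")
  write_pnml(net, f)
  n2 <- read_pnml(f)
  expect_equal(n2$places, net$places)
  expect_equal(n2$transitions, net$transitions)
  expect_equal(n2$pre, net$pre)
  expect_equal(n2$post, net$post)
  expect_equal(n2$marking, net$marking)
  unlink(f)
})

test_that("marking attributes seed the initial marking from the graph", {
  g <- chain_graph(3, marking1 = 2)
  net <- to_petri_net(g)
  expect_equal(unname(net$marking[match("m1", net$places)]), 2L)
  expect_equal(sum(net$marking), 2L)
})
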
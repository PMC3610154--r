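#' Petri nets: construction, token game, invariants, reachability
#'
#' A discrete place/transition net: places hold nonnegative integer token
#' counts (the marking), transitions fire by consuming \code{pre} and
#' producing \code{post} tokens along weighted arcs; the incidence matrix
#' is \eqn{C = post - pre} (places x transitions), so firing transition t
#' yields \eqn{M' = M + C e_t}.
#'
#' @param places,transitions character name vectors.
#' @param pre,post nonnegative integer matrices places x transitions
#'   (arc weights; 0 = no arc).
#' @param marking initial marking (defaults to all zeros — tokens must be
#'   set explicitly, which prevents accidental unbounded runs).
#' @return object of class \code{omic_petri} with fields \code{places},
#'   \code{transitions}, \code{pre}, \code{post}, \code{C}, \code{marking}.
#' @export
petri_net <- function(places, transitions, pre, post,
                      marking = rep(0L, length(places))) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  np <- length(places); nt <- length(transitions)
  stopifnot(nrow(pre) == np, ncol(pre) == nt,
            nrow(post) == np, ncol(post) == nt, length(marking) == np)
  if (any(pre < 0) || any(post < 0) || any(pre != round(pre)) || any(post != round(post)))
    stop2("arc weights must be nonnegative integers")
  if (any(marking < 0) || any(marking != round(marking)))
    stop2("marking must be nonnegative integers")
  storage.mode(pre) <- "integer"; storage.mode(post) <- "integer"
  dimnames(pre) <- dimnames(post) <- list(places, transitions)
  structure(list(places = places, transitions = transitions,
                 pre = pre, post = post, C = post - pre,
                 marking = as.integer(marking)),
            class = "omic_petri")
}

#' @export
print.omic_petri <- function(x, ...) {
  cat(sprintf("<omic_petri: %d places, %d transitions, %d tokens>\n",
              length(x$places), length(x$transitions), sum(x$marking)))
  invisible(x)
}

#' Transform a bipartite metabolic graph into a Petri net
#'
#' Simple-chemical nodes become places, process nodes transitions; edge
#' directions give the arcs, edge \code{weight} attributes (default 1,
#' integral) the arc weights.  A process flagged \code{reversible} expands
#' into two opposing transitions (suffixes \code{__f}/\code{__b}).  The
#' initial marking reads the node attribute \code{"marking"} (default 0).
#' An edge joining two nodes of the same class is a structure error.
#'
#' @param g bipartite metabolic \code{omic_graph}.
#' @export
to_petri_net <- function(g) {
  check_graph(g)
  cls <- vapply(g$nodes, function(n)
    og_get_attr(g, "node", n, "sbgn_class", default = "unspecified"), character(1))
  places <- g$nodes[cls == "simple_chemical"]
  procs <- g$nodes[cls == "process"]
  if (length(setdiff(g$nodes, c(places, procs))))
    stop2("non-bipartite graph: nodes of class other than simple_chemical/process: ",
          paste(utils::head(setdiff(g$nodes, c(places, procs)), 5), collapse = ", "))
  rev_flag <- vapply(procs, function(n)
    isTRUE(og_get_attr(g, "node", n, "reversible", default = 0) != 0), logical(1))
  trans <- unlist(lapply(seq_along(procs), function(i)
    if (rev_flag[i]) paste0(procs[i], c("__f", "__b")) else procs[i]))
  pre <- matrix(0L, length(places), length(trans), dimnames = list(places, trans))
  post <- pre
  tcol <- function(p) if (rev_flag[match(p, procs)]) paste0(p, "__f") else p
  for (i in seq_along(g$edge_id)) {
    s <- g$edge_src[i]; t <- g$edge_dst[i]
    w <- as.numeric(og_get_attr(g, "edge", g$edge_id[i], "weight", default = 1))
    if (w != round(w) || w < 1)
      stop2("edge ", g$edge_id[i], ": weight must be a positive integer")
    if (s %in% places && t %in% procs) {
      pre[s, tcol(t)] <- pre[s, tcol(t)] + w
      if (rev_flag[match(t, procs)])
        post[s, paste0(t, "__b")] <- post[s, paste0(t, "__b")] + w
    } else if (s %in% procs && t %in% places) {
      post[t, tcol(s)] <- post[t, tcol(s)] + w
      if (rev_flag[match(s, procs)])
        pre[t, paste0(s, "__b")] <- pre[t, paste0(s, "__b")] + w
    } else {
      stop2("structure error: edge ", g$edge_id[i], " (", s, " -> ", t,
            ") joins two nodes of the same class")
    }
  }
  marking <- vapply(places, function(p)
    as.integer(og_get_attr(g, "node", p, "marking", default = 0)), integer(1))
  petri_net(places, trans, pre, post, marking)
}

#' Enabled transitions under the current marking
#' @param net Petri net.
#' @export
enabled_transitions <- function(net) {
  net$transitions[vapply(seq_along(net$transitions), function(j)
    all(net$marking >= net$pre[, j]), logical(1))]
}

#' Fire one transition
#'
#' Requires every pre-place to hold at least the arc weight in tokens;
#' firing a disabled transition is an error.
#' @param net Petri net. @param transition transition name.
#' @return the net with updated marking.
#' @export
fire <- function(net, transition) {
  j <- match(transition, net$transitions)
  if (is.na(j)) stop2("unknown transition: ", transition)
  if (!all(net$marking >= net$pre[, j]))
    stop2("transition '", transition, "' is not enabled")
  net$marking <- as.integer(net$marking + net$C[, j])
  net
}

#' Token-game simulation
#'
#' Runs the discrete token game for up to \code{steps} steps.  Policy
#' \code{"random_seeded"} fires one uniformly drawn enabled transition per
#' step (reproducible via \code{seed}); \code{"maximal"} scans transitions
#' in index order and fires every one found enabled during the scan.
#' Stops early on a dead marking.
#'
#' @param net Petri net. @param steps step count.
#' @param policy firing policy. @param seed RNG seed for the random policy.
#' @return list: \code{trace} matrix ((steps+1) x places, row 1 = initial
#'   marking), \code{fired} list of transition names per step,
#'   \code{dead} flag.
#' @export
simulate_petri <- function(net, steps, policy = c("random_seeded", "maximal"),
                           seed = 1) {
  policy <- match.arg(policy)
  trace <- matrix(net$marking, 1, length(net$places),
                  dimnames = list(NULL, net$places))
  fired <- list()
  run <- function() {
    for (s in seq_len(steps)) {
      en <- enabled_transitions(net)
      if (length(en) == 0) return(TRUE)
      if (policy == "random_seeded") {
        t <- en[[sample.int(length(en), 1)]]
        net <<- fire(net, t)
        fired[[s]] <<- t
      } else {
        burst <- character()
        for (t in net$transitions) {
          if (all(net$marking >= net$pre[, match(t, net$transitions)])) {
            net <<- fire(net, t)
            burst <- c(burst, t)
          }
        }
        fired[[s]] <<- burst
      }
      trace <<- rbind(trace, net$marking)
    }
    FALSE
  }
  dead <- if (policy == "random_seeded") with_seed(seed, run()) else run()
  list(trace = trace, fired = fired, dead = dead, net = net)
}

#' P- and T-invariants
#'
#' Minimal-support nonnegative integer invariants computed by the
#' Farkas/Fourier-Motzkin elimination on the incidence matrix, in exact
#' integer arithmetic: place invariants satisfy \eqn{x^T C = 0} (weighted
#' token conservation), transition invariants \eqn{C x = 0} (firing-count
#' vectors that reproduce the marking).  Vectors are gcd-normalized; rows
#' whose support strictly contains another's are discarded.
#'
#' @param net Petri net. @param side \code{"place"} or \code{"transition"}.
#' @return list of invariants, each a named integer vector over places or
#'   transitions.
#' @export
invariants <- function(net, side = c("place", "transition")) {
  side <- match.arg(side)
  A <- if (side == "place") net$C else t(net$C)      # rows to combine
  labels <- if (side == "place") net$places else net$transitions
  D <- cbind(A, diag(nrow(A)))
  ncolA <- ncol(A)
  for (j in seq_len(ncolA)) {
    col <- D[, j, drop = TRUE]
    if (is.null(dim(D))) D <- matrix(D, nrow = 1)
    keep <- D[D[, j] == 0, , drop = FALSE]
    pos <- which(D[, j] > 0); neg <- which(D[, j] < 0)
    combs <- list()
    for (p in pos) for (q in neg) {
      r <- abs(D[q, j]) * D[p, ] + D[p, j] * D[q, ]
      g <- vec_gcd(r)
      combs[[length(combs) + 1L]] <- r / g
    }
    D <- rbind(keep, do.call(rbind, combs))
    if (nrow(D) == 0) break
    D <- unique(D)
    D <- minimal_support_rows(D, ncolA)
  }
  if (is.null(dim(D)) || nrow(D) == 0) return(list())
  inv <- D[, (ncolA + 1):(ncolA + length(labels)), drop = FALSE]
  res <- list()
  for (i in seq_len(nrow(inv))) {
    x <- inv[i, ]
    if (all(x == 0)) next
    x <- x / vec_gcd(x)
    res[[length(res) + 1L]] <- stats::setNames(as.integer(x), labels)
  }
  res
}

# drop rows whose invariant-part support strictly contains another row's
minimal_support_rows <- function(D, ncolA) {
  inv <- D[, -(seq_len(ncolA)), drop = FALSE] != 0
  n <- nrow(D)
  if (n <= 1) return(D)
  drop <- logical(n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (i == k || drop[k]) next
      # drop i when support(k) is a strict subset of support(i)
      if (all(!inv[k, ] | inv[i, ]) && any(inv[i, ] & !inv[k, ])) {
        drop[i] <- TRUE; break
      }
    }
  }
  D[!drop, , drop = FALSE]
}

#' Reachability graph
#'
#' Breadth-first exploration of all markings reachable from the initial
#' one; unbounded nets hit the state cap and return a truncated graph with
#' the \code{truncated} flag set.
#'
#' @param net Petri net. @param max_states state cap (default 1e5).
#' @return list: \code{states} (matrix, one marking per row),
#'   \code{arcs} data frame (from, transition, to; indices into states),
#'   \code{initial} = 1, \code{truncated}.
#' @export
reachability <- function(net, max_states = 1e5) {
  stopifnot(max_states >= 1)
  key <- function(m) paste(m, collapse = ",")
  states <- list(net$marking)
  index <- new.env(parent = emptyenv())
  assign(key(net$marking), 1L, envir = index)
  arcs <- list()
  queue <- 1L
  truncated <- FALSE
  while (length(queue)) {
    si <- queue[1]; queue <- queue[-1]
    M <- states[[si]]
    for (j in seq_along(net$transitions)) {
      if (!all(M >= net$pre[, j])) next
      M2 <- as.integer(M + net$C[, j])
      k2 <- key(M2)
      ti <- if (exists(k2, envir = index, inherits = FALSE))
              get(k2, envir = index) else NULL
      if (is.null(ti)) {
        if (length(states) >= max_states) { truncated <- TRUE; next }
        states[[length(states) + 1L]] <- M2
        ti <- length(states)
        assign(k2, ti, envir = index)
        queue <- c(queue, ti)
      }
      arcs[[length(arcs) + 1L]] <- data.frame(from = si,
                                              transition = net$transitions[j],
                                              to = ti, stringsAsFactors = FALSE)
    }
  }
  smat <- do.call(rbind, states)
  colnames(smat) <- net$places
  list(states = smat,
       arcs = if (length(arcs)) do.call(rbind, arcs)
              else data.frame(from = integer(), transition = character(),
                              to = integer()),
       initial = 1L, truncated = truncated)
}

#' PNML export and import (basic P/T subset)
#'
#' Writes/reads places with initial markings, transitions and weighted arcs
#' in the standard PNML interchange skeleton.
#' @param net Petri net. @param path file path.
#' @export
write_pnml <- function(net, path) {
  doc <- xml2::xml_new_root("pnml")
  nt <- xml2::xml_add_child(doc, "net", id = "net1",
                            type = "http://www.pnml.org/version-2009/grammar/ptnet")
  pg <- xml2::xml_add_child(nt, "page", id = "page1")
  for (i in seq_along(net$places)) {
    p <- xml2::xml_add_child(pg, "place", id = net$places[i])
    if (net$marking[i] > 0) {
      m <- xml2::xml_add_child(p, "initialMarking")
      xml2::xml_add_child(m, "text", as.character(net$marking[i]))
    }
  }
  for (t in net$transitions) xml2::xml_add_child(pg, "transition", id = t)
  aid <- 0L
  for (i in seq_along(net$places)) for (j in seq_along(net$transitions)) {
    for (dir in c("pre", "post")) {
      w <- net[[dir]][i, j]
      if (w == 0) next
      aid <- aid + 1L
      a <- xml2::xml_add_child(pg, "arc", id = paste0("a", aid),
                               source = if (dir == "pre") net$places[i] else net$transitions[j],
                               target = if (dir == "pre") net$transitions[j] else net$places[i])
      if (w != 1) {
        ins <- xml2::xml_add_child(a, "inscription")
        xml2::xml_add_child(ins, "text", as.character(w))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_pnml
#' @export
read_pnml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pl <- xml2::xml_find_all(doc, ".//place")
  tr <- xml2::xml_find_all(doc, ".//transition")
  places <- xml2::xml_attr(pl, "id")
  transitions <- xml2::xml_attr(tr, "id")
  marking <- vapply(pl, function(p) {
    t <- xml2::xml_find_first(p, ".//initialMarking/text")
    if (inherits(t, "xml_missing")) 0L else as.integer(xml2::xml_text(t))
  }, integer(1))
  pre <- matrix(0L, length(places), length(transitions),
                dimnames = list(places, transitions))
  post <- pre
  for (a in xml2::xml_find_all(doc, ".//arc")) {
    s <- xml2::xml_attr(a, "source"); t <- xml2::xml_attr(a, "target")
    wt <- xml2::xml_find_first(a, ".//inscription/text")
    w <- if (inherits(wt, "xml_missing")) 1L else as.integer(xml2::xml_text(wt))
    if (s %in% places) pre[s, t] <- pre[s, t] + w
    else post[t, s] <- post[t, s] + w
  }
  petri_net(places, transitions, pre, post, marking)
}
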
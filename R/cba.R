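#' Stoichiometric model for constraint-based analysis
#'
#' Holds the stoichiometric matrix S (balanced metabolites x reactions),
#' flux bounds and a linear objective: the inputs of flux balance analysis
#' \eqn{\max c^T v} s.t. \eqn{S v = 0}, \eqn{lb \le v \le ub}.
#'
#' @param S numeric matrix metabolites x reactions.
#' @param lb,ub flux bound vectors (elementwise lb <= ub).
#' @param c objective coefficient vector.
#' @param reactions,metabolites name vectors.
#' @export
stoich_model <- function(S, lb, ub, c, reactions = colnames(S),
                         metabolites = rownames(S)) {
  S <- as.matrix(S)
  reactions <- reactions %||% paste0("R", seq_len(ncol(S)))
  metabolites <- metabolites %||% paste0("M", seq_len(nrow(S)))
  if (length(lb) != ncol(S) || length(ub) != ncol(S) || length(c) != ncol(S))
    stop2("lb, ub, c must have one entry per reaction")
  if (any(lb > ub)) stop2("model invariant violated: lb > ub for reaction(s) ",
                          paste(reactions[lb > ub], collapse = ", "))
  dimnames(S) <- list(metabolites, reactions)
  structure(list(S = S, lb = as.numeric(lb), ub = as.numeric(ub),
                 c = as.numeric(c), reactions = reactions,
                 metabolites = metabolites),
            class = "omic_stoich")
}

#' @export
print.omic_stoich <- function(x, ...) {
  cat(sprintf("<omic_stoich: %d metabolites x %d reactions, objective on %s>\n",
              nrow(x$S), ncol(x$S),
              paste(x$reactions[x$c != 0], collapse = "+") %||% "none"))
  invisible(x)
}

#' Build a stoichiometric model from a bipartite metabolic graph
#'
#' Process nodes become reactions, simple-chemical nodes balanced
#' metabolite rows; edge weights are the stoichiometric coefficients
#' (consumed negative, produced positive).  Metabolites flagged with the
#' node attribute \code{"boundary"} are treated as freely exchanged: their
#' balance rows are dropped, which is equivalent to an unconstrained
#' synthesized exchange reaction.  Reversible processes get
#' \code{lb = -default_bound}, irreversible ones 0.
#'
#' @param g bipartite metabolic graph.
#' @param objective label or id of the process to maximize.
#' @param default_bound absolute flux cap (default 1000).
#' @export
from_graph <- function(g, objective, default_bound = 1000) {
  check_graph(g)
  if (missing(objective) || is.null(objective)) stop2("no objective set")
  cls <- vapply(g$nodes, function(n)
    og_get_attr(g, "node", n, "sbgn_class", default = "unspecified"), character(1))
  mets <- g$nodes[cls == "simple_chemical"]
  procs <- g$nodes[cls == "process"]
  if (length(setdiff(g$nodes, c(mets, procs))))
    stop2("non-bipartite metabolic graph")
  boundary <- vapply(mets, function(n)
    isTRUE(og_get_attr(g, "node", n, "boundary", default = 0) != 0), logical(1))
  S <- matrix(0, length(mets), length(procs), dimnames = list(mets, procs))
  for (i in seq_along(g$edge_id)) {
    s <- g$edge_src[i]; t <- g$edge_dst[i]
    w <- as.numeric(og_get_attr(g, "edge", g$edge_id[i], "weight", default = 1))
    if (s %in% mets && t %in% procs) S[s, t] <- S[s, t] - w
    else if (s %in% procs && t %in% mets) S[t, s] <- S[t, s] + w
    else stop2("structure error: edge ", g$edge_id[i], " joins same-class nodes")
  }
  S <- S[!boundary, , drop = FALSE]
  rev_flag <- vapply(procs, function(n)
    isTRUE(og_get_attr(g, "node", n, "reversible", default = 0) != 0), logical(1))
  lb <- ifelse(rev_flag, -default_bound, 0)
  ub <- rep(default_bound, length(procs))
  # per-process bound overrides
  for (j in seq_along(procs)) {
    lo <- og_get_attr(g, "node", procs[j], "flux.lb")
    hi <- og_get_attr(g, "node", procs[j], "flux.ub")
    if (!is.null(lo)) lb[j] <- as.numeric(lo)
    if (!is.null(hi)) ub[j] <- as.numeric(hi)
  }
  labels <- vapply(procs, function(n) og_label(g, n), character(1))
  oj <- which(procs == objective | labels == objective)
  if (length(oj) == 0) stop2("objective reaction not found: ", objective)
  cvec <- rep(0, length(procs)); cvec[oj[1]] <- 1
  stoich_model(S, lb, ub, cvec, reactions = procs,
               metabolites = rownames(S))
}

# LP core: optimize a'v s.t. Sv = 0, lb <= v <= ub (+ optional extra
# >=-constraint), via pracma::linprog on the shifted nonnegative variable
# x = v - lb, with the equalities written as paired inequalities.
solve_lp <- function(m, a, maximize = TRUE, extra_A = NULL, extra_b = NULL) {
  n <- ncol(m$S)
  beq <- -as.vector(m$S %*% m$lb)
  A <- rbind(m$S, -m$S, diag(n))
  b <- c(beq, -beq, m$ub - m$lb)
  if (!is.null(extra_A)) {                 # extra_A v >= extra_b
    A <- rbind(A, -matrix(extra_A, nrow = 1))
    b <- c(b, -(extra_b - sum(extra_A * m$lb)))
  }
  out <- tryCatch(
    suppressWarnings(pracma::linprog(cc = a, A = A, b = b,
                                     maximize = maximize, maxiter = 500,
                                     bigM = 1e5)),
    error = function(e) NULL)
  if (is.null(out) || is.null(out$errno) || out$errno != 1 || anyNA(out$x))
    return(list(v = rep(NA_real_, n), z = NA_real_, status = "infeasible"))
  v <- as.numeric(out$x) + m$lb
  list(v = stats::setNames(v, m$reactions), z = sum(a * v), status = "optimal")
}

#' Flux balance analysis
#'
#' Maximizes the model objective by linear programming.  With degenerate
#' alternate optima the returned vector is one solver-chosen vertex;
#' uniqueness statements belong to \code{\link{fva}}.
#'
#' @param m a \code{\link{stoich_model}}.
#' @return \code{FluxSolution}: list \code{v} (named flux vector), \code{z}
#'   (objective value), \code{status} (optimal / infeasible / unbounded).
#' @export
fba <- function(m) {
  stopifnot(inherits(m, "omic_stoich"))
  sol <- solve_lp(m, m$c)
  if (sol$status == "optimal") sol$z <- sum(m$c * sol$v)
  structure(sol, class = "omic_flux")
}

#' @export
print.omic_flux <- function(x, ...) {
  cat(sprintf("<flux solution: status %s, objective %.6g>\n", x$status,
              x$z %||% NA))
  invisible(x)
}

#' Flux variability analysis
#'
#' For each reaction, minimizes and maximizes its flux subject to the mass
#' balance, the bounds and \eqn{c^T v \ge f \cdot z^*} with \eqn{z^*} the
#' FBA optimum (fraction \code{f}, default 1 = at the optimum).
#'
#' @param m model. @param f optimum fraction in [0, 1].
#' @return data frame (reaction, vmin, vmax).
#' @export
fva <- function(m, f = 1.0) {
  sol <- fba(m)
  if (sol$status != "optimal") stop2("FBA not optimal: ", sol$status)
  zstar <- sol$z
  n <- ncol(m$S)
  res <- data.frame(reaction = m$reactions, vmin = NA_real_, vmax = NA_real_)
  for (j in seq_len(n)) {
    a <- rep(0, n); a[j] <- 1
    lo <- solve_lp(m, a, maximize = FALSE, extra_A = m$c, extra_b = f * zstar)
    hi <- solve_lp(m, a, maximize = TRUE, extra_A = m$c, extra_b = f * zstar)
    res$vmin[j] <- if (lo$status == "optimal") lo$v[j] else NA
    res$vmax[j] <- if (hi$status == "optimal") hi$v[j] else NA
  }
  res
}

#' Knockout analysis
#'
#' Fixes a reaction's flux to zero and re-solves; constraint tightening can
#' only lower the objective.
#' @param m model. @param reaction reaction name.
#' @export
knockout <- function(m, reaction) {
  j <- match(reaction, m$reactions)
  if (is.na(j)) stop2("unknown reaction: ", reaction)
  m$lb[j] <- 0; m$ub[j] <- 0
  fba(m)
}

#' Robustness scan
#'
#' Fixes \code{reaction} at \code{n_steps} evenly spaced values across its
#' FVA range and records the re-optimized objective at each; for LP models
#' the resulting curve is concave.
#'
#' @param m model. @param reaction reaction name. @param n_steps grid size.
#' @return data frame (flux, objective); objective NA where infeasible.
#' @export
robustness <- function(m, reaction, n_steps = 20) {
  j <- match(reaction, m$reactions)
  if (is.na(j)) stop2("unknown reaction: ", reaction)
  rng <- fva(m, f = 0)   # feasible range, not restricted to the optimum
  lo <- rng$vmin[j]; hi <- rng$vmax[j]
  if (!is.finite(lo) || !is.finite(hi)) stop2("no feasible range for ", reaction)
  grid <- seq(lo, hi, length.out = n_steps)
  z <- vapply(grid, function(val) {
    mm <- m; mm$lb[j] <- val; mm$ub[j] <- val
    s <- fba(mm)
    if (s$status == "optimal") s$z else NA_real_
  }, numeric(1))
  data.frame(flux = grid, objective = z)
}
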
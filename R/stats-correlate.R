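#' Correlation of two profiles
#'
#' Pearson's product-moment correlation or Spearman's rank correlation
#' (mid-ranks for ties) on pairwise-complete observations.  The two-sided
#' p-value comes from \eqn{t = r\sqrt{(n-2)/(1-r^2)}} against Student's t
#' with n-2 degrees of freedom; for Spearman with n < 10 an exact
#' permutation p-value is computed instead (full enumeration of rank
#' permutations), since the t approximation is poor at such sizes.
#'
#' @param x,y numeric vectors of equal length; NA pairs are dropped.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return list with \code{r}, \code{p}, \code{n}, \code{method}.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop2("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop2("need at least 3 pairwise-complete observations, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop2("undefined correlation: zero variance")
  if (method == "spearman") { xr <- rank(x); yr <- rank(y) }
  else { xr <- x; yr <- y }
  r <- pm_cor(xr, yr)
  if (method == "spearman" && n < 10) {
    p <- spearman_perm_p(xr, yr, r)
  } else {
    r_c <- max(min(r, 1), -1)
    if (abs(r_c) >= 1) p <- 0
    else {
      t <- r_c * sqrt((n - 2) / (1 - r_c^2))
      p <- 2 * stats::pt(-abs(t), df = n - 2)
    }
  }
  list(r = r, p = p, n = n, method = method)
}

# product-moment formula, written out (the cross-check against cor() lives
# in the test suite)
pm_cor <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# exact permutation p for Spearman at small n: enumerate all n! orderings
spearman_perm_p <- function(xr, yr, r_obs) {
  n <- length(xr)
  perms <- all_permutations(n)
  dx <- xr - mean(xr)
  denom <- sqrt(sum(dx^2)) * sqrt(sum((yr - mean(yr))^2))
  ys <- matrix(yr[perms], nrow = nrow(perms))   # each row: a permutation of yr
  rs <- as.vector((ys - mean(yr)) %*% dx) / denom
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Build the mapped-node profile matrix of a graph
#'
#' Rows are mapped nodes, columns the condition panel (union over nodes,
#' sorted), values per-condition replicate means; the observation axis for
#' all correlation and clustering analyses.
#' @param g graph with mapped data.
#' @export
og_profile_matrix <- function(g) {
  nodes <- og_mapped_nodes(g)
  if (length(nodes) == 0) stop2("graph carries no mapped data")
  profs <- lapply(nodes, function(n) og_node_profile(g, n))
  conds <- sort(unique(unlist(lapply(profs, names))))
  out <- matrix(NA_real_, length(nodes), length(conds),
                dimnames = list(nodes, conds))
  for (i in seq_along(nodes)) out[i, names(profs[[i]])] <- profs[[i]]
  out
}

#' 1:n correlation against a target substance
#'
#' Correlates one target's per-condition profile (e.g. the morphological
#' parameter fresh weight) against the profile of every other mapped node.
#' Each node gains \code{correlation.r/p/n} attributes and a fill color from
#' the diverging red-white-blue scale; nodes sharing fewer than 3 complete
#' observations with the target are skipped with a message.
#'
#' @param g graph with mapped data.
#' @param target substance name (must be mapped).
#' @param method correlation method.
#' @return the annotated graph.
#' @export
correlate_one_to_n <- function(g, target, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  check_graph(g)
  tkey <- path_seg(target)
  tnodes <- og_mapped_nodes(g)
  tnode <- tnodes[vapply(tnodes, function(n) tkey %in% og_mapped_substances(g, n),
                         logical(1))]
  if (length(tnode) == 0) stop2("target substance not mapped: ", target)
  pm <- og_profile_matrix(g)
  tp <- pm[tnode[1], ]
  skipped <- 0L
  for (n in rownames(pm)) {
    res <- tryCatch(correlate(tp, pm[n, ], method), error = function(e) NULL)
    if (is.null(res)) { skipped <- skipped + 1L; next }
    g <- og_set_attr(g, "node", n, "correlation.r", res$r)
    g <- og_set_attr(g, "node", n, "correlation.p", res$p)
    g <- og_set_attr(g, "node", n, "correlation.n", res$n)
    g <- og_set_attr(g, "node", n, "graphics.fill", correlation_color(res$r))
  }
  if (skipped) message(skipped, " node(s) skipped (too few shared observations)")
  g <- og_set_attr(g, "graph", NULL, "correlation.target", target)
  g
}

#' n:n correlation network
#'
#' Tests every unordered pair of mapped nodes and adds a correlation edge
#' when the confidence reaches \code{conf_min} (i.e. p-value
#' \eqn{\le 1 - conf\_min}) \emph{and} \eqn{|r| \ge r\_min} — defaults
#' 0.95 / 0.6, the thresholds of the ecotype-panel workflow.  Edges carry
#' \code{correlation.r/p/n}, an \code{interaction = "correlation"} tag and a
#' color by sign and magnitude (negative red, positive blue).
#'
#' @param g graph with >= 2 mapped nodes.
#' @param method correlation method.
#' @param conf_min minimal confidence (1 - p-value).
#' @param r_min minimal absolute correlation coefficient.
#' @param adjust p-value adjustment across the pair family before
#'   thresholding: \code{"none"} (default, raw thresholds) or \code{"BH"}.
#' @return list with \code{graph} and \code{result}, a
#'   \code{CorrelationResult}: data frame \code{pairs} of all tested pairs
#'   (i, j, r, p, n) plus \code{edges}, the thresholded subset.
#' @export
correlate_n_to_n <- function(g, method = c("pearson", "spearman"),
                             conf_min = 0.95, r_min = 0.6,
                             adjust = c("none", "BH")) {
  method <- match.arg(method); adjust <- match.arg(adjust)
  pm <- og_profile_matrix(g)
  nodes <- rownames(pm)
  if (length(nodes) < 2) stop2("need at least 2 mapped nodes")
  pairs <- list()
  for (a in seq_along(nodes)) for (b in seq_len(a - 1L)) {
    res <- tryCatch(correlate(pm[a, ], pm[b, ], method), error = function(e) NULL)
    if (is.null(res)) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      i = nodes[b], j = nodes[a], r = res$r, p = res$p, n = res$n,
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(i = character(), j = character(), r = numeric(),
                           p = numeric(), n = numeric())
  p_eff <- if (adjust == "BH") stats::p.adjust(pairs$p, "BH") else pairs$p
  keep <- (1 - p_eff) >= conf_min & abs(pairs$r) >= r_min
  edges <- pairs[keep, , drop = FALSE]
  rownames(edges) <- NULL
  for (k in seq_len(nrow(edges))) {
    g <- og_add_edge(g, edges$i[k], edges$j[k], list(
      interaction = "correlation",
      "correlation.r" = edges$r[k], "correlation.p" = edges$p[k],
      "correlation.n" = edges$n[k],
      "graphics.fill" = correlation_color(edges$r[k])))
  }
  result <- structure(list(pairs = pairs, edges = edges, method = method,
                           conf_min = conf_min, r_min = r_min),
                      class = "omic_correlation_result")
  list(graph = g, result = result)
}

#' @export
print.omic_correlation_result <- function(x, ...) {
  cat(sprintf("<correlation result (%s): %d pairs tested, %d edges at conf>=%g, |r|>=%g>\n",
              x$method, nrow(x$pairs), nrow(x$edges), x$conf_min, x$r_min))
  invisible(x)
}

#' Write a correlation result as CSV (i, j, r, p, n)
#' @param x correlation result. @param path output path.
#' @param what \code{"edges"} (default) or \code{"pairs"}.
#' @export
write_correlation_csv <- function(x, path, what = c("edges", "pairs")) {
  what <- match.arg(what)
  utils::write.csv(x[[what]], path, row.names = FALSE)
  invisible(path)
}
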
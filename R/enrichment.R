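#' Category over-representation analysis
#'
#' Hypergeometric enrichment of a query identifier set against a universe,
#' per category term (e.g. pathway or functional annotation sets):
#' \eqn{p = P(X \ge k)} with population \eqn{N = |universe|}, successes
#' \eqn{K = |term \cap universe|}, draws \eqn{n = |query|}, observed
#' \eqn{k = |term \cap query|} — the one-sided Fisher exact tail of the
#' 2x2 table.  Benjamini-Hochberg adjustment optional.
#'
#' @param query character vector of ids, a subset of \code{universe}.
#' @param universe character vector of all ids under consideration.
#' @param categories named list: term -> character vector of member ids
#'   (intersected with the universe).
#' @param correction \code{"bh"} or \code{"none"}.
#' @return data frame, one row per term: \code{term, k, K, n, N, p, p_adj}.
#' @export
enrichment <- function(query, universe, categories,
                       correction = c("bh", "none")) {
  correction <- match.arg(correction)
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop2("empty universe")
  query <- unique(as.character(query))
  if (!all(query %in% universe))
    stop2("query ids outside the universe: ",
          paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  N <- length(universe); n <- length(query)
  rows <- lapply(names(categories), function(term) {
    members <- intersect(unique(as.character(categories[[term]])), universe)
    K <- length(members)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (correction == "bh") stats::p.adjust(out$p, "BH") else out$p
  out[order(out$p), ]
}
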
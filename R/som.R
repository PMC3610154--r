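#' Train a self-organizing map on profile rows
#'
#' Competitive-learning quantization of mapped profiles: prototype vectors
#' on a small grid (a 1 x k chain by default, matching a target cluster
#' count; 2-D grids via \code{grid}) are moved toward samples with a
#' Gaussian neighborhood and exponentially decaying learning rate and
#' radius.  Training is fully deterministic given \code{seed}: prototypes
#' are initialized from seeded draws of the data rows and each epoch visits
#' the rows in a seeded shuffle.  Rows are z-scored (per row) by default
#' since metabolite, enzyme and morphological units differ; missing cells
#' are mean-imputed per row and flagged.
#'
#' @param profiles numeric matrix, rows = substances/nodes, columns =
#'   observation axis (e.g. ecotypes).
#' @param k target cluster count (units of a 1 x k grid); ignored when
#'   \code{grid} is given.
#' @param epochs training epochs.
#' @param seed RNG seed controlling initialization and shuffles.
#' @param grid integer c(rows, cols) unit grid.
#' @param rate0 initial learning rate.
#' @param radius0 initial neighborhood radius (grid units); default half the
#'   larger grid dimension.
#' @param normalize z-score rows before training.
#' @return an \code{omic_som} model: \code{units} (k x dim prototype
#'   matrix), \code{grid}, \code{loss} (mean best-matching distance per
#'   epoch), \code{normalize}, \code{imputed} (logical row flags).
#' @export
train_som <- function(profiles, k, epochs = 100, seed = 1, grid = c(1, k),
                      rate0 = 0.5, radius0 = max(grid) / 2, normalize = TRUE) {
  X <- as.matrix(profiles)
  if (k < 1) stop2("k must be >= 1")
  nunit <- prod(grid)
  if (nunit > nrow(X))
    warn2("more units (", nunit, ") than rows (", nrow(X), "); empty clusters allowed")
  imputed <- apply(X, 1, anyNA)
  for (i in which(imputed)) {
    m <- mean(X[i, ], na.rm = TRUE)
    X[i, is.na(X[i, ])] <- if (is.finite(m)) m else 0
  }
  if (normalize) X <- t(apply(X, 1, zscore_row))
  # unit coordinates on the grid (row-major)
  coords <- cbind(rep(seq_len(grid[1]), each = grid[2]),
                  rep(seq_len(grid[2]), times = grid[1]))
  with_seed(seed, {
    init <- sample(nrow(X), nunit, replace = nunit > nrow(X))
    W <- X[init, , drop = FALSE]
    loss <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      decay <- exp(-3 * (ep - 1) / max(1, epochs - 1))
      alpha <- rate0 * decay
      sigma <- max(radius0 * decay, 1e-3)
      for (i in sample(nrow(X))) {
        x <- X[i, ]
        d2 <- rowSums((W - matrix(x, nunit, ncol(X), byrow = TRUE))^2)
        bmu <- which.min(d2)
        gd2 <- (coords[, 1] - coords[bmu, 1])^2 + (coords[, 2] - coords[bmu, 2])^2
        h <- exp(-gd2 / (2 * sigma^2))
        W <- W + alpha * h * (matrix(x, nunit, ncol(X), byrow = TRUE) - W)
      }
      d <- as.matrix(stats::dist(rbind(W, X)))[seq_len(nunit), -seq_len(nunit),
                                               drop = FALSE]
      loss[ep] <- mean(apply(d, 2, min))
    }
    structure(list(units = W, grid = grid, coords = coords, loss = loss,
                   epochs = epochs, seed = seed, rate0 = rate0,
                   radius0 = radius0, normalize = normalize,
                   imputed = imputed, trained = TRUE),
              class = "omic_som")
  })
}

zscore_row <- function(r) {
  s <- stats::sd(r)
  if (!is.finite(s) || s == 0) r - mean(r) else (r - mean(r)) / s
}

#' @export
print.omic_som <- function(x, ...) {
  cat(sprintf("<omic_som: %dx%d grid, dim %d, %d epochs, final loss %.4g>\n",
              x$grid[1], x$grid[2], ncol(x$units), x$epochs,
              x$loss[length(x$loss)]))
  invisible(x)
}

#' Assign cluster (best-matching unit) memberships
#'
#' Each profile row is assigned the unit with the smallest Euclidean
#' distance; ties break toward the lowest unit index.  With a graph,
#' row names are taken as node ids and each mapped node gains the
#' \code{"cluster"} attribute; unmapped rows/nodes are skipped with a
#' message.  Assignment is independent of row order.
#'
#' @param model trained \code{omic_som}.
#' @param profiles matrix with the same column dimension used in training.
#' @param g optional graph to annotate (rownames of \code{profiles} = node ids).
#' @return integer vector of unit indices (named by rownames), or the
#'   annotated graph when \code{g} is given.
#' @export
assign_clusters <- function(model, profiles, g = NULL) {
  stopifnot(inherits(model, "omic_som"), isTRUE(model$trained))
  X <- as.matrix(profiles)
  for (i in seq_len(nrow(X))) {
    if (anyNA(X[i, ])) {
      m <- mean(X[i, ], na.rm = TRUE)
      X[i, is.na(X[i, ])] <- if (is.finite(m)) m else 0
    }
  }
  if (model$normalize) X <- t(apply(X, 1, zscore_row))
  W <- model$units
  cl <- vapply(seq_len(nrow(X)), function(i) {
    d2 <- rowSums((W - matrix(X[i, ], nrow(W), ncol(W), byrow = TRUE))^2)
    which(d2 <= min(d2) + 1e-12)[1]   # tie -> lowest unit index
  }, integer(1))
  names(cl) <- rownames(X)
  if (is.null(g)) return(cl)
  check_graph(g)
  skipped <- 0L
  for (i in seq_len(nrow(X))) {
    n <- rownames(X)[i]
    if (is.null(n) || !(n %in% g$nodes)) { skipped <- skipped + 1L; next }
    g <- og_set_attr(g, "node", n, "cluster", cl[[i]])
  }
  if (skipped) message(skipped, " row(s) without a matching node skipped")
  g
}
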
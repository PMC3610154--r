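#' Two-sample location tests
#'
#' Unpaired two-sample comparison with a user-set significance threshold:
#' \code{"pooled"} (equal-variance Student t), \code{"welch"}
#' (Welch-Satterthwaite) — both delegated to \code{stats::t.test} — and
#' \code{"mannwhitney"}, the Mann-Whitney U-test implemented here: the exact
#' two-sided p-value by complete enumeration of group labelings when
#' \eqn{n_a + n_b \le 12}, and the tie-corrected normal approximation with
#' continuity correction above.
#'
#' @param a,b numeric samples (NAs dropped).
#' @param variant test variant.
#' @param alpha significance threshold for the reported decision.
#' @return an \code{omic_test} list: \code{statistic}, \code{p}, \code{df}
#'   (NA where undefined), \code{alpha}, \code{significant}, \code{method}.
#' @export
t_test <- function(a, b, variant = c("pooled", "welch", "mannwhitney"),
                   alpha = 0.05) {
  variant <- match.arg(variant)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (variant == "mannwhitney") {
    if (na < 1 || nb < 1 || na + nb < 4)
      stop2("mannwhitney needs >=1 per group and >=4 combined")
    return(mann_whitney(a, b, alpha))
  }
  if (na < 2 || nb < 2) stop2("need at least 2 observations per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(test_result(0, 1, na + nb - 2, alpha, paste0(variant, " t-test")))
    stop2("zero variance in both samples")
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  test_result(unname(ht$statistic), ht$p.value, unname(ht$parameter),
              alpha, paste0(variant, " t-test"))
}

test_result <- function(stat, p, df, alpha, method, extra = list()) {
  structure(c(list(statistic = stat, p = p, df = df, alpha = alpha,
                   significant = is.finite(p) && p <= alpha, method = method),
              extra), class = "omic_test")
}

#' @export
print.omic_test <- function(x, ...) {
  cat(sprintf("<%s: statistic=%.4g, p=%.4g%s -> %s at alpha=%g>\n",
              x$method, x$statistic, x$p,
              if (is.finite(x$df %||% NA)) sprintf(", df=%.3g", x$df) else "",
              if (isTRUE(x$significant)) "significant" else "not significant",
              x$alpha))
  invisible(x)
}

u_statistic <- function(a, b) {
  sum(vapply(a, function(x) sum(x > b) + 0.5 * sum(x == b), numeric(1)))
}

mann_whitney <- function(a, b, alpha) {
  na <- length(a); nb <- length(b); N <- na + nb
  u <- u_statistic(a, b)
  if (N <= 12) {
    pool <- c(a, b)
    sel <- utils::combn(N, na)
    us <- apply(sel, 2, function(idx) u_statistic(pool[idx], pool[-idx]))
    lo <- min(u, na * nb - u); hi <- max(u, na * nb - u)
    p <- mean(us <= lo + 1e-9 | us >= hi - 1e-9)
  } else {
    mu <- na * nb / 2
    ties <- table(c(a, b))
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sig2 <- na * nb / 12 * ((N + 1) - tie_term)
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(p, 1)
  }
  test_result(u, p, NA_real_, alpha, "Mann-Whitney U-test")
}

#' Grubbs outlier test
#'
#' Flags the single most extreme point of a sample when
#' \eqn{G = \max_i |x_i - \bar x| / s} exceeds the critical value
#' \eqn{\frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}} with \eqn{t} the upper
#' \eqn{\alpha/(2n)} Student quantile at \eqn{n-2} degrees of freedom
#' (two-sided version).  A constant sample is degenerate: no outlier.
#'
#' @param x numeric sample, n >= 3. @param alpha significance level.
#' @return \code{omic_test} with extra fields \code{outlier} (index into
#'   \code{x} or NA), \code{critical}, \code{degenerate}.
#' @export
grubbs_test <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  n <- length(x[!is.na(x)])
  if (n < 3) stop2("Grubbs test needs n >= 3")
  x0 <- x[!is.na(x)]
  s <- stats::sd(x0)
  if (s == 0)
    return(test_result(0, NA_real_, NA_real_, alpha, "Grubbs test",
                       list(outlier = NA_integer_, critical = NA_real_,
                            degenerate = TRUE)))
  dev <- abs(x0 - mean(x0))
  G <- max(dev) / s
  t <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  crit <- (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
  flagged <- G > crit
  idx <- if (flagged) which(!is.na(x))[which.max(dev)] else NA_integer_
  res <- test_result(G, NA_real_, n - 2, alpha, "Grubbs test",
                     list(outlier = idx, critical = crit, degenerate = FALSE))
  res$significant <- flagged
  res
}

#' David quicktest for normality
#'
#' The studentized range \eqn{q = (\max x - \min x)/s} is compared against
#' embedded lower/upper critical bounds for the sample size and level; a
#' sample is rejected as non-normal when q falls outside.  Bounds for
#' n = 3..100 at alpha 0.05 and 0.01 are two-sided quantiles of the null
#' distribution of q, precomputed by seeded large-sample simulation and
#' shipped as a plain-text table (see the package vignette).
#'
#' @param x numeric sample, 3 <= n <= 100. @param alpha 0.05 or 0.01.
#' @return \code{omic_test}; \code{decision} is
#'   \code{"consistent-with-normal"} or \code{"rejected"}.
#' @export
david_quicktest <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  n <- length(x)
  tab <- david_table()
  if (!(n %in% tab$n)) stop2("unsupported n for David quicktest: ", n)
  if (!(alpha %in% c(0.05, 0.01))) stop2("alpha must be 0.05 or 0.01")
  s <- stats::sd(x)
  if (s == 0) stop2("degenerate sample: zero standard deviation")
  q <- (max(x) - min(x)) / s
  row <- tab[tab$n == n, ]
  lo <- if (alpha == 0.05) row$lower05 else row$lower01
  hi <- if (alpha == 0.05) row$upper05 else row$upper01
  rejected <- q < lo | q > hi
  res <- test_result(q, NA_real_, NA_real_, alpha, "David quicktest",
                     list(decision = if (rejected) "rejected"
                                     else "consistent-with-normal",
                          bounds = c(lo, hi)))
  res$significant <- rejected
  res
}

david_env <- new.env(parent = emptyenv())
david_table <- function() {
  if (is.null(david_env$tab)) {
    f <- system.file("extdata", "david_quicktest_bounds.csv", package = "omicnet")
    if (!nzchar(f)) f <- file.path("inst", "extdata", "david_quicktest_bounds.csv")
    david_env$tab <- utils::read.csv(f)
  }
  david_env$tab
}
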
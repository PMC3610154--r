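test_that("correlate reproduces hand-derived and closed-form values", {
  expect_equal(correlate(c(1, 2, 3), c(2, 4, 6))$r, 1)
  # hand evaluation of the product-moment definition:
  # cross-deviation sum 4, squared-deviation sums 5 and 5 -> r = 4/5
  r <- correlate(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$r, 0.8)
  expect_equal(r$n, 4)
  # monotone invariance of the rank correlation
  expect_equal(correlate(1:10, (1:10)^3, "spearman")$r, 1)
  expect_error(correlate(c(1, 2), c(1, 2)), "at least 3")
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("correlate agrees with cor.test on random inputs (both methods)", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    a <- correlate(x, y)
    ct <- cor.test(x, y)
    expect_equal(a$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(a$p, ct$p.value, tolerance = 1e-12)
    if (n >= 10) {   # t approximation regime for the rank version
      s <- correlate(x, y, "spearman")
      st <- suppressWarnings(cor.test(x, y, method = "spearman"))
      expect_equal(s$r, unname(st$estimate), tolerance = 1e-12)
    }
  }
  # exact permutation p at small n equals cor.test's exact value (no ties)
  set.seed(32)
  for (i in 1:5) {
    x <- sample(7); y <- sample(7)
    s <- correlate(x, y, "spearman")
    st <- cor.test(x, y, method = "spearman")
    expect_equal(s$p, st$p.value, tolerance = 1e-12)
  }
})

test_that("correlate is symmetric and affine/monotone invariant", {
  set.seed(33)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(correlate(x, y)$r, correlate(y, x)$r)
    expect_equal(correlate(2 + 3 * x, y)$r, correlate(x, y)$r, tolerance = 1e-12)
    expect_equal(correlate(exp(x), y, "spearman")$r,
                 correlate(x, y, "spearman")$r, tolerance = 1e-12)
  }
})

test_that("pairwise-complete handling drops NA pairs", {
  x <- c(1, 2, 3, 4, NA); y <- c(2, NA, 6, 8, 10)
  r <- correlate(x, y)
  expect_equal(r$n, 3)
  expect_equal(r$r, 1)
})

mapped_profile_graph <- function(P) {
  # P: substances x conditions profile matrix -> graph with one node each
  g <- og_graph()
  conds <- colnames(P) %||% paste0("C", seq_len(ncol(P)))
  subs <- rownames(P) %||% paste0("S", seq_len(nrow(P)))
  samples <- data.frame(condition = conds, time = 0, time_unit = "d",
                        replicate = 1L)
  e <- experiment(data.frame(name = subs, kind = "metabolite", unit = "u"),
                  samples, P)
  for (s in subs)
    g <- og_add_node(g, s, list(label = s, sbgn_class = "simple_chemical"))
  map_experiment(g, e, create_missing = FALSE)$graph
}

test_that("1:n correlation annotates nodes and colors the extremes", {
  base <- seq(1, 10)
  P <- rbind(FW = base, up = 2 * base, down = -base + 20,
             flat = c(rep(1, 9), 1.01))
  colnames(P) <- paste0("E", 1:10)
  g <- mapped_profile_graph(P)
  g1 <- correlate_one_to_n(g, "FW")
  expect_equal(og_get_attr(g1, "node", "up", "correlation.r"), 1)
  expect_equal(og_get_attr(g1, "node", "up", "graphics.fill"), "#0000FF")
  expect_equal(og_get_attr(g1, "node", "down", "correlation.r"), -1)
  expect_equal(og_get_attr(g1, "node", "down", "graphics.fill"), "#FF0000")
  expect_error(correlate_one_to_n(g, "NotThere"), "not mapped")
})

test_that("1:n skips nodes with too few shared observations", {
  P <- rbind(FW = c(1, 2, 3, 4), ok = c(2, 3, 4, 6), sparse = c(1, NA, NA, NA))
  colnames(P) <- paste0("E", 1:4)
  g <- mapped_profile_graph(P)
  expect_message(g1 <- correlate_one_to_n(g, "FW"), "skipped")
  expect_null(og_get_attr(g1, "node", "sparse", "correlation.r"))
  expect_false(is.null(og_get_attr(g1, "node", "ok", "correlation.r")))
})

test_that("n:n correlation equals a brute-force all-pairs oracle", {
  set.seed(35)
  n_sub <- 20; n_cond <- 15
  P <- matrix(rnorm(n_sub * n_cond), n_sub,
              dimnames = list(paste0("S", 1:n_sub), paste0("C", 1:n_cond)))
  P[1:10, ] <- P[1:10, ] + 2 * matrix(rep(rnorm(n_cond), each = 10), 10)
  g <- mapped_profile_graph(P)
  res <- correlate_n_to_n(g, conf_min = 0.95, r_min = 0.6)
  # oracle: independent double loop over all pairs via cor.test
  oracle <- character()
  for (a in 1:(n_sub - 1)) for (b in (a + 1):n_sub) {
    ct <- cor.test(P[a, ], P[b, ])
    if ((1 - ct$p.value) >= 0.95 && abs(ct$estimate) >= 0.6)
      oracle <- c(oracle, paste(sort(c(rownames(P)[a], rownames(P)[b])),
                                collapse = "~"))
  }
  got <- vapply(seq_len(nrow(res$result$edges)), function(k)
    paste(sort(c(res$result$edges$i[k], res$result$edges$j[k])), collapse = "~"),
    character(1))
  expect_setequal(got, oracle)
  expect_equal(nrow(res$result$pairs), choose(n_sub, 2))
})

test_that("n:n thresholds behave at the boundaries", {
  set.seed(36)
  P <- matrix(rnorm(5 * 10), 5, dimnames = list(paste0("S", 1:5), paste0("C", 1:10)))
  g <- mapped_profile_graph(P)
  none <- correlate_n_to_n(g, r_min = 1.01)    # unattainable threshold
  expect_equal(nrow(none$result$edges), 0)
  expect_equal(og_edge_count(none$graph), og_edge_count(g))
  # blocks of exact affine copies with orthogonal across-block profiles:
  # exactly 2 * C(3,2) = 6 edges (verified by the brute-force loop above)
  b1 <- rnorm(12); b2 <- rnorm(12)
  b1 <- b1 - mean(b1); b2 <- b2 - mean(b2)
  b2 <- b2 - b1 * sum(b1 * b2) / sum(b1^2)       # centered + orthogonal
  Q <- rbind(a1 = b1, a2 = 2 * b1 + 1, a3 = -b1,
             c1 = b2, c2 = 3 * b2, c3 = 0.5 * b2 - 2)
  colnames(Q) <- paste0("C", 1:12)
  g2 <- mapped_profile_graph(Q)
  res2 <- correlate_n_to_n(g2)
  expect_equal(nrow(res2$result$edges), 6)
})

test_that("t tests: identical samples, exact Mann-Whitney, welch=pooled identity", {
  r <- t_test(c(1, 2, 3), c(1, 2, 3), "pooled")
  expect_equal(r$statistic, 0); expect_equal(r$p, 1)
  # exhaustive enumeration over C(4,2)=6 labelings gives p = 2/6
  mw <- t_test(c(1, 2), c(3, 4), "mannwhitney")
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p, 1 / 3)
  set.seed(37)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6)
    pooled <- t_test(a, b, "pooled"); welch <- t_test(a, b, "welch")
    # equal sizes: identical t statistic; p differs only through df
    expect_equal(pooled$statistic, welch$statistic, tolerance = 1e-12)
  }
  expect_error(t_test(c(1), c(2), "pooled"), "at least 2")
})

test_that("Mann-Whitney exact p equals full permutation enumeration (with ties)", {
  enum_p <- function(a, b) {   # independent enumeration oracle
    pool <- c(a, b); na <- length(a)
    U <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    us <- apply(utils::combn(length(pool), na), 2,
                function(idx) U(pool[idx], pool[-idx]))
    u <- U(a, b)
    lo <- min(u, na * length(b) - u); hi <- max(u, na * length(b) - u)
    mean(us <= lo + 1e-9 | us >= hi - 1e-9)
  }
  set.seed(38)
  for (i in 1:10) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- sample(1:6, na, replace = TRUE)   # ties likely
    b <- sample(1:6, nb, replace = TRUE)
    expect_equal(t_test(a, b, "mannwhitney")$p, enum_p(a, b),
                 info = paste("case", i))
  }
  # tie-free case agrees with wilcox.test's exact p
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(5)
    expect_equal(t_test(a, b, "mannwhitney")$p,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("pooled t-test type-I error is calibrated at alpha", {
  set.seed(39)
  alpha <- 0.05; reps <- 2000
  rej <- mean(replicate(reps, t_test(rnorm(5), rnorm(5), "pooled",
                                     alpha)$significant))
  se <- sqrt(alpha * (1 - alpha) / reps)
  expect_lt(abs(rej - alpha), 3 * se + 1e-9)
})

test_that("Grubbs test flags the extreme point against the closed-form bound", {
  g <- grubbs_test(c(1, 1, 1, 10), alpha = 0.05)
  expect_equal(g$statistic, 1.5)
  # oracle: the t-quantile closed form evaluated independently
  tq <- qt(1 - 0.05 / 8, df = 2)
  expect_equal(g$critical, (3 / 2) * sqrt(tq^2 / (2 + tq^2)), tolerance = 1e-12)
  expect_equal(g$outlier, 4L)
  expect_true(g$significant)
  g2 <- grubbs_test(c(-1, 0, 1), alpha = 0.05)
  expect_false(g2$significant)
  expect_true(is.na(g2$outlier))
  g3 <- grubbs_test(c(2, 2, 2))
  expect_true(g3$degenerate)
  expect_error(grubbs_test(c(1, 2)), "n >= 3")
})

test_that("David quicktest: calibration, extreme spread, degenerate input", {
  set.seed(40)
  reps <- 1000
  rej <- mean(replicate(reps, david_quicktest(rnorm(10))$significant))
  expect_lt(abs(rej - 0.05), 0.025)   # ~3 binomial SE at n=1000
  # two close points plus an extreme third: range/sd hits its lower bound
  expect_equal(david_quicktest(c(0, 0, 1))$decision, "rejected")
  expect_error(david_quicktest(c(3, 3, 3)), "zero standard deviation")
  expect_error(david_quicktest(rnorm(150)), "unsupported n")
  expect_error(david_quicktest(rnorm(10), alpha = 0.10), "alpha")
})

test_that("enrichment equals the hypergeometric tail and Fisher's exact test", {
  # direct tail summation: N=20, K=5, n=5, k=4 -> 76/15504
  r <- enrichment(paste0("g", 1:5), paste0("g", 1:20),
                  list(T1 = paste0("g", c(1:4, 10))), correction = "none")
  expect_equal(r$p, 76 / 15504, tolerance = 1e-12)
  # k = 0 and query = universe boundaries
  r0 <- enrichment(paste0("g", 6:8), paste0("g", 1:20),
                   list(T1 = paste0("g", 1:2)), correction = "none")
  expect_equal(r0$p, 1)
  rU <- enrichment(paste0("g", 1:20), paste0("g", 1:20),
                   list(T1 = paste0("g", 1:7)), correction = "none")
  expect_equal(rU$k, rU$K); expect_equal(rU$p, 1)
  # random sweep against one-sided Fisher
  set.seed(41)
  for (i in 1:25) {
    N <- sample(10:60, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    uni <- paste0("x", 1:N)
    term <- sample(uni, K); query <- sample(uni, n)
    k <- length(intersect(term, query))
    p <- enrichment(query, uni, list(t = term), correction = "none")$p
    ft <- fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2),
                      alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-12)
  }
  expect_error(enrichment("a", character(), list(t = "a")), "empty universe")
  expect_error(enrichment("zz", "a", list(t = "a")), "outside the universe")
  # BH adjustment is monotone and bounded
  rb <- enrichment(paste0("g", 1:5), paste0("g", 1:20),
                   list(A = paste0("g", 1:5), B = paste0("g", 6:10),
                        C = paste0("g", c(1, 6, 11, 16))), correction = "bh")
  expect_true(all(rb$p_adj >= rb$p - 1e-15 & rb$p_adj <= 1))
})
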
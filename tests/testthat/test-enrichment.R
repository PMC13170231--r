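# ssGSEA scoring, over-representation tests, immune scores, group statistics.

test_that("singleton-set alpha = 0 score equals the hand-walked running sum", {
  e <- matrix(4:1, 1, 4, dimnames = list("u", paste0("g", 1:4)))
  es <- ssgseaScore(e, list(s = "g1"), alpha = 0)
  # walk: (1-0) + (1-1/3) + (1-2/3) + (1-1)
  expect_equal(unname(es[1, 1]), (1 - 0) + (1 - 1/3) + (1 - 2/3) + (1 - 1))
  expect_equal(unname(es[1, 1]),
               bruteSingletonES(e[1, ], colnames(e), "g1"))
  # bottom-ranked singleton is maximally depleted
  es2 <- ssgseaScore(e, list(s = "g4"), alpha = 0)
  expect_equal(unname(es2[1, 1]), bruteSingletonES(e[1, ], colnames(e), "g4"))
  expect_lt(es2[1, 1], 0)
})

test_that("singleton closed form matches the oracle on random instances", {
  set.seed(19)
  for (i in 1:20) {
    N <- sample(5:30, 1)
    vals <- rnorm(N)
    genes <- paste0("g", seq_len(N))
    e <- matrix(vals, 1, N, dimnames = list("u", genes))
    pick <- sample(genes, 1)
    expect_equal(unname(ssgseaScore(e, list(s = pick), alpha = 0)[1, 1]),
                 bruteSingletonES(vals, genes, pick), tolerance = 1e-12)
  }
})

test_that("scores are invariant under strictly increasing transforms", {
  set.seed(29)
  for (i in 1:20) {
    e <- matrix(rnorm(8 * 40), 8, 40,
                dimnames = list(paste0("u", 1:8), paste0("g", 1:40)))
    sets <- list(a = paste0("g", 1:7), b = paste0("g", c(5, 20, 33)))
    s1 <- ssgseaScore(e, sets)
    s2 <- ssgseaScore(exp(e * 2) + 3, sets)
    expect_equal(s1, s2, tolerance = 1e-12)
  }
})

test_that("degenerate sets score NA with a warning; normalization rescales", {
  e <- matrix(rnorm(12), 3, 4,
              dimnames = list(NULL, paste0("g", 1:4)))
  expect_warning(s <- ssgseaScore(e, list(all = paste0("g", 1:4))), "all genes")
  expect_true(all(is.na(s)))
  expect_warning(s2 <- ssgseaScore(e, list(none = "zz")), "no gene")
  sets <- list(a = c("g1", "g2"))
  sN <- ssgseaScore(e, sets, normalize = TRUE)
  sR <- ssgseaScore(e, sets)
  expect_equal(sN, sR / diff(range(sR)), tolerance = 1e-12)
})

test_that("the gsva backend is also rank-based per unit and finite", {
  set.seed(39)
  e <- matrix(rnorm(6 * 30), 6, 30,
              dimnames = list(paste0("u", 1:6), paste0("g", 1:30)))
  s <- ssgseaScore(e, list(a = paste0("g", 1:5)), method = "gsva")
  expect_true(all(is.finite(s)))
})

test_that("hypergeometric tail: exact toy value and exhaustive enumeration", {
  r <- hypergeomOverlap(paste0("g", 1:5), paste0("g", 1:5), paste0("g", 1:10))
  expect_equal(r$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_identical(c(r$k, r$n, r$K, r$N), c(5L, 5L, 5L, 10L))
  r0 <- hypergeomOverlap(paste0("g", 11:14), paste0("g", 7:9), paste0("g", 1:20))
  expect_equal(r0$p, 1)   # zero overlap: P(X >= 0) = 1
  set.seed(49)
  for (i in 1:10) {
    N <- sample(6:12, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    uni <- paste0("g", seq_len(N))
    marker <- uni[seq_len(K)]
    lst <- sample(uni, n)
    k <- length(intersect(lst, marker))
    expect_equal(hypergeomOverlap(lst, marker, uni)$p,
                 bruteHyperTail(N, K, n, k), tolerance = 1e-12)
  }
  expect_error(hypergeomOverlap("a", "b", character(0)), "universe")
})

test_that("overlapTest adds BH q across sets", {
  uni <- paste0("g", 1:30)
  res <- overlapTest(uni[1:8], list(a = uni[1:6], b = uni[25:30]), uni)
  expect_equal(res$q, bhFDR(res$p))
  expect_identical(res$k, c(6L, 0L))
})

test_that("immune scores: identical samples tie, coverage is logged", {
  set.seed(59)
  cnt <- matrix(rnbinom(200 * 6, mu = 50, size = 5), 200, 6,
                dimnames = list(sprintf("B%04d", 1:200), paste0("s", 1:6)))
  cnt[, 2] <- cnt[, 1]
  sigs <- list(x = sprintf("B%04d", 1:12), y = c(sprintf("B%04d", 50:60), "MISSING"))
  sc <- immuneScores(cnt, sigs)
  expect_equal(sc[1, ], sc[2, ], tolerance = 1e-12)
  expect_equal(unname(attr(sc, "coverage")["y"]), 11 / 12)
})

test_that("group comparison gates on normality and flips sign under relabelling", {
  set.seed(69)
  sc <- cbind(normal = c(rnorm(15, 2), rnorm(15)),
              skewed = c(rexp(15), rexp(15) + 2),
              flat = rep(1, 30))
  g <- rep(c("case", "control"), each = 15)
  res <- scoreGroupCompare(sc, factor(g, levels = c("case", "control")))
  expect_identical(res$test[res$set == "flat"], "degenerate")
  expect_equal(res$p[res$set == "flat"], 1)
  res2 <- scoreGroupCompare(sc, factor(g, levels = c("control", "case")))
  tRow <- res$test == "t"
  expect_equal(res2$statistic[tRow], -res$statistic[tRow], tolerance = 1e-12)
  expect_equal(res2$p, res$p, tolerance = 1e-12)
})

test_that("group comparison holds its nominal size and finds a 2-sd shift", {
  set.seed(79)
  p0 <- replicate(300, {
    sc <- cbind(s = rnorm(24))
    scoreGroupCompare(sc, rep(c("a", "b"), each = 12))$p
  })
  expect_gt(mean(p0 < 0.05), 0.02); expect_lt(mean(p0 < 0.05), 0.09)
  p1 <- replicate(60, {
    sc <- cbind(s = c(rnorm(30, 2), rnorm(30)))
    scoreGroupCompare(sc, rep(c("a", "b"), each = 30))$p
  })
  expect_gt(mean(p1 < 0.05), 0.9)
})

test_that("spearman scores: monotone transform gives rho 1, ties give NA", {
  v <- c(3, 1, 4, 1.5, 5, 9, 2.6)
  sc <- cbind(mono = exp(v), tied = rep(1, 7))
  res <- scoreMapCorrelation(v, sc)
  expect_equal(res$rho[res$set == "mono"], 1)
  expect_true(is.na(res$rho[res$set == "tied"]))
  expect_error(scoreMapCorrelation(v[1:3], sc[1:3, ]), ">= 5")
})

test_that("the normality gate matches the reference omnibus statistic", {
  # frozen from an independent implementation of the same omnibus test
  x <- c(-0.626, 0.184, -0.836, 1.595, 0.33, -0.82, 0.487, 0.738, 0.576,
         -0.305, 1.512, 0.39, -0.621, -2.215, 1.125, -0.045, -0.016, 0.944,
         0.821, 0.594)
  dp <- dagostinoPearson(x)
  expect_equal(dp$statistic, 3.923, tolerance = 1e-3)
  expect_equal(dp$p.value, 0.1406, tolerance = 1e-3)
})
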
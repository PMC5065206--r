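make_score_table <- function(n, shift = c(0, 0, 0), seed = 1,
                             classes = c("A", "B", "C")) {
  set.seed(seed)
  data.frame(
    class = rep(classes, each = n),
    score = rnorm(3 * n) + rep(shift, each = n)
  )
}

test_that("block pairing requires equal class sizes and is seeded", {
  tab <- make_score_table(20)
  b1 <- make_blocks(tab, "score", seed = 3)
  b2 <- make_blocks(tab, "score", seed = 3)
  expect_identical(b1, b2)
  expect_equal(dim(b1), c(20L, 3L))
  expect_setequal(b1[, "A"], tab$score[tab$class == "A"])
  uneq <- tab[-1, ]
  expect_error(make_blocks(uneq, "score"), "blocks undefined")
  expect_error(make_blocks(tab, "nope"), "unknown metric")
})

test_that("Friedman statistic: degenerate, hand-computed, and stats:: oracle", {
  same <- matrix(rep(1:10, 3), 10, 3)
  res <- friedman_rank_test(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  # class 1 always smallest, class 3 always largest: mean ranks 1, 2, 3
  ordered <- cbind(A = 1:10, B = 11:20, C = 21:30)
  res2 <- friedman_rank_test(ordered)
  expect_equal(unname(res2$mean_ranks), c(1, 2, 3))
  expect_equal(res2$statistic, 20)
  expect_equal(res2$p.value, pchisq(20, 2, lower.tail = FALSE))
  # agreement with stats::friedman.test, with and without ties
  set.seed(61)
  y <- matrix(rnorm(60), 20, 3)
  ref <- stats::friedman.test(y)
  got <- friedman_rank_test(y)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  yt <- matrix(sample(1:4, 60, TRUE), 20, 3)  # heavy ties
  reft <- stats::friedman.test(yt)
  gott <- friedman_rank_test(yt)
  expect_equal(gott$statistic, unname(reft$statistic), tolerance = 1e-12)
  expect_equal(gott$p.value, reft$p.value, tolerance = 1e-12)
})

test_that("pairwise z statistics follow the mean-rank formula", {
  pw <- pairwise_raw_pvalues(c(A = 2, B = 2, C = 2), n = 15)
  expect_equal(pw$p, rep(1, 3))
  pw2 <- pairwise_raw_pvalues(c(A = 1, B = 2, C = 3), n = 10)
  adj <- pw2[pw2$a == "A" & pw2$b == "B", ]
  expect_equal(abs(adj$z), sqrt(5), tolerance = 1e-12)
  expect_equal(pw2$p[1], 2 * pnorm(-sqrt(5)), tolerance = 1e-12)
  # symmetric swap gives identical |z|
  pw3 <- pairwise_raw_pvalues(c(A = 3, B = 2, C = 1), n = 10)
  expect_equal(abs(pw3$z), abs(pw2$z))
})

test_that("Holm adjustment: hand example, single p, capping", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.5, 0.5, 0.5)), c(1, 1, 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "p-values")
})

test_that("Shaffer adjustment uses the logically constrained multipliers", {
  expect_equal(shaffer_adjust(c(0.01, 0.02, 0.03), 3), c(0.03, 0.03, 0.03))
  expect_equal(shaffer_adjust(c(0.5, 0.6, 0.7), 3), c(1, 1, 1))
  expect_error(shaffer_adjust(c(0.1, 0.2), 3), "expected 3 p-values")
  set.seed(62)
  for (i in 1:50) {
    p <- runif(3)
    sh <- shaffer_adjust(p, 3); ho <- holm_adjust(p)
    expect_true(all(sh <= ho + 1e-15))
    expect_true(all(sh >= p - 1e-15))
  }
})

test_that("Bergmann-Hommel: coincides with Shaffer at k = 3, dominated at k = 4", {
  set.seed(63)
  for (i in 1:50) {
    p <- runif(3)
    expect_equal(bergmann_adjust(p, 3), shaffer_adjust(p, 3), tolerance = 1e-12)
  }
  for (i in 1:25) {
    p <- runif(6)
    bg <- bergmann_adjust(p, 4)
    sh <- shaffer_adjust(p, 4)
    ho <- holm_adjust(p)
    expect_true(all(bg <= sh + 1e-15))
    expect_true(all(sh <= ho + 1e-15))
    expect_true(all(bg >= p - 1e-15))
    expect_true(all(bg <= 1))
  }
  # symmetric inputs get symmetric adjustments
  expect_equal(length(unique(bergmann_adjust(rep(0.04, 3), 3))), 1L)
  expect_error(bergmann_adjust(runif(15), 6), "exhaustive enumeration refused")
})

test_that("significance_table flags the shifted class and only that class", {
  tab <- make_score_table(60, shift = c(0, 0, 3), seed = 64)
  rep <- significance_table(tab, metrics = "score", alpha = 0.05, seed = 1)
  pw <- rep$metrics$score$pairwise
  expect_lt(rep$metrics$score$p.value, 0.05)
  flagged <- pw[pw$sig_holm, c("a", "b")]
  expect_equal(nrow(flagged), 2L)
  expect_true(all(apply(flagged, 1, function(r) "C" %in% r)))
  expect_false(pw$sig_holm[pw$a == "A" & pw$b == "B"])
})

test_that("a tiny alpha flags nothing and the printout says Nil", {
  tab <- make_score_table(30, shift = c(0, 0, 2), seed = 65)
  rep <- significance_table(tab, metrics = "score", alpha = 1e-12, seed = 1)
  pw <- rep$metrics$score$pairwise
  expect_false(any(pw$sig_holm | pw$sig_shaffer | pw$sig_bergmann))
  expect_true(any(grepl("Nil", capture.output(print(rep)))))
  expect_error(significance_table(tab, alpha = 0), "alpha")
  expect_error(significance_table(data.frame(x = 1)), "class")
})

test_that("adjusted p-values dominate raw ones in the full report", {
  tab <- make_score_table(40, shift = c(0, 1, 2), seed = 66)
  rep <- significance_table(tab, metrics = "score", seed = 2)
  pw <- rep$metrics$score$pairwise
  expect_true(all(pw$holm >= pw$p - 1e-15))
  expect_true(all(pw$bergmann <= pw$shaffer + 1e-15))
  expect_true(all(pw$shaffer <= pw$holm + 1e-15))
})

test_that("the Kruskal-Wallis escape hatch works on unequal classes", {
  tab <- make_score_table(30, shift = c(0, 0, 3), seed = 67)
  tab <- tab[-1, ]  # unequal sizes: Friedman path must refuse
  expect_error(significance_table(tab, metrics = "score", test = "friedman"),
               "blocks undefined")
  rep <- significance_table(tab, metrics = "score", test = "kruskal")
  expect_lt(rep$metrics$score$p.value, 0.05)
  expect_equal(nrow(rep$metrics$score$pairwise), 3L)
})
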
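test_that("moving average: constants, impulse, and the window oracle", {
  expect_equal(smooth_profile(rep(5, 5), 3), rep(5, 5))
  expect_equal(smooth_profile(c(0, 0, 1, 0, 0, 0), 3),
               c(0, 1/3, 1/3, 1/3, 0, 0))
  set.seed(31)
  prof <- runif(47, 30, 60)
  for (span in c(3, 5, 7, 9)) {
    expect_equal(smooth_profile(prof, span, "wrap"),
                 oracle_smooth(prof, span, "wrap"), tolerance = 1e-12)
    expect_equal(smooth_profile(prof, span, "shrink"),
                 oracle_smooth(prof, span, "shrink"), tolerance = 1e-12)
  }
  expect_error(smooth_profile(prof, 4), "odd")
  expect_error(smooth_profile(prof, 47), "shorter than the profile")
})

test_that("absolute difference is elementwise and checks lengths", {
  expect_equal(absolute_difference(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(absolute_difference(c(3, 5), c(5, 3)), c(2, 2))
  set.seed(32)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(absolute_difference(a, b), abs(a - b))
  expect_error(absolute_difference(1:3, 1:4), "length mismatch")
})

test_that("normalized ratios handle the perfectly smooth degenerate case", {
  nr <- normalized_ratios(c(1, 1, 1, 1))
  expect_equal(nr$mu_pd, 1)
  expect_equal(nr$rat, c(1, 1, 1, 1))
  z <- normalized_ratios(c(0, 0, 0))
  expect_equal(z$mu_pd, 0)
  expect_equal(z$rat, c(0, 0, 0))
  nr2 <- normalized_ratios(c(0, 2))
  expect_equal(nr2$mu_pd, 1)
  expect_equal(nr2$rat, c(0, 2))
  expect_error(normalized_ratios(c(-1, 1)), "nonnegative")
  expect_error(normalized_ratios(numeric(0)), "empty")
})

test_that("partition fractions use half-open bins and sum to 1", {
  expect_equal(partition_fractions(rep(0, 6)), c(1, 0, 0, 0))
  expect_equal(partition_fractions(c(0.05, 0.15, 0.25, 0.35)),
               c(0.25, 0.25, 0.25, 0.25))
  # cut points belong to the upper bin
  expect_equal(partition_fractions(c(0.1, 0.2, 0.3)), c(0, 1/3, 1/3, 1/3))
  set.seed(33)
  rat <- rexp(200)
  expect_equal(sum(partition_fractions(rat)), 1)
})

test_that("pd_score weights partitions by the penalty table", {
  expect_equal(pd_score(c(1, 0, 0, 0), penalty_config(penalty = "linear")), 1)
  expect_equal(pd_score(c(0, 0, 0, 1), penalty_config(penalty = "cubic")), 64)
  expect_equal(pd_score(rep(0.25, 4), penalty_config(penalty = "quadratic")), 7.5)
  expect_error(pd_score(c(0.5, 0.5, 0.5, 0), penalty_config()), "sum to 1")
  custom <- penalty_config(penalties = c(0, 1, 10, 100))
  expect_equal(pd_score(c(0, 1, 0, 0), custom), 1)
  expect_error(penalty_config(penalties = c(4, 3, 2, 1)), "strictly increasing")
  expect_error(penalty_config(span = 4), "odd")
})

test_that("smooth analytic circle scores the minimum penalty", {
  circ <- circle_contour(r = 50, n = 360)
  for (p in c("linear", "quadratic", "cubic")) for (s in c(3, 9)) {
    res <- penalty_driven_score(circ, penalty_config(span = s, penalty = p))
    expect_lt(res$mu_pd, 1e-10)
    expect_equal(res$pd, res$config$penalties[1])
  }
})

test_that("full chain matches the straight-line oracle on a star contour", {
  star <- star_contour(base = 50, amp = 8, freq = 12)
  cfg <- penalty_config(span = 3, penalty = "linear")
  got <- penalty_driven_score(star, cfg)
  want <- oracle_pd(star, 3, cfg$penalties)
  expect_equal(got$d, want$d, tolerance = 1e-12)
  expect_equal(got$d_s, want$d_s, tolerance = 1e-12)
  expect_equal(got$mu_pd, want$mu_pd, tolerance = 1e-12)
  expect_equal(got$partitions, want$partitions, tolerance = 1e-12)
  expect_equal(got$pd, want$pd, tolerance = 1e-12)
})

test_that("PD is invariant to start-point rotation and uniform scaling", {
  ct <- star_contour(base = 40, amp = 6, freq = 9, n = 500)
  cfg <- penalty_config(span = 5, penalty = "quadratic")
  base <- penalty_driven_score(ct, cfg)
  shifted <- ct[c(101:500, 1:100), ]
  expect_equal(penalty_driven_score(shifted, cfg)$pd, base$pd, tolerance = 1e-12)
  scaled <- ct * 3
  res3 <- penalty_driven_score(scaled, cfg)
  expect_equal(res3$pd, base$pd, tolerance = 1e-12)
  expect_equal(res3$partitions, base$partitions, tolerance = 1e-12)
  expect_equal(res3$mu_pd, 3 * base$mu_pd, tolerance = 1e-12)
})

test_that("PD respects bounds and penalty-function monotonicity", {
  cts <- random_contours(6, seed = 34)
  for (ct in cts) {
    pds <- vapply(c("linear", "quadratic", "cubic"), function(p) {
      cfg <- penalty_config(span = 3, penalty = p)
      res <- penalty_driven_score(ct, cfg)
      expect_gte(res$pd, cfg$penalties[1])
      expect_lte(res$pd, cfg$penalties[4])
      expect_equal(sum(res$partitions), 1, tolerance = 1e-12)
      res$pd
    }, numeric(1))
    p4p1 <- penalty_driven_score(ct, penalty_config())$partitions
    if (p4p1[4] > p4p1[1]) {
      expect_true(pds["cubic"] >= pds["quadratic"] &&
                  pds["quadratic"] >= pds["linear"])
    }
  }
})

test_that("print method reports the score and bin fractions", {
  res <- penalty_driven_score(star_contour())
  out <- capture.output(print(res))
  expect_true(any(grepl("PD score", out)))
  expect_true(any(grepl("bin fractions", out)))
})
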
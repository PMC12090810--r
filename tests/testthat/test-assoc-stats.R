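test_that("exact Mann-Whitney matches brute-force enumeration on the 2v2 case", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3)  # 2 of the 6 assignments are as extreme
  expect_identical(res$method, "exact")
  expect_equal(res$direction, -1)
})

test_that("identical groups give p near 1 and constant data a degenerate warning", {
  res <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gt(res$p_value, 0.9)
  expect_warning(res2 <- mann_whitney_u(rep(2, 5), rep(2, 7)), "degenerate")
  expect_equal(res2$p_value, 1)
})

test_that("asymptotic path reproduces wilcox.test with continuity and tie correction", {
  set.seed(17)
  for (i in 1:50) {
    na <- sample(10:30, 1); nb <- sample(10:30, 1)
    a <- sample(stats::rpois(na, 4))  # ties by construction
    b <- stats::rpois(nb, 5)
    ours <- mann_whitney_u(a, b, method = "asymptotic")
    ref <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("exact path reproduces wilcox.test's exact p on tie-free data", {
  set.seed(19)
  for (i in 1:50) {
    na <- sample(2:7, 1); nb <- sample(2:7, 1)
    a <- stats::runif(na); b <- stats::runif(nb)
    ours <- mann_whitney_u(a, b, method = "exact")
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("asymptotic and exact p-values agree closely at small n", {
  set.seed(23)
  for (i in 1:100) {
    na <- sample(3:7, 1); nb <- sample(3:7, 1)  # both ranges length > 1

    a <- stats::rnorm(na); b <- stats::rnorm(nb, sample(c(0, 1), 1))
    pe <- mann_whitney_u(a, b, method = "exact")
    pa <- mann_whitney_u(a, b, method = "asymptotic")
    expect_identical(pe$statistic, pa$statistic)
    expect_lt(abs(pe$p_value - pa$p_value), 0.05)
  }
})

test_that("Pearson correlation handles perfect, reversed and hand-computed cases", {
  x <- c(1, 2, 3, 4, 5)
  res <- pearson_r(x, 2 * x + 1)
  expect_equal(res$statistic, 1, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-10)
  expect_equal(pearson_r(x, -x)$statistic, -1, tolerance = 1e-12)
  # hand oracle: devs (-1.5,-.5,.5,1.5) vs (-.5,-1.5,1.5,.5): R = 3/5;
  # t = 0.6*sqrt(2/0.64), and for df = 2 the two-sided p is exactly 0.4
  res2 <- pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res2$statistic, 0.6, tolerance = 1e-12)
  expect_equal(res2$p_value, 0.4, tolerance = 1e-10)
  expect_error(pearson_r(x, rep(1, 5)), "constant")
  expect_error(pearson_r(1:2, 1:2), "3")
})

test_that("Pearson R is symmetric and equivariant under affine maps", {
  set.seed(29)
  x <- stats::rnorm(20); y <- stats::rnorm(20)
  r_xy <- pearson_r(x, y)$statistic
  expect_equal(pearson_r(y, x)$statistic, r_xy, tolerance = 1e-12)
  expect_equal(pearson_r(3 * x + 2, y)$statistic, r_xy, tolerance = 1e-12)
  expect_equal(pearson_r(-3 * x + 2, y)$statistic, -r_xy, tolerance = 1e-12)
})

test_that("group summaries use midpoint medians and full ranges", {
  gs <- group_summary(c(1, 2, 3, 4, 10), c("a", "a", "a", "a", "b"))
  expect_equal(gs$a$median, 2.5)
  expect_equal(gs$a$min, 1); expect_equal(gs$a$max, 4)
  expect_equal(gs$b$median, 10); expect_equal(gs$b$min, 10)
  expect_error(group_summary(1:3, c("a", "a", "a")), NA)
  expect_error(group_summary(1:3, c("a", "b")), "length")
})
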
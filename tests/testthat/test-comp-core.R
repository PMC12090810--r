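test_that("relative-abundance normalization divides rows by their sums", {
  tab <- make_table(matrix(c(2, 2, 4,
                             1, 0, 0), nrow = 2, byrow = TRUE))
  rel <- to_relative_abundance(tab)
  expect_equal(unname(rel$values[1, ]), c(0.25, 0.25, 0.5))
  expect_equal(unname(rel$values[2, ]), c(1, 0, 0))
  expect_identical(rel$unit, "relative")
  expect_identical(rel$sample_ids, tab$sample_ids)
})

test_that("an all-zero sample aborts normalization, naming the sample", {
  tab <- make_table(matrix(c(1, 2, 0, 0), nrow = 2, byrow = TRUE),
                    samples = c("ok", "empty_sample"))
  expect_error(to_relative_abundance(tab), "empty_sample")
})

test_that("default pseudocount is the largest power of ten strictly below the minimum", {
  tab_a <- make_table(matrix(c(3.2e-4, 1 - 3.2e-4), nrow = 1), unit = "relative")
  expect_equal(default_pseudocount(tab_a), 1e-4)
  # an exact power of ten forces the next power down ("below" is strict)
  tab_b <- make_table(matrix(c(1e-3, 1 - 1e-3), nrow = 1), unit = "relative")
  expect_equal(default_pseudocount(tab_b), 1e-4)
  tab_zero <- make_table(matrix(0, 1, 2))
  expect_error(default_pseudocount(tab_zero), "positive")
})

test_that("default pseudocount rule holds as a property over random tables", {
  set.seed(42)
  for (i in 1:200) {
    m_min <- 10^stats::runif(1, -8, -1)
    v <- c(m_min, sort(stats::runif(5, m_min, 1)))
    tab <- make_table(matrix(v / sum(v), nrow = 1), unit = "relative")
    m <- min(tab$values[tab$values > 0])
    c_ <- default_pseudocount(tab)
    expect_lt(c_, m)
    expect_gt(c_, m / 10)
    expect_equal(log10(c_), round(log10(c_)), tolerance = 1e-9)
  }
})

test_that("pseudocounts are added in the requested space", {
  rel <- make_table(matrix(c(0, 0.5, 0.5), nrow = 1), unit = "relative")
  comp <- add_pseudocount(rel, 1e-6, mode = "relative_space")
  expect_equal(unname(comp$values[1, ]), c(1e-6, 0.500001, 0.500001))
  cnt <- make_table(matrix(c(0, 1, 3), nrow = 1), unit = "counts")
  comp2 <- add_pseudocount(cnt, 1, mode = "count_space")
  expect_equal(unname(comp2$values[1, ]), c(1 / 7, 2 / 7, 4 / 7))
  expect_error(add_pseudocount(rel, 0), "positive")
  expect_error(add_pseudocount(rel, 1e-6, mode = "count_space"), "count")
  expect_error(add_pseudocount(cnt, 1, mode = "relative_space"), "relative")
})

test_that("CLR maps equal compositions to zero and splits ln-ratios symmetrically", {
  comp <- positive_composition(
    matrix(c(0.5, 0.5), 1, dimnames = list("s1", c("a", "b"))), 1e-6)
  expect_equal(unname(clr_transform(comp)$values[1, ]), c(0, 0))
  comp2 <- positive_composition(
    matrix(c(exp(1), 1), 1, dimnames = list("s1", c("a", "b"))), 1e-6)
  expect_equal(unname(clr_transform(comp2)$values[1, ]), c(0.5, -0.5))
})

test_that("CLR rows close to zero and are invariant to row rescaling", {
  set.seed(7)
  for (i in 1:20) {
    m <- random_pos_matrix(5, 8)
    clr <- clr_transform(positive_composition(m, 1e-6))
    expect_true(all(abs(rowSums(clr$values)) < 1e-8))
    lambda <- 10^stats::runif(1, -6, 6)
    clr2 <- clr_transform(positive_composition(m * lambda, 1e-6))
    expect_equal(clr2$values, clr$values, tolerance = 1e-9)
  }
})

test_that("CLR agrees with vegan's implementation", {
  skip_if_not_installed("vegan")
  set.seed(11)
  m <- random_pos_matrix(6, 10)
  ours <- clr_transform(positive_composition(m, 1e-6))$values
  ref <- as.matrix(vegan::decostand(m, method = "clr", pseudocount = 0))
  expect_equal(as.vector(ours), as.vector(ref), tolerance = 1e-10)
})

test_that("CLR refuses non-positive entries, naming sample and feature", {
  m <- matrix(c(1, 0, 2, 3), 2, dimnames = list(c("s1", "s2"), c("fa", "fb")))
  expect_error(positive_composition(m, 1e-6), "s2.*fa|fa.*s2")
})

test_that("a pseudocount-only feature transforms to ln(c) - ln(g)", {
  set.seed(3)
  c_ <- 1e-6
  for (i in 1:50) {
    row <- random_rel_row(n_pos = sample(3:30, 1), n_zero = sample(1:5, 1))
    x <- row + c_
    m <- matrix(x, 1, dimnames = list("s", sprintf("f%d", seq_along(x))))
    clr <- clr_transform(positive_composition(m, c_))$values[1, ]
    g <- geometric_mean(x)
    j <- which(row == 0)
    expect_equal(unname(clr[j]), rep(log(c_) - log(g), length(j)),
                 tolerance = 1e-10)
  }
})

test_that("CLR value at a zero-filled feature increases strictly with the pseudocount", {
  set.seed(5)
  row <- random_rel_row(n_pos = 10, n_zero = 1)
  j <- which(row == 0)
  grid <- 10^seq(-8, -2)
  vals <- vapply(grid, function(c_) {
    m <- matrix(row + c_, 1, dimnames = list("s", sprintf("f%d", seq_along(row))))
    clr_transform(positive_composition(m, c_))$values[1, j]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("geometric mean behaves as the exp-mean-log and is lowered by tiny entries", {
  expect_equal(geometric_mean(rep(0.25, 4)), 0.25)
  expect_equal(geometric_mean(c(4, 1)), 2)
  a <- c(0.3, 0.7)
  expect_lt(geometric_mean(c(1e-6, a)), geometric_mean(a))
  expect_error(geometric_mean(c(1, 0)), "positive")
})

test_that("Shannon diversity matches hand-computed values and vegan", {
  expect_equal(shannon_diversity(rep(1 / 7, 7)), log(7))
  expect_equal(shannon_diversity(c(1, 0, 0)), 0)
  expect_equal(shannon_diversity(c(0.5, 0.25, 0.25)), 1.5 * log(2),
               tolerance = 1e-12)
  expect_error(shannon_diversity(c(0.5, 0.4)), "sum to 1")
  expect_error(shannon_diversity(c(-0.1, 1.1)), "negative")
  skip_if_not_installed("vegan")
  set.seed(13)
  row <- random_rel_row(12)
  expect_equal(shannon_diversity(row),
               unname(vegan::diversity(matrix(row, 1), index = "shannon")),
               tolerance = 1e-12)
})

test_that("Shannon equals minus log of the weighted geometric mean on 1000 random rows", {
  set.seed(101)
  for (i in 1:1000) {
    row <- random_rel_row(n_pos = sample(2:40, 1), n_zero = sample(0:10, 1))
    wgm <- weighted_geometric_mean(row)
    expect_gt(wgm, 0); expect_lte(wgm, 1)
    expect_equal(shannon_diversity(row), -log(wgm), tolerance = 1e-10)
  }
})

test_that("weighted geometric mean handles the degenerate and uniform cases", {
  expect_equal(weighted_geometric_mean(1), 1)
  expect_equal(weighted_geometric_mean(rep(0.2, 5)), 0.2)
})
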
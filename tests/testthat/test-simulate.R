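test_that("counterexample simulation is deterministic and balanced", {
  cfg <- simulation_config(seed = 99)
  ds1 <- simulate_counterexample(cfg)
  ds2 <- simulate_counterexample(cfg)
  expect_identical(ds1$table$values, ds2$table$values)
  expect_identical(ds1$labels, ds2$labels)
  expect_equal(unname(table(ds1$labels)["positive"]), 50)
  expect_equal(unname(table(ds1$labels)["negative"]), 50)
  ds3 <- simulate_counterexample(simulation_config(seed = 100))
  expect_false(identical(ds1$table$values, ds3$table$values))
})

test_that("the empty variant has the stated support pattern", {
  ds <- simulate_counterexample(simulation_config(seed = 4))
  v <- ds$table$values
  expect_true(all(v[, ds$sparse_feature_id] == 0))
  pos <- names(ds$labels)[ds$labels == "positive"]
  neg <- names(ds$labels)[ds$labels == "negative"]
  expect_true(all(rowSums(v[pos, ] > 0) == 30))
  expect_true(all(rowSums(v[neg, ] > 0) == 20))
  expect_equal(unname(rowSums(v)), rep(1, 100), tolerance = 1e-9)
})

test_that("nonzero and partial sparse variants fill the last feature label-blind", {
  ds_nz <- simulate_counterexample(simulation_config(sparse_variant = "nonzero",
                                                     seed = 8))
  expect_true(all(ds_nz$table$values[, ds_nz$sparse_feature_id] > 0))
  ds_p <- simulate_counterexample(simulation_config(sparse_variant = "partial",
                                                    partial_fraction = 0.2,
                                                    seed = 8))
  expect_equal(sum(ds_p$table$values[, ds_p$sparse_feature_id] > 0),
               round(0.2 * 100))
})

test_that("simulation config validates its sizes", {
  expect_error(simulation_config(n_positive = 0), "positive integers")
  expect_error(simulation_config(n_features_positive = 31), "smaller")
  expect_error(simulation_config(pseudocount = -1), "positive")
  expect_error(simulation_config(sparse_variant = "partial",
                                 partial_fraction = 1.2), "between")
})

test_that("cohort simulation separates Shannon diversity by design", {
  ds <- simulate_cohort(cohort_config(seed = 21))
  rel <- to_relative_abundance(ds$table)
  H <- shannon_diversities(rel)
  case <- ds$labels == "case"
  mw <- mann_whitney_u(H[case], H[!case])
  expect_lt(mean(H[case]), mean(H[!case]))
  expect_lt(mw$p_value, 0.05)
})

test_that("the singleton taxon carries exactly one read in one sample", {
  ds <- simulate_cohort(cohort_config(seed = 31))
  col <- ds$table$values[, ds$sparse_feature_id]
  expect_equal(sum(col > 0), 1)
  expect_equal(sum(col), 1)
  ds2 <- simulate_cohort(cohort_config(singleton_taxon = FALSE, seed = 31))
  expect_null(ds2$sparse_feature_id)
})

test_that("cohort simulation is deterministic under a fixed seed", {
  a <- simulate_cohort(cohort_config(seed = 77))
  b <- simulate_cohort(cohort_config(seed = 77))
  expect_identical(a$table$values, b$table$values)
})

test_that("Shannon separation grows with the concentration gap", {
  pairs <- list(c(0.8, 1.25), c(0.3, 3), c(0.1, 10))
  gaps <- vapply(seq_along(pairs), function(k) {
    mean(vapply(1:10, function(r) {
      ds <- simulate_cohort(cohort_config(
        concentration_low_diversity = pairs[[k]][1],
        concentration_high_diversity = pairs[[k]][2],
        singleton_taxon = FALSE, seed = 1000 * k + r))
      H <- shannon_diversities(to_relative_abundance(ds$table))
      mean(H[ds$labels == "control"]) - mean(H[ds$labels == "case"])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})
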
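boot_small <- function(n = 150, n_boot = 25, seed = 1, ...) {
  spec <- small_spec(n = n)
  ds <- generate_panel(spec, seed = 99)
  cfg <- test_config(seed = seed, n_boot = n_boot, ...)
  bootstrap_edges(ds, cfg)
}

test_that("bootstrap is deterministic given the root seed", {
  b1 <- boot_small()
  b2 <- boot_small()
  expect_identical(b1$edge_table$ci_low, b2$edge_table$ci_low)
  expect_identical(b1$edge_boot, b2$edge_boot)
  expect_equal(length(b1$streams), b1$n_boot + b1$n_redrawn)
  b3 <- boot_small(seed = 2)
  expect_false(identical(b1$edge_boot, b3$edge_boot))
})

test_that("percentile CIs are ordered and bracket the bootstrap mass", {
  b <- boot_small()
  expect_true(all(b$edge_table$ci_low <= b$edge_table$ci_high))
  expect_true(all(b$edge_table$boot_mean >= b$edge_table$ci_low - 1e-12))
  expect_true(all(b$edge_table$boot_mean <= b$edge_table$ci_high + 1e-12))
})

test_that("a strong edge's CI excludes zero at n = 800", {
  b_true <- diag(0.15, 4)
  b_true[3, 1] <- 0.5
  spec <- small_spec(n = 800, b = b_true)
  ds <- generate_panel(spec, seed = 55)
  bt <- bootstrap_edges(ds, test_config(seed = 3, n_boot = 100),
                        compute_centralities = FALSE)
  row <- bt$edge_table[bt$edge_table$source == "IU1" &
                         bt$edge_table$target == "GA1", ]
  expect_gt(row$ci_low, 0)
})

test_that("edge difference tests: self-comparison, separation, guards", {
  b_true <- diag(0.15, 4)
  b_true[3, 1] <- 0.5                      # strong IU1 -> GA1
  spec <- small_spec(n = 800, b = b_true)
  ds <- generate_panel(spec, seed = 77)
  bt <- bootstrap_edges(ds, test_config(seed = 5, n_boot = 100))

  self <- edge_difference_test(bt, c("IU1", "GA1"), c("IU1", "GA1"))
  expect_false(self$significant)
  sep <- edge_difference_test(bt, c("IU1", "GA1"), c("IU2", "GA2"))
  expect_true(sep$significant)
  expect_error(edge_difference_test(bt, c("XX", "GA1"), c("IU1", "GA1")),
               class = "clpn_validation_error")
})

test_that("centrality difference tests: self, hub vs isolated, guards", {
  b_true <- diag(0.15, 4)
  b_true[1, 2] <- 0.4; b_true[1, 3] <- 0.4; b_true[1, 4] <- 0.4  # GA1 hub
  spec <- small_spec(n = 800, b = b_true)
  ds <- generate_panel(spec, seed = 78)
  bt <- bootstrap_edges(ds, test_config(seed = 6, n_boot = 100))

  self <- centrality_difference_test(bt, "GA1", "GA1", "crosslagged_out")
  expect_false(self$significant)
  hub <- centrality_difference_test(bt, "GA1", "IU2", "crosslagged_out")
  expect_true(hub$significant)
  expect_error(centrality_difference_test(bt, "GA1", "IU2", "strength"),
               class = "clpn_validation_error")
  expect_error(centrality_difference_test(bt, "GA1", "nope",
                                          "crosslagged_in"),
               class = "clpn_validation_error")
})

test_that("CS coefficient: boundary, failure, and mixed grids", {
  props <- c(0.1, 0.3, 0.5, 0.7)
  all_good <- matrix(0.9, 40, 4)
  expect_equal(cs_coefficient(all_good, props), 0.7)  # criterion always met
  all_bad <- matrix(0.2, 40, 4)
  expect_equal(cs_coefficient(all_bad, props), 0)
  mixed <- cbind(rep(0.9, 40), rep(0.9, 40), rep(c(0.9, 0.2), 20),
                 rep(0.2, 40))
  expect_equal(cs_coefficient(mixed, props), 0.3)
  # NA columns count as failures
  na_col <- cbind(rep(0.9, 40), matrix(NA_real_, 40, 3))
  expect_equal(cs_coefficient(na_col, props), 0.1)
})

test_that("case-dropping stability: curve anchors, skipping, determinism", {
  spec <- small_spec(n = 200)
  ds <- generate_panel(spec, seed = 101)
  cfg <- test_config(seed = 7, n_boot = 10,
                     drop_proportions = c(0.2, 0.5))
  st <- case_drop_stability(ds, cfg, n_subsamples = 10)
  expect_equal(st$proportions[1], 0)
  expect_equal(st$curve$median[st$curve$proportion == 0], c(1, 1, 1))
  expect_true(all(st$cs >= 0 & st$cs <= 0.5))
  st2 <- case_drop_stability(ds, cfg, n_subsamples = 10)
  expect_identical(st$correlations, st2$correlations)

  # a proportion leaving fewer subjects than cv_folds is skipped
  tiny <- generate_panel(small_spec(n = 24), seed = 8)
  expect_false(clpnet:::any_constant_node(tiny))
  cfg2 <- test_config(seed = 1, cv_folds = 10,
                      drop_proportions = c(0.2, 0.7), n_boot = 3)
  expect_warning(st3 <- case_drop_stability(tiny, cfg2, n_subsamples = 3),
                 "skipped")
  expect_equal(st3$skipped, 0.7)
})

test_that("subsample correlations degrade as more cases are dropped", {
  b_true <- diag(0.2, 4)
  b_true[3, 1] <- 0.45; b_true[1, 4] <- 0.35; b_true[2, 3] <- 0.3
  spec <- small_spec(n = 1200, b = b_true)
  ds <- generate_panel(spec, seed = 107)
  cfg <- test_config(seed = 9, drop_proportions = c(0.1, 0.6))
  st <- case_drop_stability(ds, cfg, statistics = "edge", n_subsamples = 20)
  m <- colMeans(st$correlations$edge, na.rm = TRUE)
  expect_gt(m[1], m[2])
})
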
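test_that("descriptive table matches the adjusted-moment oracle", {
  nodes <- toy_nodes()
  # [1,2,3] in one column: mean 2, sd 1
  w1 <- cbind(c(1, 2, 3), c(2, 2, 2) + c(-1, 0, 1), c(1, 3, 5), c(2, 3, 4))
  ds <- panel_dataset(1:3, w1, w1, nodes)
  dt <- descriptive_table(ds)
  r <- dt[dt$node_id == "GA1" & dt$wave == 1, ]
  expect_equal(r$mean, 2)
  expect_equal(r$sd, 1)
  expect_equal(r$skewness, 0, tolerance = 1e-12)  # symmetric sample

  # random sample: both estimators match textbook formulas to 1e-10
  set.seed(50)
  x <- sample(1:4, 50, replace = TRUE)
  m <- matrix(rep(x, 4), 50, 4)
  ds2 <- panel_dataset(1:50, m, m, nodes)
  dt2 <- descriptive_table(ds2)
  or <- moments_oracle(m[, 2])
  got <- dt2[dt2$node_id == "GA2" & dt2$wave == 1, ]
  expect_equal(got$skewness, or$skewness, tolerance = 1e-10)
  expect_equal(got$kurtosis, or$kurtosis, tolerance = 1e-10)
})

test_that("non-normality flag follows the |skew| > 2 / |kurt| > 7 rule", {
  nodes <- toy_nodes()
  skewed <- c(rep(1, 57), rep(4, 3))     # heavily right-skewed
  mild <- sample(rep(1:4, 15))
  w <- cbind(skewed, mild, rep(1:5, 12), rep(1:5, 12))
  ds <- panel_dataset(1:60, w, w, nodes)
  dt <- descriptive_table(ds)
  expect_true(dt[dt$node_id == "GA1" & dt$wave == 1, "nonnormal"])
  expect_false(dt[dt$node_id == "GA2" & dt$wave == 1, "nonnormal"])
  or <- moments_oracle(skewed)
  expect_true(abs(or$skewness) > 2)
})

test_that("constant node column yields NA shape stats with a warning", {
  nodes <- toy_nodes()
  w <- cbind(rep(2, 10), rep(1:2, 5), rep(1:5, 2), rep(1:5, 2))
  ds <- panel_dataset(1:10, w, w, nodes)
  warns <- capture_warnings(dt <- descriptive_table(ds))
  expect_true(any(grepl("constant", warns)))  # flagged for both waves
  r <- dt[dt$node_id == "GA1" & dt$wave == 1, ]
  expect_equal(r$sd, 0)
  expect_true(is.na(r$skewness))
})

test_that("paired comparison: identity, formula oracle, monotonicity", {
  x <- c(1, 2, 3, 4, 5)
  id <- paired_comparison(x, x)
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
  expect_equal(id$mean_difference, 0)
  expect_equal(id$cohens_d, 0)

  # n = 5 worked vectors against a from-scratch evaluation
  x1 <- c(2, 3, 1, 4, 2)
  x2 <- c(3, 3, 2, 6, 2)
  got <- paired_comparison(x1, x2)
  d <- x2 - x1
  t_exp <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(got$t, t_exp, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_exp), df = 4), tolerance = 1e-12)
  expect_equal(got$cohens_d, mean(d) / sd(d), tolerance = 1e-12)
  expect_lt(got$d_low, got$d_high)
  expect_equal(sign(got$mean_difference), sign(got$cohens_d))

  # shifting x2 upward strictly increases t
  set.seed(8)
  a <- rnorm(40); b <- a + rnorm(40, sd = 0.5)
  t0 <- paired_comparison(a, b)$t
  t1 <- paired_comparison(a, b + 0.3)$t
  expect_gt(t1, t0)

  expect_error(paired_comparison(c(1, 2, 3), c(2, 3, 4, 5)),
               class = "clpn_validation_error")
  expect_error(paired_comparison(c(1, 2, 3), c(2, 3, 4)),
               class = "clpn_degenerate_error")  # sd(d)=0, mean != 0
})

test_that("attrition comparison: identity, closed-form separation, guards", {
  g <- c(1, 2, 3, 4)
  same <- attrition_comparison(g, g)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(12)
  a <- rnorm(100, 0, 1); b <- rnorm(100, 1, 1)
  res <- attrition_comparison(a, b)
  expect_lt(res$p, 0.001)
  expect_equal(res$mean_completers, mean(a))
  expect_equal(res$mean_dropouts, mean(b))
  expect_error(attrition_comparison(1, c(1, 2)),
               class = "clpn_validation_error")
})

test_that("nonparanormal transform matches the truncated-ECDF formula", {
  x <- 1:5
  expect_equal(as.vector(nonparanormal_transform(cbind(x))), npn_oracle(x),
               tolerance = 1e-12)
  # with ties
  y <- c(1, 2, 2, 3, 5, 5, 5, 6)
  expect_equal(as.vector(nonparanormal_transform(cbind(y))), npn_oracle(y),
               tolerance = 1e-12)
})

test_that("nonparanormal invariants: ranks, scale, variance, constants", {
  set.seed(33)
  for (rep in 1:5) {
    x <- sample(1:5, 40, replace = TRUE) + rnorm(40, sd = 1e-6)
    z <- as.vector(nonparanormal_transform(cbind(x)))
    # rank-preserving: no inversions anywhere, strict away from the
    # Winsorized tails
    zo <- z[order(x)]
    expect_true(all(diff(zo) >= 0))
    mid <- 5:35
    expect_true(all(diff(zo[mid]) > 0))
    expect_equal(sd(z), 1, tolerance = 1e-8)                 # unit variance
    z2 <- as.vector(nonparanormal_transform(cbind(3.7 * x + 11)))
    expect_equal(z2, z, tolerance = 1e-12)                   # scale-invariant
  }
  expect_warning(zc <- nonparanormal_transform(cbind(c(2, 2, 2, 2))),
                 "constant")
  expect_equal(as.vector(zc), c(0, 0, 0, 0))
  expect_error(nonparanormal_transform(cbind(1:3)),
               class = "clpn_validation_error")
})

test_that("transform_panel gaussianizes both waves and leaves covariates", {
  ds <- toy_panel(n = 80)
  tr <- transform_panel(ds)
  expect_true(tr$transformed)
  expect_equal(apply(tr$wave1, 2, sd), rep(1, 4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(apply(tr$wave2, 2, sd), rep(1, 4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(tr$covariates, ds$covariates)
})

test_that("cronbach alpha: perfect parallel items give 1, formula holds", {
  set.seed(4)
  base <- rnorm(30)
  perfect <- cbind(base, base, base)
  expect_equal(cronbach_alpha(perfect), 1, tolerance = 1e-12)
  items <- cbind(base + rnorm(30), base + rnorm(30), base + rnorm(30))
  k <- 3
  manual <- k / (k - 1) *
    (1 - sum(apply(items, 2, var)) / var(rowSums(items)))
  expect_equal(cronbach_alpha(items), manual, tolerance = 1e-12)
  expect_error(cronbach_alpha(cbind(base)), class = "clpn_validation_error")
})
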
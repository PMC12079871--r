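test_that("generation is reproducible and honors response ranges", {
  spec <- synthetic_spec(n_subjects = 300, seed = 5)
  d1 <- generate_panel(spec)
  d2 <- generate_panel(spec)
  expect_identical(d1$wave1, d2$wave1)
  expect_identical(d1$wave2, d2$wave2)
  expect_identical(d1$covariates, d2$covariates)
  d3 <- generate_panel(spec, seed = 6)
  expect_false(identical(d1$wave1, d3$wave1))

  for (j in seq_along(spec$nodes)) {
    nd <- spec$nodes[[j]]
    expect_true(all(d1$wave1[, j] >= nd$response_min &
                      d1$wave1[, j] <= nd$response_max))
    expect_true(all(d1$wave2[, j] >= nd$response_min &
                      d1$wave2[, j] <= nd$response_max))
  }
})

test_that("spec validation: density, thresholds, positive definiteness", {
  expect_error(synthetic_spec(density = 1.4), class = "clpn_validation_error")
  expect_error(synthetic_spec(r_within = 0.1, r_between = 0.9),
               "positive definite", class = "clpn_validation_error")
  bad_th <- lapply(default_nodes(), function(nd) c(1, 0.5, 0.2))
  expect_error(synthetic_spec(thresholds = bad_th),
               class = "clpn_validation_error")
})

test_that("null model: cross-construct cross-wave correlations stay small", {
  spec <- synthetic_spec(n_subjects = 5000, seed = 9,
                         true_b = matrix(0, 19, 19), r_between = 0)
  ds <- generate_panel(spec, seed = 10)
  cons <- vapply(spec$nodes, `[[`, character(1), "construct")
  ga <- which(cons == "GA"); iu <- which(cons == "IU")
  cc <- cor(ds$wave1[, ga], ds$wave2[, iu])
  expect_lt(max(abs(cc)), 0.05)
})

test_that("GA thresholds produce right-skewed marginals at n = 5000", {
  spec <- synthetic_spec(n_subjects = 5000, seed = 11)
  ds <- generate_panel(spec)
  dt <- descriptive_table(ds)
  ga <- dt[grepl("^GA", dt$node_id), ]
  expect_true(all(ga$skewness > 0.8))
  iu <- dt[grepl("^IU", dt$node_id), ]
  expect_true(all(abs(iu$skewness) < 1))
})

test_that("latent-scale regression recovers the generating matrix", {
  spec <- synthetic_spec(n_subjects = 5000, seed = 13)
  ds <- generate_panel(spec, seed = 14, latent = TRUE)
  l1 <- attr(ds, "latent_wave1"); l2 <- attr(ds, "latent_wave2")
  p <- ncol(l1)
  z <- unlist(lapply(seq(1, p, by = 4), function(j) {  # a quarter of targets
    fit <- lm(l2[, j] ~ l1)
    (coef(fit)[-1] - spec$true_b[, j]) / sqrt(diag(vcov(fit)))[-1]
  }))
  # standardized errors behave like N(0,1): nearly all within 2.5 SE, none
  # outlandish
  expect_gte(mean(abs(z) <= 2.5), 0.95)
  expect_lt(max(abs(z)), 5)
})

test_that("recovery metrics on enumerated instances", {
  b <- matrix(0, 5, 5); diag(b) <- 0.2
  b[1, 2] <- 0.3; b[2, 3] <- -0.2
  # perfect recovery
  m <- recovery_metrics(b, b)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$weight_correlation, 1)
  # all-zero estimate
  m0 <- recovery_metrics(b, matrix(0, 5, 5))
  expect_equal(m0$sensitivity, 0)
  expect_equal(m0$specificity, 1)
  expect_true(m0$constant_estimate)
  expect_equal(m0$weight_correlation, 0)
  # 10 true edges, 5 recovered, no false positives
  b10 <- matrix(0, 6, 6)
  cells <- cbind(c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5),
                 c(2, 3, 4, 5, 1, 6, 2, 6, 1, 3))
  b10[cells] <- 0.2
  est <- matrix(0, 6, 6)
  est[cells[1:5, , drop = FALSE]] <- 0.15
  mh <- recovery_metrics(b10, est)
  expect_equal(mh$sensitivity, 0.5)
  expect_equal(mh$specificity, 1)
  # no true edges: sensitivity is a sentinel
  mn <- recovery_metrics(diag(0.2, 4), diag(0.1, 4))
  expect_true(is.na(mn$sensitivity))
  expect_true(mn$no_true_edges)
  # detection threshold screens small weights
  espec <- b; espec[1, 2] <- 0.05
  mt <- recovery_metrics(b, espec, threshold = 0.1)
  expect_equal(mt$sensitivity, 0.5)
})

test_that("oracle injection scores perfectly at every sample size", {
  spec <- small_spec(n = 100)
  pc <- power_analysis(spec, n_grid = c(50, 100), replications = 2,
                       config = test_config(seed = 1), seed = 1,
                       estimator = function(ds, cfg) spec$true_b)
  expect_equal(pc$sensitivity_mean, c(1, 1))
  expect_equal(pc$specificity_mean, c(1, 1))
  expect_equal(pc$correlation_mean, c(1, 1))
  expect_equal(pc$n_failed, c(0L, 0L))
})

test_that("recovery improves with sample size on a moderate-weight spec", {
  b <- diag(0.15, 4)
  b[3, 1] <- 0.25; b[1, 4] <- 0.2; b[4, 2] <- 0.25
  spec <- small_spec(b = b, seed = 21)
  pc <- power_analysis(spec, n_grid = c(250, 2000), replications = 5,
                       config = test_config(seed = 2), seed = 3,
                       detection = "nonzero")
  expect_gte(pc$sensitivity_mean[2], pc$sensitivity_mean[1])
  err <- function(i) 1 - pc$correlation_mean[i]
  expect_lt(err(2), err(1))
})

test_that("discretization degrades but does not destroy recovery", {
  spec <- small_spec(n = 2000, seed = 23)
  cors <- vapply(1:3, function(s) {
    ord <- generate_panel(spec, seed = 200 + s)
    lat <- latent_panel(spec, n = 2000, seed = 200 + s)
    cfg <- test_config(seed = s)
    m_ord <- recovery_metrics(spec$true_b,
                              estimate_clpn(transform_panel(ord), cfg))
    m_lat <- recovery_metrics(spec$true_b,
                              estimate_clpn(transform_panel(lat), cfg))
    c(m_ord$weight_correlation, m_lat$weight_correlation)
  }, numeric(2))
  expect_gte(mean(cors[1, ]), 0.8 * mean(cors[2, ]))
})
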
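test_that("estimated network is invariant under joint row permutation", {
  spec <- small_spec(n = 200)
  ds <- generate_panel(spec, seed = 5)
  cfg <- test_config(seed = 2)
  tr <- transform_panel(ds)
  res <- estimate_clpn(tr, cfg)

  perm <- sample(length(ds$subject_ids))
  dsp <- panel_dataset(ds$subject_ids[perm], ds$wave1[perm, ],
                       ds$wave2[perm, ], ds$nodes,
                       ds$covariates[perm, , drop = FALSE],
                       ds$covariate_names)
  resp <- estimate_clpn(transform_panel(dsp), cfg)
  expect_equal(res$weights, resp$weights, tolerance = 1e-10)
})

test_that("identical config and seed reproduce the result bitwise", {
  spec <- small_spec(n = 150)
  ds <- generate_panel(spec, seed = 8)
  cfg <- test_config(seed = 4)
  r1 <- estimate_clpn(transform_panel(ds), cfg)
  r2 <- estimate_clpn(transform_panel(ds), cfg)
  expect_identical(serialize(r1$weights, NULL), serialize(r2$weights, NULL))
  expect_identical(r1$threshold, r2$threshold)
})

test_that("result summaries are recomputable from the weight matrix", {
  spec <- small_spec(n = 300)
  ds <- generate_panel(spec, seed = 3)
  res <- estimate_clpn(transform_panel(ds), test_config(seed = 1))
  w <- res$weights
  expect_equal(res$autoregressive_mean, mean(abs(diag(w))))
  off <- w[row(w) != col(w)]
  expect_equal(res$crosslagged_mean, mean(abs(off[off != 0])))
})

test_that("strong cross-lagged paths are recovered with correct sign", {
  b <- diag(0.15, 4)
  b[3, 1] <- 0.5; b[1, 4] <- 0.5; b[4, 2] <- 0.5
  spec <- small_spec(n = 2000, b = b, seed = 17)
  ds <- generate_panel(spec, seed = 23)
  res <- estimate_clpn(transform_panel(ds), test_config(seed = 5))
  for (cell in list(c(3, 1), c(1, 4), c(4, 2))) {
    expect_gt(res$weights[cell[1], cell[2]], 0)
  }
})

test_that("a null generator yields a near-empty thresholded network", {
  b <- diag(0.15, 4)
  spec <- small_spec(n = 2000, b = b, seed = 19, r_between = 0)
  ds <- generate_panel(spec, seed = 29)
  res <- estimate_clpn(transform_panel(ds), test_config(seed = 6))
  off <- res$weights[row(res$weights) != col(res$weights)]
  expect_lt(max(abs(off)), 0.08)
  edges <- threshold_edges(res)
  # cross-construct cells (true zeros) should be absent from the network
  cons <- res$constructs
  cross <- edges[cons[match(edges$source, res$node_ids)] !=
                   cons[match(edges$target, res$node_ids)], ]
  expect_lte(nrow(cross), 2)
})

test_that("threshold rules: two-value mean, fixed, autoregressive exclusion", {
  w <- diag(0.2, 3)
  w[1, 2] <- 0.010; w[2, 3] <- 0.018
  res <- fake_result(w, constructs = c("GA", "GA", "IU"))
  edges <- threshold_edges(res, rule = "mean_abs_nonzero_crosslagged")
  expect_equal(attr(edges, "threshold"), 0.014)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$weight, 0.018)
  expect_false(any(edges$is_autoregressive))
  expect_equal(nrow(attr(edges, "autoregressive")), 3L)

  # fixed threshold above all weights empties the list
  empty <- threshold_edges(res, rule = "fixed", fixed_value = 0.05)
  expect_equal(nrow(empty), 0L)

  # diagonal-only matrix: empty cross-lagged list regardless of rule
  ar_only <- fake_result(diag(0.3, 3), constructs = c("GA", "GA", "IU"))
  expect_warning(e2 <- threshold_edges(ar_only), "no nonzero")
  expect_equal(nrow(e2), 0L)
  expect_equal(attr(e2, "threshold"), 0)

  # weak inequality: an edge exactly at the threshold is retained
  w3 <- diag(0.2, 3); w3[1, 2] <- 0.014; w3[2, 3] <- 0.014
  at <- threshold_edges(fake_result(w3, constructs = c("GA", "GA", "IU")),
                        rule = "fixed", fixed_value = 0.014)
  expect_equal(nrow(at), 2L)
})

test_that("edge summaries: percentage, tie-breaking, top-k", {
  e <- data.frame(source = c("A", "B", "C", "D"), target = c("B", "C", "D", "A"),
                  weight = c(0.2, 0.1, 0.05, 0.3), is_autoregressive = FALSE)
  s <- summarize_edges(e, top_k = 2)
  expect_equal(s$pct_positive, 100)
  expect_equal(nrow(s$top), 2L)
  expect_equal(s$top$weight[1], 0.3)

  tie <- data.frame(source = c("B", "A"), target = c("A", "B"),
                    weight = c(0.3, -0.3), is_autoregressive = FALSE)
  st <- summarize_edges(tie)
  expect_equal(st$pct_positive, 50)
  # lexicographic (source, target) order breaks the |weight| tie
  expect_equal(st$top$source, c("A", "B"))
})

test_that("covariate penalization honors the config switch", {
  spec <- small_spec(n = 300, n_covariates = 2)
  ds <- generate_panel(spec, seed = 31)
  tr <- transform_panel(ds)
  r_pen <- estimate_clpn(tr, test_config(seed = 7, penalize_covariates = TRUE))
  r_free <- estimate_clpn(tr, test_config(seed = 7, penalize_covariates = FALSE))
  expect_equal(dim(r_pen$covariate_weights), c(2L, 4L))
  # unpenalized covariates are never exactly zeroed; penalized ones can be
  expect_true(all(r_free$covariate_weights != 0))
})
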
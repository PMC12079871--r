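# Independent oracles and small fixtures used across the suite.

# From-scratch cyclic coordinate-descent LASSO solving
#   min (1/2n)||y - b0 - Xs b||^2 + lambda * sum(mask * |b|)
# with Xs = scale(X) (same standardization as the implementation).
# Kept deliberately independent of glmnet.
lasso_cd_oracle <- function(y, x, lambda, mask = rep(1, ncol(x)),
                            tol = 1e-12, maxit = 1e5) {
  xs <- scale(as.matrix(x))
  n <- length(y)
  p <- ncol(xs)
  yc <- y - mean(y)
  xtx <- colSums(xs^2) / n
  beta <- rep(0, p)
  r <- yc
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(p)) {
      old <- beta[j]
      rho <- sum(xs[, j] * r) / n + xtx[j] * old
      new <- if (mask[j] > 0) {
        sign(rho) * max(0, abs(rho) - lambda * mask[j]) / xtx[j]
      } else {
        rho / xtx[j]
      }
      if (new != old) {
        r <- r - xs[, j] * (new - old)
        beta[j] <- new
        delta <- max(delta, abs(new - old))
      }
    }
    if (delta < tol) break
  }
  list(beta = beta, intercept = mean(y))
}

# Textbook adjusted-moment estimators (SPSS conventions): G1 skewness and
# G2 excess kurtosis.
moments_oracle <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  list(skewness = g1 * sqrt(n * (n - 1)) / (n - 2),
       kurtosis = ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)))
}

# Direct evaluation of the truncated-ECDF nonparanormal formula for one
# column, written independently of the package function.
npn_oracle <- function(x) {
  n <- length(x)
  delta <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
  f <- rank(x, ties.method = "average") / n
  z <- qnorm(pmin(pmax(f, delta), 1 - delta))
  z / sd(z)
}

# Tiny two-construct node sets.
toy_nodes <- function() {
  list(node_info("GA1", "GA", 1, 4), node_info("GA2", "GA", 1, 4),
       node_info("IU1", "IU", 1, 5), node_info("IU2", "IU", 1, 5))
}

# Wide-range nodes let continuous latent scores pass range validation, for
# tests that need the estimator's correctly-specified (latent-scale) regime.
wide_nodes <- function(ids_ga, ids_iu, lim = 50) {
  c(lapply(ids_ga, function(i) node_info(i, "GA", -lim, lim)),
    lapply(ids_iu, function(i) node_info(i, "IU", -lim, lim)))
}

# Panel holding the pre-discretization latent scores of a synthetic draw.
latent_panel <- function(spec, n = spec$n_subjects, seed = spec$seed,
                         lim = 50) {
  ds <- generate_panel(spec, n = n, seed = seed, latent = TRUE)
  cons <- vapply(spec$nodes, `[[`, character(1), "construct")
  ids <- vapply(spec$nodes, `[[`, character(1), "id")
  panel_dataset(
    subject_ids = ds$subject_ids,
    wave1 = attr(ds, "latent_wave1"),
    wave2 = attr(ds, "latent_wave2"),
    nodes = wide_nodes(ids[cons == "GA"], ids[cons == "IU"], lim = lim),
    covariates = ds$covariates,
    covariate_names = ds$covariate_names
  )
}

# 4-node spec (2 GA + 2 IU) with a hand-set cross-lagged structure; fast
# enough for resampling tests.
small_spec <- function(n = 400, b = NULL, seed = 11, n_covariates = 0, ...) {
  nodes <- toy_nodes()
  if (is.null(b)) {
    b <- diag(0.15, 4)
    b[3, 1] <- 0.4   # IU1 -> GA1
    b[1, 4] <- 0.3   # GA1 -> IU2
  }
  synthetic_spec(n_subjects = n, nodes = nodes, true_b = b,
                 n_covariates = n_covariates, seed = seed, ...)
}

# A toy raw panel with deterministic integer responses.
toy_panel <- function(n = 60, seed = 3) {
  spec <- small_spec(n = n, seed = seed)
  generate_panel(spec, seed = seed)
}

# Quick estimation settings for tests (smaller grid and folds than the
# analysis defaults; estimation accuracy at test sample sizes is unaffected).
test_config <- function(cv_folds = 5, lambda_grid_size = 30, n_boot = 0,
                        ...) {
  clpn_config(cv_folds = cv_folds, lambda_grid_size = lambda_grid_size,
              n_boot = n_boot, ...)
}

# A hand-built clpn_result for operations that only need a weight matrix.
fake_result <- function(weights, constructs = NULL) {
  ids <- rownames(weights) %||% paste0("N", seq_len(nrow(weights)))
  dimnames(weights) <- list(ids, ids)
  structure(
    list(weights = weights, node_ids = ids,
         constructs = constructs %||% rep(c("GA", "IU"),
                                          length.out = nrow(weights)),
         fits = NULL, covariate_weights = matrix(0, 0, nrow(weights)),
         autoregressive_mean = mean(abs(diag(weights))),
         crosslagged_mean = clpnet:::crosslagged_mean(weights),
         config = clpn_config(),
         threshold = clpnet:::compute_threshold(
           weights, "mean_abs_nonzero_crosslagged")),
    class = "clpn_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
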
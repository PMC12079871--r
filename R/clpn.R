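#' Estimate a cross-lagged panel network
#'
#' Runs one cross-validated LASSO regression per wave-2 node on all wave-1
#' nodes plus covariates (see [fit_node_lasso()]) and assembles the directed
#' coefficient matrix: entry (i, j) is the weight of node i at wave 1
#' predicting node j at wave 2, so the diagonal holds the autoregressive
#' paths and the off-diagonal the cross-lagged edges. Fold assignment per
#' target is derived from the subject ids and `config$seed` offset by the
#' target index, making the result reproducible and invariant under joint
#' row permutation of the panel.
#'
#' @param dataset A nonparanormal-transformed [panel_dataset()] (see
#'   [transform_panel()]); a warning is issued if the transformed flag is
#'   absent.
#' @param config A [clpn_config()].
#' @return An object of class `clpn_result`: `weights` (p x p), `node_ids`,
#'   `constructs`, `fits` (per-target `node_fit` with node and covariate
#'   coefficients split out), `covariate_weights` (q x p),
#'   `autoregressive_mean` (mean |diagonal|), `crosslagged_mean` (mean
#'   |nonzero off-diagonal|), `threshold` (under `config$threshold_rule`),
#'   and the config used.
#' @export
estimate_clpn <- function(dataset, config = clpn_config()) {
  config <- validate_config(config)
  if (!isTRUE(dataset$transformed)) {
    warning("dataset does not carry the transformed flag; ",
            "estimate_clpn expects nonparanormal-transformed waves")
  }
  ids <- node_ids(dataset$nodes)
  p <- length(ids)
  q <- ncol(dataset$covariates)
  x <- cbind(dataset$wave1, dataset$covariates)
  mask <- c(rep(1, p), rep(if (config$penalize_covariates) 1 else 0, q))

  weights <- matrix(0, p, p, dimnames = list(ids, ids))
  cov_w <- matrix(0, q, p, dimnames = list(dataset$covariate_names, ids))
  fits <- vector("list", p)
  names(fits) <- ids
  for (j in seq_len(p)) {
    fid <- stable_foldid(dataset$subject_ids, config$cv_folds,
                         derive_seed(config$seed, j))
    fit <- tryCatch(
      fit_node_lasso(dataset$wave2[, j], x, folds = config$cv_folds,
                     grid_size = config$lambda_grid_size,
                     lambda_rule = config$lambda_rule,
                     penalize_mask = mask, foldid = fid, target_id = ids[j]),
      error = function(e) {
        stop_clpn("node fit for target '%s' failed: %s", ids[j],
                  conditionMessage(e), class = "clpn_estimation_error")
      })
    weights[, j] <- fit$coefficients[seq_len(p)]
    if (q > 0) cov_w[, j] <- fit$coefficients[p + seq_len(q)]
    fit$node_coefficients <- fit$coefficients[seq_len(p)]
    fit$covariate_coefficients <- if (q > 0) {
      fit$coefficients[p + seq_len(q)]
    } else numeric(0)
    fits[[j]] <- fit
  }

  res <- structure(
    list(weights = weights, node_ids = ids,
         constructs = node_constructs(dataset$nodes),
         fits = fits, covariate_weights = cov_w,
         autoregressive_mean = mean(abs(diag(weights))),
         crosslagged_mean = crosslagged_mean(weights),
         config = config),
    class = "clpn_result"
  )
  res$threshold <- compute_threshold(weights, config$threshold_rule,
                                     config$fixed_threshold)
  res
}

# Mean absolute nonzero cross-lagged weight (0 when the off-diagonal is
# entirely zero).
crosslagged_mean <- function(weights) {
  off <- weights[row(weights) != col(weights)]
  nz <- off[off != 0]
  if (length(nz) == 0) 0 else mean(abs(nz))
}

compute_threshold <- function(weights, rule, fixed_value = NULL) {
  off <- weights[row(weights) != col(weights)]
  nz <- off[off != 0]
  switch(rule,
    mean_abs_nonzero_crosslagged = if (length(nz)) mean(abs(nz)) else 0,
    mean_signed_crosslagged = if (length(nz)) max(0, mean(nz)) else 0,
    fixed = {
      if (is.null(fixed_value)) {
        stop_clpn("fixed threshold rule requires a value",
                  class = "clpn_config_error")
      }
      fixed_value
    },
    stop_clpn("unknown threshold rule '%s'", rule, class = "clpn_config_error")
  )
}

#' Threshold the cross-lagged edges of an estimated network
#'
#' Retains cross-lagged (off-diagonal) edges with |weight| at or above the
#' threshold; autoregressive paths never enter the threshold computation or
#' the retained list and are carried separately. The default rule sets the
#' threshold to the mean absolute nonzero cross-lagged weight, the
#' conventional device for removing low-weight edges from a dense LASSO
#' solution.
#'
#' @param result A `clpn_result`.
#' @param rule Threshold rule (see [clpn_config()]); defaults to the rule in
#'   `result$config`.
#' @param fixed_value Threshold value when `rule = "fixed"`.
#' @return A data.frame of class `clpn_edge_list` with columns `source`,
#'   `target`, `weight`, `is_autoregressive` (all `FALSE` in the retained
#'   list), sorted by |weight| descending with ties broken by (source,
#'   target); attributes `threshold` and `autoregressive` (data.frame of the
#'   p diagonal paths).
#' @export
threshold_edges <- function(result, rule = NULL, fixed_value = NULL) {
  rule <- rule %||% result$config$threshold_rule
  fixed_value <- fixed_value %||% result$config$fixed_threshold
  w <- result$weights
  thr <- compute_threshold(w, rule, fixed_value)
  off <- which(row(w) != col(w) & w != 0, arr.ind = TRUE)
  if (nrow(off) == 0) {
    warning("no nonzero cross-lagged edges; returning empty edge list")
  }
  edges <- data.frame(
    source = result$node_ids[off[, 1]],
    target = result$node_ids[off[, 2]],
    weight = w[off],
    is_autoregressive = logical(nrow(off))
  )
  edges <- edges[abs(edges$weight) >= thr, , drop = FALSE]
  ord <- order(-abs(edges$weight), edges$source, edges$target)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  ar <- data.frame(source = result$node_ids, target = result$node_ids,
                   weight = diag(w), is_autoregressive = TRUE)
  structure(edges, class = c("clpn_edge_list", "data.frame"),
            threshold = thr, rule = rule, autoregressive = ar)
}

#' Summarize an edge list
#'
#' Counts of positive and negative cross-lagged edges, the percentage
#' positive (integer percent, as reported in network write-ups), and the
#' top-k edges by absolute weight.
#'
#' @param edges A `clpn_edge_list` (or data.frame with `source`, `target`,
#'   `weight`).
#' @param top_k Number of top edges to list.
#' @return A list of class `clpn_edge_summary`: `n_edges`, `n_positive`,
#'   `n_negative`, `pct_positive`, `share_positive`, `top`.
#' @export
summarize_edges <- function(edges, top_k = 10) {
  n <- nrow(edges)
  npos <- sum(edges$weight > 0)
  ord <- order(-abs(edges$weight), edges$source, edges$target)
  structure(
    list(n_edges = n, n_positive = npos, n_negative = sum(edges$weight < 0),
         pct_positive = if (n) round(100 * npos / n) else NA_integer_,
         share_positive = if (n) npos / n else NA_real_,
         top = utils::head(edges[ord, , drop = FALSE], top_k)),
    class = "clpn_edge_summary"
  )
}

#' @export
print.clpn_result <- function(x, ...) {
  nz <- sum(x$weights[row(x$weights) != col(x$weights)] != 0)
  cat(sprintf("CLPN: %d nodes, %d nonzero cross-lagged edges\n",
              length(x$node_ids), nz))
  cat(sprintf("  mean |autoregressive| = %.3f, mean |cross-lagged, nonzero| = %.3f\n",
              x$autoregressive_mean, x$crosslagged_mean))
  cat(sprintf("  threshold (%s) = %.4f\n", x$config$threshold_rule,
              x$threshold))
  invisible(x)
}

#' @export
print.clpn_edge_summary <- function(x, ...) {
  cat(sprintf("%d cross-lagged edges: %d positive (%d%%), %d negative\n",
              x$n_edges, x$n_positive, x$pct_positive, x$n_negative))
  print(x$top)
  invisible(x)
}
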
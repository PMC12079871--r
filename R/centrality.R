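#' In-/out-prediction centrality via nested variance decompositions
#'
#' Operationalizes the prediction-centrality indices of a cross-lagged panel
#' network as differences of R-squared between nested unpenalized
#' least-squares models fitted on the LASSO-selected support. For target
#' node j let M0 be the baseline predictor set (all covariates plus j's own
#' wave-1 score, so the autoregressive path is always partialed out, even if
#' the LASSO zeroed it), and let S_j be the LASSO-retained wave-1 predictors
#' of j excluding j itself, split into same-construct W_j and
#' other-construct X_j. Then
#' \itemize{
#'   \item cross-lagged in-prediction(j)   = R2(M0 + W_j + X_j) - R2(M0):
#'     variance explained by all other nodes' prior values;
#'   \item cross-construct in-prediction(j) = R2(M0 + W_j + X_j) -
#'     R2(M0 + W_j): the part attributable to the other construct;
#'   \item cross-lagged out-prediction(i) = sum over targets j != i with
#'     i in S_j of R2(full_j) - R2(full_j without i);
#'   \item cross-construct out-prediction(i) = the same sum restricted to
#'     targets in the other construct.
#' }
#' Every quantity is a nested-model delta-R2, hence nonnegative (values in
#' (-1e-12, 0) from floating point are clamped to 0), and each
#' cross-construct index is bounded above by its cross-lagged counterpart.
#'
#' @param dataset The nonparanormal-transformed [panel_dataset()] the network
#'   was estimated on.
#' @param result The `clpn_result` from [estimate_clpn()].
#' @return A data.frame of class `clpn_centrality` with columns `node_id`,
#'   `construct`, `crosslagged_out`, `crosslagged_in`, `crossconstruct_out`,
#'   `crossconstruct_in`.
#' @export
compute_centrality <- function(dataset, result) {
  ids <- result$node_ids
  cons <- result$constructs
  p <- length(ids)
  covs <- dataset$covariates
  w1 <- dataset$wave1

  out_cl <- out_cc <- in_cl <- in_cc <- numeric(p)
  names(out_cl) <- names(out_cc) <- names(in_cl) <- names(in_cc) <- ids

  for (j in seq_len(p)) {
    y <- dataset$wave2[, j]
    support <- which(result$weights[, j] != 0)
    s_j <- setdiff(support, j)
    same <- s_j[cons[s_j] == cons[j]]
    other <- s_j[cons[s_j] != cons[j]]

    m0 <- cbind(covs, w1[, j, drop = FALSE])
    r2_m0 <- ols_r2(y, m0)
    r2_m0w <- ols_r2(y, cbind(m0, w1[, same, drop = FALSE]))
    full_cols <- c(same, other)
    r2_full <- ols_r2(y, cbind(m0, w1[, full_cols, drop = FALSE]))

    in_cl[j] <- max(0, r2_full - r2_m0)
    in_cc[j] <- max(0, r2_full - r2_m0w)

    for (i in s_j) {
      rest <- setdiff(full_cols, i)
      d <- max(0, r2_full - ols_r2(y, cbind(m0, w1[, rest, drop = FALSE])))
      out_cl[i] <- out_cl[i] + d
      if (cons[i] != cons[j]) out_cc[i] <- out_cc[i] + d
    }
  }

  structure(
    data.frame(node_id = ids, construct = cons,
               crosslagged_out = out_cl, crosslagged_in = in_cl,
               crossconstruct_out = out_cc, crossconstruct_in = in_cc,
               row.names = NULL),
    class = c("clpn_centrality", "data.frame")
  )
}

# R^2 of an OLS fit with intercept; collinear columns are dropped by the
# pivoted QR inside lm.fit (with a warning, since a rank-deficient refit
# means the LASSO support was not identifiable in the refit).
ols_r2 <- function(y, x) {
  xm <- cbind(`(Intercept)` = 1, as.matrix(x))
  fit <- stats::lm.fit(xm, y)
  if (fit$rank < ncol(xm)) {
    warning("rank-deficient least-squares refit; collinear column(s) dropped")
  }
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Ranked centrality listings
#'
#' Orders nodes by each prediction index (ties broken by node id) and names
#' the most out-predictive and most in-predicted node per scope.
#'
#' @param table A `clpn_centrality` data.frame.
#' @return A list of class `clpn_centrality_report`: per-index rankings
#'   (`rankings`), the per-index argmax (`leaders`), and
#'   `no_predictive_structure = TRUE` when every index is zero everywhere.
#' @export
centrality_report <- function(table) {
  idx <- c("crosslagged_out", "crosslagged_in",
           "crossconstruct_out", "crossconstruct_in")
  rankings <- lapply(idx, function(k) {
    ord <- order(-table[[k]], table$node_id)
    table[ord, c("node_id", k)]
  })
  names(rankings) <- idx
  leaders <- vapply(rankings, function(r) r$node_id[1], character(1))
  structure(
    list(rankings = rankings, leaders = leaders,
         no_predictive_structure = all(vapply(idx, function(k) {
           all(table[[k]] == 0)
         }, logical(1)))),
    class = "clpn_centrality_report"
  )
}

#' @export
print.clpn_centrality_report <- function(x, ...) {
  if (x$no_predictive_structure) {
    cat("No predictive structure: all centrality indices are zero.\n")
    return(invisible(x))
  }
  for (k in names(x$leaders)) {
    cat(sprintf("  highest %-18s: %s\n", k, x$leaders[[k]]))
  }
  invisible(x)
}
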
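#' Nonparametric bootstrap of edge weights and centralities
#'
#' Resamples subjects with replacement `config$n_boot` times; each resample
#' is re-run through the full estimation pipeline (nonparanormal transform,
#' node-wise cross-validated LASSO, centrality decomposition) and the edge
#' weights and centrality indices are collected. Percentile 95% CIs are
#' reported per edge. A degenerate resample (one with a constant raw node
#' column, which the transform cannot Gaussianize) is redrawn and counted.
#' All resampling is driven by streams derived from `config$seed`, so a
#' given seed yields a bitwise-identical result.
#'
#' @param dataset A raw (untransformed) [panel_dataset()].
#' @param config A [clpn_config()]; `n_boot` controls the resample count.
#' @param compute_centralities Collect centrality distributions too (needed
#'   by [centrality_difference_test()])? Default `TRUE`.
#' @return An object of class `clpn_bootstrap`: `edge_table` (source,
#'   target, estimate, boot_mean, ci_low, ci_high, is_autoregressive),
#'   `edge_boot` (n_boot x p^2 matrix of vectorized weight matrices),
#'   `centrality_boot` (list of n_boot x p matrices per index), the
#'   full-sample `result` and `centrality`, `n_boot`, `n_redrawn`, `seed`,
#'   and `streams` (a log of every derived seed).
#' @export
bootstrap_edges <- function(dataset, config = clpn_config(),
                            compute_centralities = TRUE) {
  config <- validate_config(config)
  if (config$n_boot < 1L) {
    stop_clpn("bootstrap requires n_boot >= 1", class = "clpn_config_error")
  }
  n <- length(dataset$subject_ids)
  full <- fit_pipeline(dataset, config)
  ids <- full$result$node_ids
  p <- length(ids)
  pair_names <- as.vector(outer(ids, ids, function(a, b) paste0(a, "->", b)))

  edge_boot <- matrix(NA_real_, config$n_boot, p * p,
                      dimnames = list(NULL, pair_names))
  idx_names <- c("crosslagged_out", "crosslagged_in",
                 "crossconstruct_out", "crossconstruct_in")
  cent_boot <- if (compute_centralities) {
    stats::setNames(lapply(idx_names, function(k) {
      matrix(NA_real_, config$n_boot, p, dimnames = list(NULL, ids))
    }), idx_names)
  } else NULL

  n_redrawn <- 0L
  streams <- integer(0)
  for (b in seq_len(config$n_boot)) {
    attempt <- 0L
    repeat {
      sb <- derive_seed(config$seed, b * 131L + attempt)
      streams <- c(streams, sb)
      rows <- with_seed(sb, sample.int(n, n, replace = TRUE))
      sub <- subset_panel(dataset, rows)
      if (!any_constant_node(sub)) break
      n_redrawn <- n_redrawn + 1L
      attempt <- attempt + 1L
      if (attempt > 100L) {
        stop_clpn("could not draw a non-degenerate bootstrap resample",
                  class = "clpn_estimation_error")
      }
    }
    cfg_b <- config
    cfg_b$seed <- sb
    fb <- fit_pipeline(sub, cfg_b, centrality = compute_centralities)
    edge_boot[b, ] <- as.vector(fb$result$weights)
    if (compute_centralities) {
      for (k in idx_names) cent_boot[[k]][b, ] <- fb$centrality[[k]]
    }
  }

  est <- as.vector(full$result$weights)
  ci <- apply(edge_boot, 2, stats::quantile, probs = c(0.025, 0.975))
  src <- rep(ids, times = p)
  tgt <- rep(ids, each = p)
  edge_table <- data.frame(
    source = src, target = tgt, estimate = est,
    boot_mean = colMeans(edge_boot),
    ci_low = ci[1, ], ci_high = ci[2, ],
    is_autoregressive = src == tgt, row.names = NULL
  )

  structure(
    list(edge_table = edge_table, edge_boot = edge_boot,
         centrality_boot = cent_boot, result = full$result,
         centrality = full$centrality, n_boot = config$n_boot,
         n_redrawn = n_redrawn, seed = config$seed, streams = streams),
    class = "clpn_bootstrap"
  )
}

# Transform + estimate (+ centrality) in one step; the unit re-run on every
# resample and subsample.
fit_pipeline <- function(dataset, config, centrality = TRUE) {
  tr <- transform_panel(dataset)
  res <- estimate_clpn(tr, config)
  list(result = res,
       centrality = if (centrality) compute_centrality(tr, res) else NULL)
}

subset_panel <- function(dataset, rows) {
  structure(
    list(subject_ids = paste0("r", seq_along(rows)),
         wave1 = dataset$wave1[rows, , drop = FALSE],
         wave2 = dataset$wave2[rows, , drop = FALSE],
         covariates = dataset$covariates[rows, , drop = FALSE],
         covariate_names = dataset$covariate_names,
         nodes = dataset$nodes),
    class = "panel_dataset"
  )
}

any_constant_node <- function(dataset) {
  any(apply(dataset$wave1, 2, stats::sd) == 0) ||
    any(apply(dataset$wave2, 2, stats::sd) == 0)
}

boot_edge_col <- function(boot, edge) {
  key <- paste0(edge[1], "->", edge[2])
  if (!key %in% colnames(boot$edge_boot)) {
    stop_clpn("edge %s is not tracked in this bootstrap", key,
              class = "clpn_validation_error")
  }
  boot$edge_boot[, key]
}

#' Bootstrap edge-weight difference test
#'
#' Two edges differ significantly when the bootstrap percentile CI of their
#' weight difference excludes zero. Tests are unadjusted for multiplicity;
#' interpret patterns, not single stars.
#'
#' @param boot A `clpn_bootstrap`.
#' @param edge_a,edge_b Length-2 character vectors `c(source, target)`.
#' @param conf_level CI level.
#' @return A list: `significant`, `ci` (of the difference), `edge_a`,
#'   `edge_b`.
#' @export
edge_difference_test <- function(boot, edge_a, edge_b, conf_level = 0.95) {
  d <- boot_edge_col(boot, edge_a) - boot_edge_col(boot, edge_b)
  a <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(d, probs = c(a, 1 - a)))
  list(significant = ci[1] > 0 || ci[2] < 0, ci = ci,
       edge_a = paste0(edge_a, collapse = "->"),
       edge_b = paste0(edge_b, collapse = "->"))
}

#' Bootstrap centrality difference test
#'
#' @param boot A `clpn_bootstrap` built with `compute_centralities = TRUE`.
#' @param node_a,node_b Node ids.
#' @param index_name One of `"crosslagged_out"`, `"crosslagged_in"`,
#'   `"crossconstruct_out"`, `"crossconstruct_in"`.
#' @param conf_level CI level.
#' @return A list: `significant`, `ci`, `index_name`.
#' @export
centrality_difference_test <- function(boot, node_a, node_b, index_name,
                                       conf_level = 0.95) {
  if (is.null(boot$centrality_boot)) {
    stop_clpn("bootstrap was run without centrality distributions",
              class = "clpn_validation_error")
  }
  if (!index_name %in% names(boot$centrality_boot)) {
    stop_clpn("unknown centrality index '%s'", index_name,
              class = "clpn_validation_error")
  }
  m <- boot$centrality_boot[[index_name]]
  for (nd in c(node_a, node_b)) {
    if (!nd %in% colnames(m)) {
      stop_clpn("node '%s' is not tracked in this bootstrap", nd,
                class = "clpn_validation_error")
    }
  }
  d <- m[, node_a] - m[, node_b]
  a <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(d, probs = c(a, 1 - a)))
  list(significant = ci[1] > 0 || ci[2] < 0, ci = ci,
       index_name = index_name)
}

#' Case-dropping stability with CS coefficients
#'
#' For each drop proportion, draws subsamples of the retained fraction of
#' subjects without replacement, re-runs the full pipeline, and records the
#' Pearson correlation between subsample and full-sample statistics: the
#' vectorized cross-lagged (off-diagonal) edge weights, and the cross-lagged
#' in- and out-prediction vectors. The correlation-stability coefficient
#' CS(r, conf) is the largest tested proportion at which at least `conf` of
#' subsamples correlate >= r with the full sample; the reported value lies
#' on the tested grid (no interpolation), so its resolution is the grid's.
#' Proportion 0 (the full sample, correlation exactly 1) is prepended to the
#' curves by construction.
#'
#' @param dataset A raw [panel_dataset()].
#' @param config A [clpn_config()]; `drop_proportions`, `cs_correlation`,
#'   `cs_confidence` and `seed` are taken from it.
#' @param statistics Subset of `c("edge", "in", "out")`.
#' @param n_subsamples Subsamples per proportion (defaults to
#'   `config$n_boot`).
#' @return An object of class `clpn_stability`: `proportions` (with 0
#'   prepended), `correlations` (per statistic, a matrix subsamples x
#'   proportions), `curve` (long data.frame of correlation quantiles), `cs`
#'   (named vector `cs_edge`, `cs_in`, `cs_out`), `skipped` proportions.
#' @export
case_drop_stability <- function(dataset, config = clpn_config(),
                                statistics = c("edge", "in", "out"),
                                n_subsamples = NULL) {
  config <- validate_config(config)
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (any(config$drop_proportions > 0.75)) {
    stop_clpn("drop proportions above 0.75 are not supported",
              class = "clpn_config_error")
  }
  B <- n_subsamples %||% config$n_boot
  n <- length(dataset$subject_ids)
  need_cent <- any(c("in", "out") %in% statistics)
  full <- fit_pipeline(dataset, config, centrality = need_cent)
  w <- full$result$weights
  ref <- list(
    edge = w[row(w) != col(w)],
    "in" = if (need_cent) full$centrality$crosslagged_in,
    out = if (need_cent) full$centrality$crosslagged_out
  )

  props <- config$drop_proportions
  cors <- stats::setNames(lapply(statistics, function(s) {
    matrix(NA_real_, B, length(props),
           dimnames = list(NULL, format(props)))
  }), statistics)
  skipped <- numeric(0)

  for (k in seq_along(props)) {
    m <- ceiling((1 - props[k]) * n)
    if (m < config$cv_folds) {
      warning(sprintf("drop proportion %.2f leaves %d subjects (< cv_folds); skipped",
                      props[k], m))
      skipped <- c(skipped, props[k])
      next
    }
    for (b in seq_len(B)) {
      sb <- derive_seed(config$seed, 10000L * k + b)
      rows <- with_seed(sb, sample.int(n, m, replace = FALSE))
      sub <- subset_panel(dataset, rows)
      if (any_constant_node(sub)) next
      cfg_b <- config
      cfg_b$seed <- sb
      fb <- fit_pipeline(sub, cfg_b, centrality = need_cent)
      wb <- fb$result$weights
      vals <- list(
        edge = wb[row(wb) != col(wb)],
        "in" = if (need_cent) fb$centrality$crosslagged_in,
        out = if (need_cent) fb$centrality$crosslagged_out
      )
      for (s in statistics) {
        cors[[s]][b, k] <- safe_cor(ref[[s]], vals[[s]])
      }
    }
  }

  tested <- setdiff(props, skipped)
  cs <- vapply(statistics, function(s) {
    cs_coefficient(cors[[s]], props, config$cs_correlation,
                   config$cs_confidence)
  }, numeric(1))
  names(cs) <- paste0("cs_", statistics)

  curve <- do.call(rbind, lapply(statistics, function(s) {
    qs <- apply(cors[[s]], 2, function(col) {
      stats::quantile(col, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                      na.rm = TRUE)
    })
    data.frame(statistic = s, proportion = c(0, props),
               q025 = c(1, qs[1, ]), q25 = c(1, qs[2, ]),
               median = c(1, qs[3, ]), q75 = c(1, qs[4, ]),
               q975 = c(1, qs[5, ]), row.names = NULL)
  }))

  structure(
    list(proportions = c(0, props), correlations = cors, curve = curve,
         cs = cs, skipped = skipped, n_subsamples = B, seed = config$seed),
    class = "clpn_stability"
  )
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Correlation-stability (CS) coefficient
#'
#' The largest tested drop proportion at which at least `confidence` of
#' subsample correlations reach `correlation`. `NA` correlations (from
#' degenerate subsamples) count as failures; an all-`NA` column fails its
#' proportion; if no tested proportion qualifies the CS is 0.
#'
#' @param correlations Matrix (subsamples x proportions) of correlations
#'   with the full-sample statistic.
#' @param proportions Drop proportions, one per column.
#' @param correlation Correlation criterion (conventionally 0.7).
#' @param confidence Required fraction of qualifying subsamples
#'   (conventionally 0.95).
#' @return Scalar CS value on the tested grid (or 0).
#' @export
cs_coefficient <- function(correlations, proportions, correlation = 0.7,
                           confidence = 0.95) {
  ok <- vapply(seq_along(proportions), function(k) {
    col <- correlations[, k]
    if (all(is.na(col))) return(FALSE)
    mean(!is.na(col) & col >= correlation) >= confidence
  }, logical(1))
  if (!any(ok)) return(0)
  max(proportions[ok])
}

#' @export
print.clpn_stability <- function(x, ...) {
  cat(sprintf("Case-dropping stability (%d subsamples per proportion)\n",
              x$n_subsamples))
  for (k in names(x$cs)) cat(sprintf("  %s = %.2f\n", k, x$cs[[k]]))
  invisible(x)
}
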
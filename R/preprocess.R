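#' Descriptive statistics per node and wave
#'
#' Mean, SD, skewness and excess kurtosis for every node at both waves of the
#' raw (untransformed) panel, with a non-normality flag when |skewness| > 2
#' or |kurtosis| > 7. Skewness and kurtosis use the small-sample-adjusted
#' (SPSS-convention, type 2) estimators, since published descriptive tables
#' for questionnaire panels are conventionally produced under them.
#'
#' @param dataset A [panel_dataset()]; descriptives are computed on the raw
#'   responses, before any transformation.
#' @return A data.frame with one row per node per wave: `node_id`, `wave`,
#'   `mean`, `sd`, `skewness`, `kurtosis`, `nonnormal`. Constant columns get
#'   `NA` skewness/kurtosis with a warning.
#' @export
descriptive_table <- function(dataset) {
  ids <- node_ids(dataset$nodes)
  rows <- lapply(c(1, 2), function(w) {
    m <- if (w == 1) dataset$wave1 else dataset$wave2
    do.call(rbind, lapply(seq_along(ids), function(j) {
      x <- m[, j]
      s <- stats::sd(x)
      if (s == 0) {
        warning(sprintf("node %s wave %d is constant; skewness/kurtosis undefined",
                        ids[j], w))
        sk <- NA_real_; ku <- NA_real_
      } else {
        # adjusted estimators are defined for n >= 3 (skewness) / 4 (kurtosis)
        sk <- if (length(x) >= 3) e1071::skewness(x, type = 2) else NA_real_
        ku <- if (length(x) >= 4) e1071::kurtosis(x, type = 2) else NA_real_
      }
      data.frame(node_id = ids[j], wave = w, mean = mean(x), sd = s,
                 skewness = sk, kurtosis = ku,
                 nonnormal = isTRUE(abs(sk) > 2 || abs(ku) > 7))
    }))
  })
  do.call(rbind, rows)
}

#' Paired comparison of one node across waves
#'
#' Paired t-test of wave-2 minus wave-1 responses with mean difference,
#' 95% CI, and Cohen's d for paired data (mean difference over SD of the
#' differences). The d confidence interval uses the normal approximation
#' d +/- z(0.975) * sqrt(1/n + d^2/(2n)); this is a documented convention of
#' this package, not a claim about any particular published table's method.
#'
#' @param x1,x2 Equal-length numeric vectors (wave 1, wave 2), n >= 3.
#' @param conf_level Confidence level for both intervals.
#' @return A one-row data.frame: `t`, `df`, `p`, `mean_difference`,
#'   `diff_low`, `diff_high`, `cohens_d`, `d_low`, `d_high`.
#' @export
paired_comparison <- function(x1, x2, conf_level = 0.95) {
  if (length(x1) != length(x2)) {
    stop_clpn("paired vectors must have equal length",
              class = "clpn_validation_error")
  }
  n <- length(x1)
  if (n < 3) stop_clpn("need n >= 3 pairs", class = "clpn_validation_error")
  d <- x2 - x1
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) != 0) {
      stop_clpn("zero variance of differences with nonzero mean difference",
                class = "clpn_degenerate_error")
    }
    return(data.frame(t = 0, df = n - 1, p = 1, mean_difference = 0,
                      diff_low = 0, diff_high = 0, cohens_d = 0,
                      d_low = 0, d_high = 0))
  }
  tt <- stats::t.test(x2, x1, paired = TRUE, conf.level = conf_level)
  dval <- mean(d) / sdd
  se_d <- sqrt(1 / n + dval^2 / (2 * n))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    mean_difference = mean(d),
    diff_low = tt$conf.int[1], diff_high = tt$conf.int[2],
    cohens_d = dval, d_low = dval - z * se_d, d_high = dval + z * se_d
  )
}

#' Paired comparisons for every node
#'
#' @param dataset A [panel_dataset()].
#' @return A data.frame with one row per node (columns as in
#'   [paired_comparison()], plus `node_id` and the two wave means).
#' @export
paired_comparison_table <- function(dataset) {
  ids <- node_ids(dataset$nodes)
  do.call(rbind, lapply(seq_along(ids), function(j) {
    cmp <- paired_comparison(dataset$wave1[, j], dataset$wave2[, j])
    cbind(data.frame(node_id = ids[j],
                     mean_t1 = mean(dataset$wave1[, j]),
                     mean_t2 = mean(dataset$wave2[, j])),
          cmp)
  }))
}

#' Attrition comparison (completers vs. dropouts)
#'
#' Welch two-sample t-test comparing a baseline variable between subjects
#' retained at follow-up and those lost to attrition.
#'
#' @param completers,dropouts Numeric vectors, each of length >= 2.
#' @return A one-row data.frame: `t`, `df`, `p`, `mean_completers`,
#'   `mean_dropouts`.
#' @export
attrition_comparison <- function(completers, dropouts) {
  if (length(completers) < 2 || length(dropouts) < 2) {
    stop_clpn("each group needs >= 2 subjects", class = "clpn_validation_error")
  }
  if (stats::sd(completers) == 0 && stats::sd(dropouts) == 0 &&
      mean(completers) == mean(dropouts)) {
    return(data.frame(t = 0, df = length(completers) + length(dropouts) - 2,
                      p = 1, mean_completers = mean(completers),
                      mean_dropouts = mean(dropouts)))
  }
  tt <- stats::t.test(completers, dropouts, var.equal = FALSE)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, mean_completers = mean(completers),
             mean_dropouts = mean(dropouts))
}

#' Nonparanormal (Gaussian copula) transformation
#'
#' Column-wise rank-based Gaussianization: the average-rank empirical CDF
#' F(x) = rank(x)/n is Winsorized to [delta_n, 1 - delta_n] with
#' delta_n = 1 / (4 n^(1/4) sqrt(pi log n)), mapped through the standard
#' normal quantile function, and the result rescaled to unit sample
#' variance. The transform is monotone (rank-preserving) and invariant to
#' positive affine rescaling of the input; it is strictly monotone except
#' where Winsorization ties the most extreme ranks (those with
#' F outside [delta_n, 1 - delta_n]).
#'
#' @param x Numeric matrix (subjects x variables), n >= 4. Columns are
#'   transformed independently.
#' @param ties_method ECDF convention for ties; `"average"` (default) uses
#'   average ranks with F = rank/n, `"shifted"` uses rank/(n+1) (in which
#'   case Winsorization is typically inactive).
#' @return Matrix of the same shape. A constant column maps to all zeros
#'   with a warning (every observation sits at the distribution's median).
#' @export
nonparanormal_transform <- function(x, ties_method = c("average", "shifted")) {
  ties_method <- match.arg(ties_method)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) stop_clpn("need n >= 4 rows", class = "clpn_validation_error")
  delta <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
  out <- apply(x, 2, function(col) {
    if (stats::sd(col) == 0) {
      warning("constant column in nonparanormal_transform; returning zeros")
      return(rep(0, n))
    }
    f <- switch(ties_method,
                average = rank(col, ties.method = "average") / n,
                shifted = rank(col, ties.method = "average") / (n + 1))
    z <- stats::qnorm(pmin(pmax(f, delta), 1 - delta))
    z / stats::sd(z)
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Apply the nonparanormal transformation to a panel
#'
#' Transforms all node columns of both waves; covariates are left on their
#' original scale. The returned object carries `transformed = TRUE` and is
#' the expected input of [estimate_clpn()] and [compute_centrality()].
#'
#' @param dataset A [panel_dataset()].
#' @inheritParams nonparanormal_transform
#' @return A `panel_dataset` whose wave matrices hold transformed scores.
#' @export
transform_panel <- function(dataset, ties_method = "average") {
  out <- dataset
  out$wave1 <- nonparanormal_transform(dataset$wave1, ties_method)
  out$wave2 <- nonparanormal_transform(dataset$wave2, ties_method)
  out$transformed <- TRUE
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a set of items:
#' alpha = k/(k-1) * (1 - sum of item variances / variance of the total).
#'
#' @param items Numeric subjects x items matrix, k >= 2 items.
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2) stop_clpn("need >= 2 items", class = "clpn_validation_error")
  vt <- stats::var(rowSums(items))
  if (vt == 0) return(NA_real_)
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / vt)
}
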
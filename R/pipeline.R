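#' Run the full cross-lagged panel network analysis
#'
#' Executes the standard sequence on a raw panel: descriptive and
#' paired-comparison tables (on untransformed responses), nonparanormal
#' transformation, node-wise LASSO network estimation, edge thresholding,
#' prediction-centrality decomposition, nonparametric bootstrap accuracy,
#' case-dropping stability, and the subgroup sensitivity analysis. With
#' `config$n_boot = 0` the two resampling sections are marked skipped and
#' everything else still runs. The whole run is deterministic given
#' `config$seed`.
#'
#' @param dataset A raw [panel_dataset()].
#' @param config A [clpn_config()].
#' @param subgroup Run the cutoff-split sensitivity analysis? Disable when
#'   the panel has no screening construct.
#' @return An object of class `clpn_report` with elements `descriptives`,
#'   `paired_tests`, `result`, `edges`, `centrality`, `bootstrap`,
#'   `stability`, `subgroups` (each either populated or the string
#'   `"skipped"`), and a `provenance` block (config, config hash, seed,
#'   package version).
#' @export
run_full_analysis <- function(dataset, config = clpn_config(),
                              subgroup = TRUE) {
  config <- validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_clpn("stage '%s' failed: %s", name, conditionMessage(e),
                class = "clpn_stage_error")
    })
  }
  descriptives <- stage("descriptives", descriptive_table(dataset))
  paired <- stage("paired_tests", paired_comparison_table(dataset))
  transformed <- stage("transform", transform_panel(dataset))
  result <- stage("estimate", estimate_clpn(transformed, config))
  edges <- stage("threshold", threshold_edges(result))
  centrality <- stage("centrality", compute_centrality(transformed, result))
  boot <- if (config$n_boot > 0) {
    stage("bootstrap", bootstrap_edges(dataset, config))
  } else "skipped"
  stability <- if (config$n_boot > 0) {
    stage("stability", case_drop_stability(dataset, config))
  } else "skipped"
  subgroups <- if (subgroup) {
    stage("subgroups", subgroup_analysis(dataset, config))
  } else "skipped"

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  structure(
    list(descriptives = descriptives, paired_tests = paired,
         result = result, edges = edges, centrality = centrality,
         bootstrap = boot, stability = stability, subgroups = subgroups,
         provenance = list(
           package = "clpnet",
           version = as.character(utils::packageVersion("clpnet")),
           seed = config$seed,
           config = unclass(config),
           config_hash = config_hash(cfg_json)
         )),
    class = "clpn_report"
  )
}

config_hash <- function(json) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(json, f)
  unname(tools::md5sum(f))
}

#' Cutoff-split subgroup sensitivity analysis
#'
#' Splits the sample on the wave-1 native-scored sum of the screening
#' construct (sum >= cutoff is the high group; the per-item offset between
#' stored and native scoring is derived from the node ranges, see
#' [construct_sum_score()]) and re-runs transform + estimation +
#' thresholding independently per group. A group smaller than 10 subjects
#' per node triggers a stability caveat, echoing the usual caution about
#' sparse-group network estimates.
#'
#' @param dataset A raw [panel_dataset()].
#' @param config A [clpn_config()]; `subgroup_cutoff` sets the split.
#' @param construct Screening construct tag (default `"GA"`).
#' @param native_min Native minimum of the instrument's item scoring.
#' @return A list of class `clpn_subgroups`: per group (`high`, `low`) the
#'   `n`, `result`, `edges`, `n_nonzero` cross-lagged edges,
#'   `mean_abs_crosslagged`, `n_above_threshold`, and `caveat`; plus
#'   `cutoff` and a `comparison` data.frame of the density summaries.
#' @export
subgroup_analysis <- function(dataset, config = clpn_config(),
                              construct = "GA", native_min = 0) {
  config <- validate_config(config)
  score <- construct_sum_score(dataset, construct, wave = 1,
                               native_min = native_min)
  hi <- score >= config$subgroup_cutoff
  if (!any(hi) || all(hi)) {
    stop_clpn("cutoff %g produces an empty subgroup (high n = %d, low n = %d)",
              config$subgroup_cutoff, sum(hi), sum(!hi),
              class = "clpn_validation_error")
  }
  p <- length(dataset$nodes)
  fit_group <- function(rows, tag) {
    sub <- subset_panel(dataset, which(rows))
    sub$subject_ids <- dataset$subject_ids[rows]
    caveat <- NULL
    if (sum(rows) < 10 * p) {
      caveat <- sprintf(
        "group '%s' has %d subjects (< 10 per node); estimates may be unstable",
        tag, sum(rows))
      warning(caveat)
    }
    fb <- fit_pipeline(sub, config, centrality = FALSE)
    edges <- threshold_edges(fb$result)
    w <- fb$result$weights
    off <- w[row(w) != col(w)]
    list(n = sum(rows), result = fb$result, edges = edges,
         n_nonzero = sum(off != 0),
         mean_abs_crosslagged = if (any(off != 0)) mean(abs(off[off != 0])) else 0,
         n_above_threshold = nrow(edges), caveat = caveat)
  }
  high <- fit_group(hi, "high")
  low <- fit_group(!hi, "low")
  structure(
    list(high = high, low = low, cutoff = config$subgroup_cutoff,
         comparison = data.frame(
           group = c("high", "low"),
           n = c(high$n, low$n),
           n_nonzero = c(high$n_nonzero, low$n_nonzero),
           mean_abs_crosslagged = c(high$mean_abs_crosslagged,
                                    low$mean_abs_crosslagged),
           n_above_threshold = c(high$n_above_threshold,
                                 low$n_above_threshold))),
    class = "clpn_subgroups"
  )
}

#' Export an analysis report to disk
#'
#' Writes every report section as CSV (display precision 3 decimals for
#' edge and centrality tables; full precision retained in the JSON
#' companions), the thresholded network as GraphML, a full-precision master
#' JSON report from which every CSV can be regenerated, and a run log.
#' Nothing is written if any target file exists and `overwrite` is
#' disabled.
#'
#' @param report A `clpn_report` from [run_full_analysis()].
#' @param out_dir Output directory (created if absent).
#' @param overwrite Allow replacing existing files?
#' @return Invisibly, a data.frame manifest (`path`, `md5`).
#' @export
export_report <- function(report, out_dir, overwrite = FALSE) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_clpn("cannot create directory %s", out_dir,
                       class = "clpn_io_error")
  }
  files <- c("descriptives.csv", "paired_tests.csv", "edges.csv",
             "edges.json", "centrality.csv", "centrality.json",
             "bootstrap.csv", "stability.csv", "subgroups.csv",
             "network.graphml", "report.json", "run.log")
  paths <- file.path(out_dir, files)
  names(paths) <- files
  if (!overwrite) {
    hit <- paths[file.exists(paths)]
    if (length(hit)) {
      stop_clpn("output file(s) already exist (set overwrite = TRUE): %s",
                paste(basename(hit), collapse = ", "),
                class = "clpn_io_error")
    }
  }

  round_df <- function(df, digits = 3) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits)
    df
  }
  wcsv <- function(df, path) utils::write.csv(df, path, row.names = FALSE)

  wcsv(round_df(report$descriptives, 2), paths["descriptives.csv"])
  wcsv(round_df(report$paired_tests, 2), paths["paired_tests.csv"])
  edges_df <- as.data.frame(report$edges)
  wcsv(round_df(edges_df), paths["edges.csv"])
  jsonlite::write_json(
    list(threshold = attr(report$edges, "threshold"), edges = edges_df,
         autoregressive = attr(report$edges, "autoregressive")),
    paths["edges.json"], auto_unbox = TRUE, digits = NA)
  wcsv(round_df(as.data.frame(report$centrality)), paths["centrality.csv"])
  jsonlite::write_json(as.data.frame(report$centrality),
                       paths["centrality.json"], auto_unbox = TRUE,
                       digits = NA)
  if (inherits(report$bootstrap, "clpn_bootstrap")) {
    wcsv(report$bootstrap$edge_table, paths["bootstrap.csv"])
  } else {
    wcsv(data.frame(section = "bootstrap", status = "skipped"),
         paths["bootstrap.csv"])
  }
  if (inherits(report$stability, "clpn_stability")) {
    wcsv(report$stability$curve, paths["stability.csv"])
  } else {
    wcsv(data.frame(section = "stability", status = "skipped"),
         paths["stability.csv"])
  }
  if (inherits(report$subgroups, "clpn_subgroups")) {
    wcsv(report$subgroups$comparison, paths["subgroups.csv"])
  } else {
    wcsv(data.frame(section = "subgroups", status = "skipped"),
         paths["subgroups.csv"])
  }
  export_graphml(report$result, paths["network.graphml"],
                 edges = report$edges)
  jsonlite::write_json(report_to_json(report), paths["report.json"],
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("clpnet %s", report$provenance$version),
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("seed: %d", report$provenance$seed),
    sprintf("config_hash: %s", report$provenance$config_hash)
  ), paths["run.log"])

  manifest <- data.frame(path = unname(paths),
                         md5 = unname(tools::md5sum(unname(paths))),
                         row.names = NULL)
  invisible(manifest)
}

# Serializable view of a report: every CSV above is a projection of this.
report_to_json <- function(report) {
  list(
    provenance = report$provenance,
    descriptives = report$descriptives,
    paired_tests = report$paired_tests,
    weights = as.data.frame(report$result$weights),
    covariate_weights = as.data.frame(report$result$covariate_weights),
    threshold = attr(report$edges, "threshold"),
    edges = as.data.frame(report$edges),
    autoregressive = attr(report$edges, "autoregressive"),
    centrality = as.data.frame(report$centrality),
    bootstrap = if (inherits(report$bootstrap, "clpn_bootstrap")) {
      report$bootstrap$edge_table
    } else "skipped",
    stability = if (inherits(report$stability, "clpn_stability")) {
      list(curve = report$stability$curve,
           cs = as.list(report$stability$cs))
    } else "skipped",
    subgroups = if (inherits(report$subgroups, "clpn_subgroups")) {
      report$subgroups$comparison
    } else "skipped"
  )
}

#' Export a network as GraphML
#'
#' Writes a directed weighted graph with a `weight` edge attribute, an
#' `is_autoregressive` edge attribute, and a `construct` vertex attribute.
#'
#' @param result A `clpn_result`.
#' @param path Output path.
#' @param edges Optional `clpn_edge_list` (thresholded); by default all
#'   nonzero edges (including autoregressive paths) are written.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(result, path, edges = NULL) {
  if (is.null(edges)) {
    w <- result$weights
    nz <- which(w != 0, arr.ind = TRUE)
    ed <- data.frame(source = result$node_ids[nz[, 1]],
                     target = result$node_ids[nz[, 2]],
                     weight = w[nz],
                     is_autoregressive = nz[, 1] == nz[, 2])
  } else {
    ed <- rbind(as.data.frame(edges),
                attr(edges, "autoregressive")[
                  attr(edges, "autoregressive")$weight != 0, , drop = FALSE])
  }
  g <- igraph::graph_from_data_frame(
    ed, directed = TRUE,
    vertices = data.frame(name = result$node_ids,
                          construct = result$constructs))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Plot an estimated network
#'
#' Minimal static plot of the thresholded cross-lagged network: constructs
#' are color-coded, edge width scales with |weight|, dashed edges are
#' negative.
#'
#' @param x A `clpn_result`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.clpn_result <- function(x, ...) {
  edges <- threshold_edges(x)
  if (nrow(edges) == 0) {
    warning("no edges to plot")
    return(invisible(NULL))
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges), directed = TRUE,
    vertices = data.frame(name = x$node_ids, construct = x$constructs))
  cons <- unique(x$constructs)
  vcol <- c("lightsteelblue", "lightsalmon")[match(x$constructs, cons)]
  ew <- abs(igraph::E(g)$weight)
  igraph::plot.igraph(
    g, vertex.color = vcol,
    edge.width = 1 + 4 * ew / max(ew),
    edge.lty = ifelse(igraph::E(g)$weight < 0, 2, 1),
    edge.arrow.size = 0.3, ...)
  invisible(g)
}

#' @export
print.clpn_report <- function(x, ...) {
  cat("CLPN analysis report\n")
  status <- function(s) if (identical(s, "skipped")) "skipped" else "ok"
  for (k in c("descriptives", "paired_tests", "result", "edges",
              "centrality", "bootstrap", "stability", "subgroups")) {
    cat(sprintf("  %-12s %s\n", k, status(x[[k]])))
  }
  invisible(x)
}
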
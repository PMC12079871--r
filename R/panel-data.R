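#' Describe a network node
#'
#' A node is one questionnaire item: a short id, the construct it belongs to
#' (a two-wave panel analysis always involves exactly two constructs, e.g.
#' generalized-anxiety symptoms vs. intolerance-of-uncertainty elements), and
#' the declared response range. Ranges are dataset-declared, never assumed:
#' the same instrument can be stored 0-based or 1-based, and downstream
#' sum-score logic (see [gad7_native_sum()]) derives any offset from these
#' fields.
#'
#' @param id Short unique label, e.g. `"GA1"`, `"IU10"`.
#' @param construct Construct tag, e.g. `"GA"` or `"IU"`.
#' @param response_min,response_max Integer bounds of the admissible raw
#'   response, `response_min < response_max`.
#' @param description Optional free-text item content.
#' @return An object of class `node_info`.
#' @export
node_info <- function(id, construct, response_min, response_max,
                      description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!(response_min < response_max)) {
    stop_clpn("node '%s': response_min (%s) must be < response_max (%s)",
              id, response_min, response_max, class = "clpn_validation_error")
  }
  structure(
    list(id = id, construct = as.character(construct),
         description = description,
         response_min = as.numeric(response_min),
         response_max = as.numeric(response_max)),
    class = "node_info"
  )
}

#' Default 19-node specification (7 GA + 12 IU items)
#'
#' The standard node set for a GAD-7 x IUSC-12 panel: seven generalized
#' anxiety symptoms (`GA1`-`GA7`) and twelve intolerance-of-uncertainty
#' elements (`IU1`-`IU12`). GA items are stored 1-4 by default (the common
#' 1-based storage of the 0-3 instrument scoring; pass `ga_base = 0` for
#' native 0-3 storage) and IU items 1-5.
#'
#' @param ga_base First stored category of the GA items (0 or 1).
#' @return List of [node_info()] objects.
#' @export
default_nodes <- function(ga_base = 1) {
  ga_desc <- c("Nervousness", "Uncontrollable worry", "Excessive worry",
               "Trouble relaxing", "Restlessness", "Irritability",
               "Feeling afraid")
  iu_desc <- c("Upset", "Frustration", "'Should think ahead' belief",
               "Catastrophizing belief", "Obsessive thoughts",
               "Aversive attitude", "'Should prepare everything' belief",
               "Live with discomfort", "Be paralysed", "Work with hindrance",
               "Stop actions", "Escape uncertainty")
  c(
    lapply(seq_len(7), function(i) {
      node_info(paste0("GA", i), "GA", ga_base, ga_base + 3, ga_desc[i])
    }),
    lapply(seq_len(12), function(i) {
      node_info(paste0("IU", i), "IU", 1, 5, iu_desc[i])
    })
  )
}

node_ids <- function(nodes) vapply(nodes, `[[`, character(1), "id")
node_constructs <- function(nodes) vapply(nodes, `[[`, character(1), "construct")

#' Construct a two-wave panel dataset
#'
#' Bundles wave-1 and wave-2 responses, covariates, and node metadata into a
#' validated container. Validation is total: every cell of both waves is
#' checked against its node's declared range, subject ids must be unique, and
#' missing values are a hard error (no imputation is offered; panels with
#' missingness must be handled upstream).
#'
#' @param subject_ids Character or integer vector of unique identifiers.
#' @param wave1,wave2 Numeric subjects x nodes matrices, same node order.
#' @param nodes List of [node_info()] objects, one per column.
#' @param covariates Numeric subjects x q matrix (may have 0 columns).
#'   Categorical covariates must arrive numerically encoded by the caller.
#' @param covariate_names Column names for `covariates`.
#' @return An object of class `panel_dataset`.
#' @export
panel_dataset <- function(subject_ids, wave1, wave2, nodes,
                          covariates = NULL, covariate_names = NULL) {
  ids <- node_ids(nodes)
  if (anyDuplicated(ids)) {
    stop_clpn("duplicated node ids: %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", "),
              class = "clpn_validation_error")
  }
  if (length(unique(node_constructs(nodes))) != 2L) {
    stop_clpn("a panel analysis requires exactly two constructs (got: %s)",
              paste(unique(node_constructs(nodes)), collapse = ", "),
              class = "clpn_validation_error")
  }
  wave1 <- as.matrix(wave1); wave2 <- as.matrix(wave2)
  n <- length(subject_ids)
  if (anyDuplicated(subject_ids)) {
    stop_clpn("duplicated subject ids: %s",
              paste(utils::head(unique(subject_ids[duplicated(subject_ids)]), 3),
                    collapse = ", "),
              class = "clpn_validation_error")
  }
  if (nrow(wave1) != n || nrow(wave2) != n) {
    stop_clpn("wave matrices must have one row per subject (n = %d)", n,
              class = "clpn_validation_error")
  }
  if (ncol(wave1) != length(nodes) || ncol(wave2) != length(nodes)) {
    stop_clpn("wave matrices must have one column per node (p = %d)",
              length(nodes), class = "clpn_validation_error")
  }
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n) {
    stop_clpn("covariates must have one row per subject",
              class = "clpn_validation_error")
  }
  covariate_names <- covariate_names %||% colnames(covariates) %||% character(0)
  if (ncol(covariates) != length(covariate_names)) {
    stop_clpn("covariate_names length (%d) != covariate columns (%d)",
              length(covariate_names), ncol(covariates),
              class = "clpn_validation_error")
  }
  colnames(wave1) <- colnames(wave2) <- ids
  if (ncol(covariates) > 0) colnames(covariates) <- covariate_names
  if (anyNA(wave1) || anyNA(wave2) || anyNA(covariates)) {
    stop_clpn("missing values are not allowed in a panel dataset",
              class = "clpn_validation_error")
  }
  for (w in c("wave1", "wave2")) {
    m <- if (w == "wave1") wave1 else wave2
    for (j in seq_along(nodes)) {
      bad <- which(m[, j] < nodes[[j]]$response_min |
                     m[, j] > nodes[[j]]$response_max)
      if (length(bad)) {
        stop_clpn(
          "out-of-range value %s for node %s (%s), subject %s (allowed [%s, %s])",
          format(m[bad[1], j]), ids[j], w, subject_ids[bad[1]],
          format(nodes[[j]]$response_min), format(nodes[[j]]$response_max),
          class = "clpn_validation_error")
      }
    }
  }
  structure(
    list(subject_ids = subject_ids, wave1 = wave1, wave2 = wave2,
         covariates = covariates, covariate_names = covariate_names,
         nodes = nodes),
    class = "panel_dataset"
  )
}

#' @export
print.panel_dataset <- function(x, ...) {
  tab <- table(node_constructs(x$nodes))
  cat(sprintf("Two-wave panel: %d subjects, %d nodes (%s), %d covariate(s)\n",
              length(x$subject_ids), length(x$nodes),
              paste(sprintf("%d %s", tab, names(tab)), collapse = " + "),
              ncol(x$covariates)))
  invisible(x)
}

#' @export
dim.panel_dataset <- function(x) c(length(x$subject_ids), length(x$nodes))

#' Load a two-wave panel from CSV
#'
#' Expects one row per subject and columns `subject_id`, `<node_id>_t1` and
#' `<node_id>_t2` for every node in `node_spec`, plus the named covariate
#' columns. Row order is preserved; node column order follows `node_spec`.
#'
#' @param path CSV file path (UTF-8, comma-delimited, header required).
#' @param node_spec List of [node_info()] objects.
#' @param covariate_names Character vector of covariate columns to read.
#' @return A [panel_dataset()].
#' @export
load_panel <- function(path, node_spec, covariate_names = character(0)) {
  if (!file.exists(path)) {
    stop_clpn("panel file not found: %s", path, class = "clpn_io_error")
  }
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- node_ids(node_spec)
  needed <- c("subject_id", paste0(ids, "_t1"), paste0(ids, "_t2"),
              covariate_names)
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_clpn("missing column(s): %s", paste(missing, collapse = ", "),
              class = "clpn_io_error")
  }
  panel_dataset(
    subject_ids = df$subject_id,
    wave1 = as.matrix(df[paste0(ids, "_t1")]),
    wave2 = as.matrix(df[paste0(ids, "_t2")]),
    nodes = node_spec,
    covariates = if (length(covariate_names)) {
      as.matrix(df[covariate_names])
    } else NULL,
    covariate_names = covariate_names
  )
}

#' Write a panel dataset to the documented CSV layout
#'
#' Inverse of [load_panel()]: writing then re-loading reproduces identical
#' matrices.
#'
#' @param dataset A [panel_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(dataset, path) {
  ids <- node_ids(dataset$nodes)
  df <- data.frame(subject_id = dataset$subject_ids, check.names = FALSE)
  w1 <- dataset$wave1; colnames(w1) <- paste0(ids, "_t1")
  w2 <- dataset$wave2; colnames(w2) <- paste0(ids, "_t2")
  df <- cbind(df, as.data.frame(w1), as.data.frame(w2))
  if (ncol(dataset$covariates) > 0) {
    df <- cbind(df, as.data.frame(dataset$covariates))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Native sum score for one construct
#'
#' Sums a construct's wave-1 (or wave-2) items on the instrument's native
#' 0-based scoring. Screening cutoffs (e.g. the GAD-7 clinical cutoff of 10)
#' are defined on native scoring; when items are stored with a shifted range
#' (e.g. 1-4 instead of 0-3) the per-item offset is derived from each node's
#' declared `response_min`, never hard-coded.
#'
#' @param dataset A [panel_dataset()].
#' @param construct Construct tag to sum over.
#' @param wave 1 or 2.
#' @param native_min Native minimum of the instrument's item scoring
#'   (0 for the GAD-7).
#' @return Numeric vector of per-subject native sum scores.
#' @export
construct_sum_score <- function(dataset, construct, wave = 1, native_min = 0) {
  sel <- node_constructs(dataset$nodes) == construct
  if (!any(sel)) {
    stop_clpn("no nodes in construct '%s'", construct,
              class = "clpn_validation_error")
  }
  m <- if (wave == 1) dataset$wave1 else dataset$wave2
  offsets <- vapply(dataset$nodes[sel], function(nd) {
    nd$response_min - native_min
  }, numeric(1))
  rowSums(sweep(m[, sel, drop = FALSE], 2, offsets))
}

#' @rdname construct_sum_score
#' @export
gad7_native_sum <- function(dataset, wave = 1) {
  construct_sum_score(dataset, "GA", wave = wave, native_min = 0)
}
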
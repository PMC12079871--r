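#' Analysis configuration
#'
#' Normalized configuration for the full CLPN pipeline. Defaults follow the
#' conventional settings for this analysis family: 10-fold cross-validated
#' LASSO, penalty chosen at minimum mean CV error, 5000 bootstrap resamples,
#' a case-dropping grid from 5% to 75%, the CS criterion r = 0.7 at 95%
#' confidence, and a subgroup screening cutoff of 10 (GAD-7 native scoring).
#'
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param lambda_grid_size Length of the log-spaced penalty grid.
#' @param lambda_rule `"min_cv_error"` (default) or `"one_se"`.
#' @param penalize_covariates Should covariate coefficients be L1-penalized
#'   like node predictors? Default `TRUE`.
#' @param threshold_rule Edge-retention threshold rule:
#'   `"mean_abs_nonzero_crosslagged"` (default; mean of absolute nonzero
#'   cross-lagged weights), `"mean_signed_crosslagged"` (signed mean of
#'   nonzero cross-lagged weights), or `"fixed"`.
#' @param fixed_threshold Required when `threshold_rule = "fixed"`.
#' @param n_boot Number of bootstrap resamples.
#' @param drop_proportions Strictly increasing case-dropping proportions in
#'   (0, 1).
#' @param cs_correlation Correlation criterion for the CS coefficient.
#' @param cs_confidence Confidence level for the CS coefficient.
#' @param subgroup_cutoff Native-scored sum cutoff for the subgroup split.
#' @param seed Root seed for all randomized stages.
#' @return An object of class `clpn_config`.
#' @export
clpn_config <- function(cv_folds = 10,
                        lambda_grid_size = 100,
                        lambda_rule = c("min_cv_error", "one_se"),
                        penalize_covariates = TRUE,
                        threshold_rule = c("mean_abs_nonzero_crosslagged",
                                           "mean_signed_crosslagged", "fixed"),
                        fixed_threshold = NULL,
                        n_boot = 5000,
                        drop_proportions = seq(0.05, 0.75, by = 0.05),
                        cs_correlation = 0.7,
                        cs_confidence = 0.95,
                        subgroup_cutoff = 10,
                        seed = 1L) {
  cfg <- list(
    cv_folds = as.integer(cv_folds),
    lambda_grid_size = as.integer(lambda_grid_size),
    lambda_rule = match.arg(lambda_rule),
    penalize_covariates = isTRUE(penalize_covariates),
    threshold_rule = match.arg(threshold_rule),
    fixed_threshold = fixed_threshold,
    n_boot = as.integer(n_boot),
    drop_proportions = as.numeric(drop_proportions),
    cs_correlation = as.numeric(cs_correlation),
    cs_confidence = as.numeric(cs_confidence),
    subgroup_cutoff = as.numeric(subgroup_cutoff),
    seed = as.integer(seed)
  )
  class(cfg) <- "clpn_config"
  validate_config(cfg)
}

#' Validate and normalize a configuration
#'
#' @param config A `clpn_config` or plain named list of the same fields
#'   (missing fields are filled with defaults).
#' @return A validated `clpn_config`.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "clpn_config")) {
    known <- names(formals(clpn_config))
    extra <- setdiff(names(config), known)
    if (length(extra)) {
      stop_clpn("unknown config field(s): %s", paste(extra, collapse = ", "),
                class = "clpn_config_error")
    }
    return(do.call(clpn_config, config))
  }
  cfg <- config
  if (cfg$cv_folds < 2L) {
    stop_clpn("cv_folds must be >= 2 (got %d)", cfg$cv_folds,
              class = "clpn_config_error")
  }
  if (cfg$lambda_grid_size < 2L) {
    stop_clpn("lambda_grid_size must be >= 2", class = "clpn_config_error")
  }
  dp <- cfg$drop_proportions
  if (length(dp) == 0L || any(dp <= 0) || any(dp >= 1) ||
      any(diff(dp) <= 0)) {
    stop_clpn("drop_proportions must be strictly increasing within (0, 1)",
              class = "clpn_config_error")
  }
  if (!(cfg$cs_correlation > 0 && cfg$cs_correlation < 1)) {
    stop_clpn("cs_correlation must lie in (0, 1)", class = "clpn_config_error")
  }
  if (cfg$threshold_rule == "fixed" &&
      (is.null(cfg$fixed_threshold) || !is.finite(cfg$fixed_threshold))) {
    stop_clpn("threshold_rule = 'fixed' requires a finite fixed_threshold",
              class = "clpn_config_error")
  }
  if (cfg$n_boot < 0L) {
    stop_clpn("n_boot must be >= 0", class = "clpn_config_error")
  }
  cfg
}

#' Read a configuration from YAML or JSON
#'
#' Keys are the argument names of [clpn_config()]; missing keys take the
#' defaults.
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return A validated `clpn_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_clpn("config file not found: %s", path, class = "clpn_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop_clpn("unsupported config format: .%s", ext, class = "clpn_io_error")
  )
  validate_config(raw)
}

#' @export
print.clpn_config <- function(x, ...) {
  cat("CLPN analysis configuration\n")
  cat(sprintf("  LASSO: %d-fold CV, %d-point grid, rule = %s\n",
              x$cv_folds, x$lambda_grid_size, x$lambda_rule))
  cat(sprintf("  threshold rule: %s%s\n", x$threshold_rule,
              if (x$threshold_rule == "fixed") {
                sprintf(" (%g)", x$fixed_threshold)
              } else ""))
  cat(sprintf("  bootstraps: %d; drop grid: %s\n", x$n_boot,
              paste(format(x$drop_proportions), collapse = ", ")))
  cat(sprintf("  CS criterion: r >= %g at %g%% confidence; cutoff: %g; seed: %d\n",
              x$cs_correlation, 100 * x$cs_confidence, x$subgroup_cutoff,
              x$seed))
  invisible(x)
}
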
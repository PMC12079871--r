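#' Cross-validated LASSO regression for one target node
#'
#' Fits the penalized least-squares problem
#' \deqn{\min_\beta \frac{1}{2n}\|y - \beta_0 - X\beta\|_2^2 +
#'   \lambda \sum_k m_k |\beta_k|}
#' where `m` is a 0/1 penalty mask (covariates may be left unpenalized).
#' Predictor columns are standardized internally to zero mean and unit
#' sample variance, and coefficients are reported on that standardized
#' scale, which is what makes node-wise edge weights comparable across
#' predictors. The solver is \pkg{glmnet}; the lambda passed to it is
#' pre-scaled by `sum(mask)/ncol(X)` to undo glmnet's internal rescaling of
#' penalty factors, so the objective above holds exactly as written.
#'
#' The penalty grid is log-spaced over four orders of magnitude downward
#' from `lambda_max`, the smallest penalty at which every penalized
#' coefficient is zero (computed from the correlation of each penalized
#' predictor with the residual of `y` on the unpenalized block). With
#' `lambda = NULL` the penalty is chosen by K-fold cross-validation
#' (minimum mean CV error, or the one-standard-error rule); a numeric
#' `lambda` skips CV and solves at that fixed penalty.
#'
#' @param y Numeric response vector.
#' @param x Numeric predictor matrix, `nrow(x) == length(y) >= folds`.
#' @param folds Number of CV folds.
#' @param lambda Optional fixed penalty (skips cross-validation).
#' @param grid_size Number of grid points.
#' @param lambda_rule `"min_cv_error"` or `"one_se"`.
#' @param penalize_mask 0/1 vector, one per column of `x`; default all 1.
#' @param foldid Optional explicit fold assignment (length n, values in
#'   `1:folds`); overrides `seed`-based assignment.
#' @param seed Seed for fold assignment when `foldid` is absent.
#' @param target_id Optional label carried into the result.
#' @return An object of class `node_fit`: `coefficients` (named, on the
#'   standardized-predictor scale; dropped zero-variance columns appear with
#'   coefficient 0), `intercept`, `selected_penalty`, `cv_curve` (data.frame
#'   `lambda`, `cv_error`; `NULL` for fixed-lambda fits), `r_squared_full`,
#'   `lambda_grid`, `target_id`.
#' @export
fit_node_lasso <- function(y, x, folds = 10, lambda = NULL,
                           grid_size = 100,
                           lambda_rule = c("min_cv_error", "one_se"),
                           penalize_mask = NULL, foldid = NULL,
                           seed = NULL, target_id = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  x <- as.matrix(x)
  n <- length(y)
  if (nrow(x) != n) {
    stop_clpn("nrow(x) != length(y)", class = "clpn_validation_error")
  }
  if (is.null(lambda) && folds > n) {
    stop_clpn("folds (%d) exceeds sample size (%d)", folds, n,
              class = "clpn_validation_error")
  }
  pnames <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  mask <- penalize_mask %||% rep(1, ncol(x))
  if (length(mask) != ncol(x)) {
    stop_clpn("penalize_mask length mismatch", class = "clpn_validation_error")
  }

  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sprintf("dropping zero-variance predictor(s): %s",
                    paste(pnames[!keep], collapse = ", ")))
  }
  xs <- scale(x[, keep, drop = FALSE])
  mask_k <- mask[keep]
  p <- ncol(xs)
  if (p == 0) stop_clpn("no usable predictors", class = "clpn_validation_error")
  if (sum(mask_k) == 0) {
    stop_clpn("at least one predictor must be penalized",
              class = "clpn_validation_error")
  }

  # lambda_max: smallest penalty zeroing all penalized coefficients, from the
  # KKT conditions after partialling out the unpenalized block.
  resid0 <- if (any(mask_k == 0)) {
    stats::lm.fit(cbind(1, xs[, mask_k == 0, drop = FALSE]), y)$residuals
  } else {
    y - mean(y)
  }
  lam_max <- max(abs(crossprod(xs[, mask_k > 0, drop = FALSE], resid0)) / n)
  if (lam_max <= 0) lam_max <- 1e-3
  grid <- exp(seq(log(lam_max), log(lam_max * 1e-4), length.out = grid_size))

  adjust <- sum(mask_k) / p  # undo glmnet's penalty-factor rescaling

  if (!is.null(lambda)) {
    lam_seq <- sort(unique(c(grid[grid > lambda], lambda)), decreasing = TRUE)
    if (length(lam_seq) < 3) {
      # glmnet's coef() needs a short path to interpolate over; the exact
      # refit below still solves at `lambda` itself
      lam_seq <- sort(unique(c(max(lambda, lam_max) * c(4, 2), lambda)),
                      decreasing = TRUE)
    }
    fit <- glmnet::glmnet(xs, y, family = "gaussian", standardize = FALSE,
                          intercept = TRUE, penalty.factor = mask_k,
                          lambda = lam_seq * adjust, thresh = 1e-12)
    sel <- lambda
    cf <- as.numeric(stats::coef(fit, s = lambda * adjust, exact = TRUE,
                                 x = xs, y = y, penalty.factor = mask_k))
    cv_curve <- NULL
  } else {
    # explicit K-fold CV around the glmnet path: fold-wise mean squared
    # prediction error on a fixed grid (leaner than cv.glmnet, and the fold
    # assignment is fully caller-controlled)
    fid <- foldid %||% with_seed(seed, sample(rep(seq_len(folds),
                                                  length.out = n)))
    lam_g <- grid * adjust
    fold_mse <- matrix(NA_real_, folds, length(grid))
    for (k in seq_len(folds)) {
      hold <- fid == k
      fit_k <- glmnet::glmnet(xs[!hold, , drop = FALSE], y[!hold],
                              family = "gaussian", standardize = FALSE,
                              intercept = TRUE, penalty.factor = mask_k,
                              lambda = lam_g, thresh = 1e-10)
      nl <- length(fit_k$lambda)
      pred <- xs[hold, , drop = FALSE] %*% fit_k$beta
      pred <- sweep(as.matrix(pred), 2, fit_k$a0, `+`)
      fold_mse[k, seq_len(nl)] <- colMeans((y[hold] - pred)^2)
    }
    cvm <- colMeans(fold_mse)
    cvsd <- apply(fold_mse, 2, stats::sd) / sqrt(folds)
    usable <- which(!is.na(cvm))
    i_min <- usable[which.min(cvm[usable])]
    i_sel <- if (lambda_rule == "min_cv_error") {
      i_min
    } else {
      min(usable[cvm[usable] <= cvm[i_min] + cvsd[i_min]])
    }
    sel <- grid[i_sel]
    fit <- glmnet::glmnet(xs, y, family = "gaussian", standardize = FALSE,
                          intercept = TRUE, penalty.factor = mask_k,
                          lambda = lam_g, thresh = 1e-10)
    i_sel <- min(i_sel, length(fit$lambda))
    sel <- grid[i_sel]
    cf <- c(fit$a0[i_sel], as.numeric(fit$beta[, i_sel]))
    cv_curve <- data.frame(lambda = grid, cv_error = cvm)
  }

  beta <- numeric(length(pnames))
  names(beta) <- pnames
  beta[keep] <- cf[-1]
  fitted <- cf[1] + xs %*% cf[-1]
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)

  structure(
    list(target_id = target_id, coefficients = beta, intercept = cf[1],
         selected_penalty = sel, cv_curve = cv_curve,
         r_squared_full = max(0, min(1, r2)), lambda_grid = grid,
         dropped = pnames[!keep]),
    class = "node_fit"
  )
}

# Fold assignment that is deterministic given (subject ids, seed) and
# invariant under joint row permutation of the dataset: the seeded shuffle is
# applied to the id-sorted subject order, then split into contiguous folds.
stable_foldid <- function(subject_ids, folds, seed) {
  n <- length(subject_ids)
  ord <- order(as.character(subject_ids))
  shuffled <- with_seed(seed, ord[sample(n)])
  sizes <- rep(n %/% folds, folds) + c(rep(1, n %% folds),
                                       rep(0, folds - n %% folds))
  fid <- integer(n)
  fid[shuffled] <- rep(seq_len(folds), times = sizes)
  fid
}
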
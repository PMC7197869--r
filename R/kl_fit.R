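#' Median-split joint feature distribution
#'
#' Maps each observation (row of a feature matrix) to the binary pattern of
#' indicators `feature > reference median`, over a chosen subset of features,
#' and returns the probability of each of the `2^n` joint bins. The reference
#' medians always come from the experimental-side dataset: model feature sets
#' are binned against the data's medians, never their own.
#'
#' @param features Numeric matrix or data frame of feature values (rows =
#'   observations; must contain the columns named in `subset`).
#' @param reference_medians Named numeric vector of per-feature medians.
#' @param subset Character vector of feature names (the subset R).
#' @return Numeric vector of length `2^length(subset)` summing to 1; bin
#'   index is the little-endian bit pattern of the per-feature indicators.
#' @export
median_split_joint <- function(features, reference_medians, subset) {
  if (!nrow(features)) stop("invalid: empty dataset")
  stopifnot(all(subset %in% colnames(features)),
            all(subset %in% names(reference_medians)))
  x <- as.matrix(features[, subset, drop = FALSE])
  above <- sweep(x, 2, reference_medians[subset], ">")
  idx <- as.integer(above %*% 2^(seq_along(subset) - 1)) + 1L
  tabulate(idx, nbins = 2^length(subset)) / nrow(x)
}

#' Kullback-Leibler distance between binned joint distributions
#'
#' \eqn{K = \sum_b P_D(b) \ln(P_D(b) / (P_M(b) + \epsilon))} over the joint
#' bins, with \eqn{0 \ln(0/x) := 0}. The regularizer \eqn{\epsilon} is added
#' to the model side only, so empty model bins give a large but finite
#' contribution.
#'
#' @param p_data Data-side bin probabilities.
#' @param p_model Model-side bin probabilities (same binning).
#' @param eps Regularizer (default 1e-7).
#' @return Scalar KL distance.
#' @export
kl_distance <- function(p_data, p_model, eps = 1e-7) {
  if (length(p_data) != length(p_model))
    stop("invalid: mismatched bin counts (different subsets?)")
  nz <- p_data > 0
  sum(p_data[nz] * log(p_data[nz] / (p_model[nz] + eps)))
}

#' Soft-minimum parameter estimate over a model grid
#'
#' Converts the KL distances of all grid models into normalized weights
#' \eqn{\alpha_m = K_m^{-\beta} / \sum_m K_m^{-\beta}} (a soft minimum:
#' the smallest distances dominate) and returns the weighted average
#' \eqn{x = \sum_m x_m \alpha_m} and weighted standard error
#' \eqn{\sigma^2 = \sum_m (x_m - x)^2 \alpha_m} of a model parameter.
#' KL values below `floor` (including the tiny negatives the \eqn{\epsilon}
#' regularizer can produce) are clipped to `floor` first.
#'
#' @param k_values KL distances, one per grid model.
#' @param x_values Parameter values of the grid models.
#' @param beta Soft-minimum exponent (default 3).
#' @param floor Lower clip for KL values (default 1e-6).
#' @return List with `estimate`, `se`, and the `weights` used.
#' @export
subset_estimate <- function(k_values, x_values, beta = 3, floor = 1e-6) {
  stopifnot(length(k_values) == length(x_values))
  k <- pmax(k_values, floor)
  w <- k^(-beta)
  w <- w / sum(w)
  est <- sum(x_values * w)
  list(estimate = est, se = sqrt(sum((x_values - est)^2 * w)), weights = w)
}

#' Fit network parameters to a feature dataset by KL matching
#'
#' The estimator draws `n_subsets` random subsets of `n_feat` of the 15
#' features (without replacement within a subset). For each subset it bins
#' the data and every library model against the data's feature medians,
#' computes the KL distance of each model from the data, turns the distances
#' into soft-minimum weights over the grid, and forms a subset-level estimate
#' of each parameter with its weighted standard error. Subset estimates are
#' then combined with inverse-error weights
#' \eqn{\phi_R = \sigma_R^{-1} / \sum_r \sigma_r^{-1}} into the final
#' estimate and its weighted standard error. One weight set per subset is
#' shared by both parameters.
#'
#' @param data_features Data frame of feature vectors (the experimental-side
#'   dataset), columns as in [feature_names()].
#' @param library A model library: list with `grid` (data frame with `g_E`,
#'   `g_I`) and `features` (list of feature data frames, one per grid row).
#' @param n_feat Features per subset (default 7).
#' @param n_subsets Number of random subsets (default 30).
#' @param beta Soft-minimum exponent (default 3).
#' @param eps KL regularizer (default 1e-7).
#' @param seed Integer seed for the subset draws.
#' @param min_obs Minimum number of observations required (default 10).
#' @return A `param_estimate`: `gE`, `gI`, `se_gE`, `se_gI`, the per-subset
#'   intermediates, and `kl_grid`, the matrix of log mean KL distances
#'   (subset-averaged) over the grid.
#' @export
fit_dataset <- function(data_features, library, n_feat = 7, n_subsets = 30,
                        beta = 3, eps = 1e-7, seed = 1, min_obs = 10) {
  if (nrow(data_features) < min_obs)
    stop(sprintf("dataset too small: %d observations (< %d)",
                 nrow(data_features), min_obs))
  feats <- feature_names()
  med <- vapply(data_features[, feats], stats::median, 0)
  n_models <- nrow(library$grid)
  set.seed(seed)
  subsets <- replicate(n_subsets, sample(feats, n_feat), simplify = FALSE)
  k_mat <- matrix(NA_real_, n_models, n_subsets)  # KL per model x subset
  est <- array(NA_real_, c(n_subsets, 2, 2),
               dimnames = list(NULL, c("g_E", "g_I"), c("estimate", "se")))
  for (r in seq_len(n_subsets)) {
    subs <- subsets[[r]]
    p_d <- median_split_joint(data_features, med, subs)
    for (m in seq_len(n_models)) {
      p_m <- median_split_joint(library$features[[m]], med, subs)
      k_mat[m, r] <- kl_distance(p_d, p_m, eps)
    }
    for (par in c("g_E", "g_I")) {
      e <- subset_estimate(k_mat[, r], library$grid[[par]], beta)
      est[r, par, ] <- c(e$estimate, e$se)
    }
  }
  out <- list(subsets = subsets, k_mat = k_mat, per_subset = est,
              grid = library$grid, beta = beta, eps = eps, seed = seed)
  for (par in c("g_E", "g_I")) {
    se <- pmax(est[, par, "se"], 1e-12)   # a zero-spread axis gets equal weights
    phi <- (1 / se) / sum(1 / se)
    x <- sum(est[, par, "estimate"] * phi)
    out[[if (par == "g_E") "gE" else "gI"]] <- x
    out[[if (par == "g_E") "se_gE" else "se_gI"]] <-
      sqrt(sum((x - est[, par, "estimate"])^2 * phi))
    out[[if (par == "g_E") "phi_gE" else "phi_gI"]] <- phi
  }
  out$kl_grid <- log(pmax(rowMeans(k_mat), 1e-6))
  class(out) <- "param_estimate"
  out
}

#' @export
print.param_estimate <- function(x, ...) {
  cat(sprintf("gE* = %.2f (se %.2f),  gI* = %.2f (se %.2f)  [%d models, %d subsets]\n",
              x$gE, x$se_gE, x$gI, x$se_gI, nrow(x$grid), length(x$subsets)))
  invisible(x)
}

#' Straight-line fit with errors in both coordinates
#'
#' Minimizes the effective-variance chi-square
#' \eqn{\chi^2 = \sum_i (y_i - a - b x_i)^2 / (\sigma_{y,i}^2 + b^2
#' \sigma_{x,i}^2)}, iterating weighted least squares with weights recomputed
#' from the current slope until convergence. The slope standard error comes
#' from the curvature of the chi-square at the minimum (the usual weighted
#' least-squares expression with the converged weights), and the p-value from
#' a two-tailed t-test of slope / SE with n - 2 degrees of freedom. With
#' vanishing x-errors the fit coincides with weighted ordinary least squares.
#'
#' @param x,y Coordinates.
#' @param sx,sy Per-point standard errors (scalars are recycled).
#' @param max_iter,tol Iteration controls.
#' @return List with `slope`, `intercept`, `se_slope`, `p_value`, `df`.
#' @export
eiv_regression <- function(x, y, sx = 0, sy = 1, max_iter = 50, tol = 1e-10) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  sx <- rep_len(sx, n); sy <- rep_len(sy, n)
  if (stats::var(x) == 0) stop("singular: all x identical")
  sy <- pmax(sy, 1e-12)
  b <- stats::coef(stats::lm.wfit(cbind(1, x), y, w = 1 / sy^2))[2]
  a <- NA_real_
  for (it in seq_len(max_iter)) {
    w <- 1 / (sy^2 + b^2 * sx^2)
    fit <- stats::lm.wfit(cbind(1, x), y, w = w)
    b_new <- stats::coef(fit)[2]
    a <- stats::coef(fit)[1]
    if (abs(b_new - b) < tol * (abs(b) + tol)) { b <- b_new; break }
    b <- b_new
  }
  w <- 1 / (sy^2 + b^2 * sx^2)
  xbar <- sum(w * x) / sum(w)
  se_b <- sqrt(1 / sum(w * (x - xbar)^2))
  tval <- b / se_b
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(slope = unname(b), intercept = unname(a), se_slope = se_b,
       p_value = p, df = n - 2)
}

#' Parameter-recovery experiment on a simulated grid
#'
#' Validates the estimator end to end with the model as its own ground
#' truth: every grid simulation is split into two non-overlapping halves;
#' the first halves play the role of experimental datasets, the second
#' halves form the model library. Each pseudo-experimental dataset is fitted
#' against the library, and the recovered (gE*, gI*) are tabulated against
#' the true grid values, together with a per-g_E regression of gE* on gI*
#' (slopes near zero indicate the two estimates are not confounded).
#'
#' @param halves A list as returned by [library_split_halves()]: `grid` plus
#'   `pseudo_experimental` and `pseudo_model` feature-table lists.
#' @param n_feat,n_subsets,beta,seed Passed to [fit_dataset()].
#' @return List with `table` (data frame: g_E, g_I, gE_hat, gI_hat, se_gE,
#'   se_gI) and `slopes` (per-g_E regression of gE* on gI*).
#' @export
recovery_experiment <- function(halves, n_feat = 7, n_subsets = 30, beta = 3,
                                seed = 1) {
  grid <- halves$grid
  lib <- list(grid = grid, features = halves$pseudo_model)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fit <- fit_dataset(halves$pseudo_experimental[[i]], lib,
                       n_feat = n_feat, n_subsets = n_subsets, beta = beta,
                       seed = seed + i)
    rows[[i]] <- data.frame(g_E = grid$g_E[i], g_I = grid$g_I[i],
                            gE_hat = fit$gE, gI_hat = fit$gI,
                            se_gE = fit$se_gE, se_gI = fit$se_gI)
  }
  tab <- do.call(rbind, rows)
  slopes <- lapply(split(tab, tab$g_E), function(d) {
    if (nrow(d) < 3) return(NULL)
    fit <- eiv_regression(d$gI_hat, d$gE_hat, sx = d$se_gI, sy = d$se_gE)
    data.frame(g_E = d$g_E[1], slope = fit$slope, se_slope = fit$se_slope,
               p_value = fit$p_value)
  })
  list(table = tab, slopes = do.call(rbind, slopes))
}
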
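#' Default penalty grid
#'
#' Candidate scalar ridge penalties: zero plus `n_points` log-spaced values
#' between `lower * dbar` and `upper * dbar`, where `dbar` is the mean
#' diagonal of the unpenalized covariance estimate -- a scale-aware anchor,
#' so the grid adapts to the magnitude of the log-abundances.
#'
#' @param data a filtered [sc_dataset()].
#' @param null_model grid for the null-model covariance estimator?
#' @param n_points number of positive candidates.
#' @param lower,upper multiples of `dbar` bounding the positive candidates.
#' @return increasing numeric vector of candidates, starting at 0.
#' @export
sc_lambda_grid <- function(data, null_model = FALSE, n_points = 25,
                           lower = 1e-3, upper = 1e2) {
  assert_sc_dataset(data)
  mu <- estimate_mu(data, null_model)
  mu_mat <- if (null_model) matrix(mu, data$n, data$p, byrow = TRUE)
            else mu[as.integer(data$groups), , drop = FALSE]
  Z <- sc_zmat(data)
  Zc <- (Z - mu_mat) * data$Y
  dbar <- mean(colSums(Zc^2) / colSums(data$Y))
  # guard against (numerically) zero residual variance: floating-point dust
  # from centering constant columns must not collapse the scale anchor
  floor_ <- 1e-12 * (1 + mean(Z[data$Y == 1]^2))
  if (!is.finite(dbar) || dbar <= floor_) dbar <- 1
  c(0, exp(seq(log(lower * dbar), log(upper * dbar), length.out = n_points)))
}

#' Positive definiteness of the penalized covariance estimate
#'
#' A penalty belongs to the feasible set when the full penalized covariance
#' estimate is numerically positive definite: smallest eigenvalue greater
#' than `tol` times the largest (a relative, scale-free criterion).
#'
#' @inheritParams sc_lambda_grid
#' @param lambda nonnegative scalar or length-`p` vector.
#' @param tol relative eigenvalue tolerance.
#' @return logical flag.
#' @export
sc_is_feasible <- function(lambda, data, null_model = FALSE, tol = 1e-10) {
  assert_sc_dataset(data)
  mu <- estimate_mu(data, null_model)
  sig <- estimate_sigma(data, mu, lambda, null_model)
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  max(ev) > 0 && min(ev) > tol * max(ev)
}

#' Information criterion for penalty selection
#'
#' \deqn{M(\lambda) = -2\,\ell(\hat\theta_\lambda) +
#'   \left[\log n + \tfrac12 \log p\right]
#'   \sum_k \sum_i tr\!\left((\hat\Sigma^\lambda)_{V_{ik}}^{-1}\right),}
#' where \eqn{\ell} is the *unpenalized* log-likelihood evaluated at the
#' penalized closed-form estimates and the trace sum is the model
#' complexity measure (trace of the Fisher information of the weighted
#' regression reformulation).  `p` is the retained dimension of `data`.
#' Empty supports contribute zero to the trace sum.
#'
#' @inheritParams sc_is_feasible
#' @return scalar criterion value (smaller is better).
#' @export
sc_ic <- function(lambda, data, null_model = FALSE) {
  assert_sc_dataset(data)
  if (!sc_is_feasible(lambda, data, null_model))
    stop_feasible("`lambda` is outside the feasible set (penalized covariance estimate not positive definite)")
  params <- sc_fit(data, lambda, null_model)
  ll <- sc_loglik(params, data)
  trsum <- 0
  for (i in seq_len(data$n)) {
    v <- which(data$Y[i, ] == 1)
    if (!length(v)) next
    R <- chol(params$sigma[v, v, drop = FALSE])
    trsum <- trsum + sum(diag(chol2inv(R)))
  }
  -2 * ll + (log(data$n) + 0.5 * log(data$p)) * trsum
}

#' Select the ridge penalty by information-criterion minimization
#'
#' Scans a grid of scalar candidates, discards those for which the
#' penalized covariance estimate is not positive definite, and returns the
#' feasible candidate minimizing the information criterion [sc_ic()].
#' Ties are broken toward the smaller penalty (less bias).
#'
#' @inheritParams sc_is_feasible
#' @param grid increasing vector of nonnegative candidates; defaults to
#'   [sc_lambda_grid()].
#' @return An object of class `"sc_lambda_selection"`: list with `lambda`
#'   (the selected value), `ic` (its criterion value), `loglik`, and
#'   `grid`, a data frame with one row per candidate (`lambda`, `feasible`,
#'   `ic`) for diagnostics.
#' @export
sc_select_lambda <- function(data, grid = NULL, null_model = FALSE) {
  assert_sc_dataset(data)
  if (is.null(grid)) grid <- sc_lambda_grid(data, null_model)
  if (!is.numeric(grid) || length(grid) < 1L || any(grid < 0) || anyNA(grid))
    stop_config("`grid` must contain at least one nonnegative candidate")
  grid <- sort(grid)
  # preconditions of the closed forms: pairwise support, and per-group
  # presences under the alternative (errors from estimate_mu otherwise)
  if (any(crossprod(data$Y) == 0))
    stop_degenerate("some variable pairs are never co-observed; run sc_filter() first")
  invisible(estimate_mu(data, null_model))

  ev <- scman_eval_grid_cpp(sc_zmat(data), data$Y,
                            as.integer(data$groups) - 1L, data$K,
                            null_model, grid)
  if (ev$best < 1L)
    stop_feasible("no candidate in the grid yields a positive definite covariance estimate; extend the grid upward")
  structure(list(
    lambda = grid[ev$best],
    ic = ev$ic[ev$best],
    loglik = ev$ll[ev$best],
    null_model = null_model,
    grid = data.frame(lambda = grid, feasible = ev$feasible, ic = ev$ic)
  ), class = "sc_lambda_selection")
}

#' @export
print.sc_lambda_selection <- function(x, ...) {
  cat(sprintf("Penalty selection (%s model): lambda = %g (IC = %.4f)\n",
              if (x$null_model) "null" else "alternative", x$lambda, x$ic))
  cat(sprintf("%d of %d grid candidates feasible\n",
              sum(x$grid$feasible), nrow(x$grid)))
  invisible(x)
}
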
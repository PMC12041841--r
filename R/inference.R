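#' Likelihood-ratio-type statistic
#'
#' \deqn{D_{\lambda,\lambda_0} = -2\left[\ell_0(\hat\pi_0, \hat\mu_0,
#'   \hat\Sigma_0^{\lambda_0}) - \ell(\hat\pi, \hat\mu,
#'   \hat\Sigma^{\lambda})\right],}
#' the drop in *unpenalized* log-likelihood between the pooled (null) and
#' group-specific (alternative) closed-form fits, each computed at its own
#' penalized covariance estimate.  With complete data and
#' `lambda = lambda0 = 0` this is the classical Gaussian MANOVA LRT.  When
#' the two penalties differ, `D` can be negative; the permutation null
#' calibrates the test regardless.  Setting `penalized_ratio = TRUE`
#' contrasts the penalized log-likelihoods instead (a sensitivity
#' analysis, not the default definition).
#'
#' @param data a filtered [sc_dataset()] with `K >= 2` groups.
#' @param lambda,lambda0 penalties for the alternative and null covariance
#'   estimates (scalars or length-`p` vectors); both must be feasible.
#' @param penalized_ratio contrast penalized rather than unpenalized
#'   log-likelihoods.
#' @return scalar statistic.
#' @export
sc_lrt_stat <- function(data, lambda, lambda0 = lambda,
                        penalized_ratio = FALSE) {
  assert_sc_dataset(data)
  if (data$K < 2L)
    stop_config("the test requires at least two groups")
  fit1 <- sc_fit(data, lambda, null_model = FALSE)
  fit0 <- sc_fit(data, lambda0, null_model = TRUE)
  if (penalized_ratio) {
    -2 * (sc_penalized_loglik(fit0, data) - sc_penalized_loglik(fit1, data))
  } else {
    -2 * (sc_loglik(fit0, data) - sc_loglik(fit1, data))
  }
}

#' Regularized MANOVA permutation test for semicontinuous data
#'
#' Tests whether `K` groups of semicontinuous observations share both the
#' presence-pattern distribution and the conditional means of the
#' log-abundances.  The pipeline is: pairwise-support filtering, masking of
#' variables absent from some group, information-criterion selection of the
#' ridge penalties under both hypotheses, the likelihood-ratio-type
#' statistic [sc_lrt_stat()], and a group-label permutation null.  By
#' default (`reselect = TRUE`) the penalties are re-selected on every
#' permuted dataset, so the extra variability of the data-driven penalty
#' choice is propagated into the null distribution; `reselect = FALSE`
#' reuses the observed penalties for speed.
#'
#' Penalty selection is continuous by default: the positive-definiteness
#' boundary is located by bisection and the criterion is minimized by
#' golden section on the log scale (with a final comparison against zero
#' penalty when that is feasible).  Supplying `lambda_grid`/`lambda0_grid`
#' switches to an argmin scan over those candidates instead.  The
#' continuous search matters under permutation: with a coarse grid the
#' selected penalties of the two models snap between candidates and
#' desynchronize across permutations, adding noise of several
#' log-likelihood units to the statistic -- enough to swamp the group
#' signal when `p` is large relative to `n`.
#'
#' @param X numeric matrix, data frame, or an [sc_dataset()].
#' @param groups group labels (ignored when `X` is already an
#'   `sc_dataset`).
#' @param B number of label permutations.
#' @param seed optional integer seed for the permutation stream.
#' @param lambda_grid,lambda0_grid optional candidate penalties for the
#'   alternative and null model; supplying either switches that model's
#'   selection from the continuous search to an argmin scan over the given
#'   candidates.  The search bounds/candidates are computed once from the
#'   observed (filtered and masked) data and stay fixed across
#'   permutations; only the selection is re-done.
#' @param reselect re-select the penalties on each permuted dataset.
#' @param p_value `"add_one"` (default): \eqn{(1 + \#\{D_b \ge
#'   D_{obs}\})/(B+1)}, guaranteeing validity and `p >= 1/(B+1)`;
#'   `"strict"`: the plain proportion \eqn{\#\{D_b \ge D_{obs}\}/B} of
#'   resamples at least as extreme as the observed statistic.
#' @param penalized_ratio see [sc_lrt_stat()].
#' @param keep_perm_stats store the permuted statistics in the result.
#' @return An object of class `"scmanova"`: list with `statistic`,
#'   `p_value`, `lambda_hat`, `lambda0_hat`, `p_star`, `removed` (data
#'   frame of dropped variables with reasons), `B`, `seed`,
#'   `perm_statistics` (if kept), `perm_failures`, and a `config` echo.
#'
#' @examples
#' d <- sc_simulate(sc_scenario(K = 2, nk = 5, p = 8, pi1 = 0.2), seed = 1)
#' scmanova(d, B = 99, seed = 2)
#' @export
scmanova <- function(X, groups = NULL, B = 1000, seed = NULL,
                     lambda_grid = NULL, lambda0_grid = NULL,
                     reselect = TRUE,
                     p_value = c("add_one", "strict"),
                     penalized_ratio = FALSE,
                     keep_perm_stats = TRUE) {
  p_value <- match.arg(p_value)
  if (!is.numeric(B) || length(B) != 1L || B < 1)
    stop_config("`B` must be a positive integer")
  B <- as.integer(B)
  data <- if (inherits(X, "sc_dataset")) X else sc_dataset(X, groups)
  if (data$K < 2L)
    stop_config("the test requires at least two groups")

  flt <- sc_filter(data)
  fdata <- flt$data
  removed <- flt$report$removed

  # variables absent from some group: group means undefined, masked for both
  # fits so the two likelihoods stay comparable
  keep <- group_present_cols(fdata)
  if (length(keep) < 2L)
    stop_degenerate("fewer than 2 variables are present in every group")
  if (length(keep) < fdata$p) {
    dropped <- setdiff(seq_len(fdata$p), keep)
    removed <- rbind(removed, data.frame(
      index = NA_integer_,
      name = fdata$var_names[dropped],
      reason = "absent in a group",
      stringsAsFactors = FALSE))
  }
  mdata <- sc_subset_cols(fdata, keep)

  # an explicitly supplied grid switches from the continuous search to an
  # argmin scan over those candidates; otherwise the default grid only
  # provides the upper search bound (its maximum, 100 * mean diagonal)
  continuous <- is.null(lambda_grid) && is.null(lambda0_grid)
  if (is.null(lambda_grid)) lambda_grid <- sc_lambda_grid(mdata, FALSE)
  if (is.null(lambda0_grid)) lambda0_grid <- sc_lambda_grid(mdata, TRUE)
  lambda_grid <- sort(lambda_grid)
  lambda0_grid <- sort(lambda0_grid)

  Z <- sc_zmat(fdata)
  Yn <- fdata$Y
  glab <- as.integer(fdata$groups) - 1L

  obs <- scman_pipeline_cpp(Z, Yn, glab, fdata$K, lambda_grid, lambda0_grid,
                            continuous, penalized_ratio)
  if (obs$status == 1L)
    stop_degenerate("fewer than 2 variables are present in every group")
  if (obs$status %in% c(2L, 3L))
    stop_feasible(sprintf(
      "no feasible penalty candidate for the %s model; extend the grid upward",
      if (obs$status == 2L) "alternative" else "null"))

  if (!is.null(seed)) set.seed(seed)
  n <- fdata$n
  perms <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
  glab1 <- glab + 1L
  if (!any(matrix(glab1[perms], n, B) != glab1)) {
    warning("all sampled permutations leave the group labels unchanged; p-value is 1")
    Db <- rep(obs$D, B)
    perm_status <- rep(0L, B)
  } else {
    pg <- if (reselect) lambda_grid else obs$lambda
    pg0 <- if (reselect) lambda0_grid else obs$lambda0
    pr <- scman_perm_cpp(Z, Yn, glab, fdata$K, perms, pg, pg0,
                         continuous && reselect, penalized_ratio)
    Db <- pr$D
    perm_status <- pr$status
  }
  failures <- sum(perm_status != 0L)
  if (failures > 0L) {
    warning(sprintf(
      "%d of %d permuted fits were degenerate; their statistics count as larger than the observed one",
      failures, B))
    Db[perm_status != 0L] <- Inf
  }

  # ties count as at-least-as-extreme in both modes (conservative)
  pv <- if (p_value == "add_one") (1 + sum(Db >= obs$D)) / (B + 1)
        else sum(Db >= obs$D) / B

  structure(list(
    statistic = obs$D,
    p_value = pv,
    p_value_mode = p_value,
    lambda_hat = obs$lambda,
    lambda0_hat = obs$lambda0,
    p_star = obs$p_star,
    removed = removed,
    B = B,
    seed = seed,
    n = fdata$n,
    K = fdata$K,
    perm_statistics = if (keep_perm_stats) Db else NULL,
    perm_failures = failures,
    config = list(B = B, seed = seed, reselect = reselect,
                  p_value = p_value, penalized_ratio = penalized_ratio,
                  lambda_search = if (continuous) "continuous" else "grid",
                  lambda_grid = lambda_grid, lambda0_grid = lambda0_grid),
    call = match.call()
  ), class = "scmanova")
}

#' @export
print.scmanova <- function(x, ...) {
  cat("Regularized MANOVA test for semicontinuous data\n\n")
  cat(sprintf("  D = %.4f, p-value = %.4g (%s, B = %d)\n",
              x$statistic, x$p_value,
              if (x$p_value_mode == "add_one") "add-one" else "strict",
              x$B))
  cat(sprintf("  lambda = %g (alternative), lambda0 = %g (null)\n",
              x$lambda_hat, x$lambda0_hat))
  cat(sprintf("  retained dimension p* = %d (%d variable%s removed)\n",
              x$p_star, nrow(x$removed),
              if (nrow(x$removed) == 1L) "" else "s"))
  if (x$perm_failures > 0L)
    cat(sprintf("  note: %d degenerate permuted fits counted conservatively\n",
                x$perm_failures))
  invisible(x)
}
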
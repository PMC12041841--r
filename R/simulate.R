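#' Simulation scenario for level/power studies
#'
#' One cell of the factorial design used to study the test: `K` balanced
#' groups of size `nk`, dimension `p`, compound-symmetric unit-variance
#' covariance with off-diagonal `rho` for the Gaussian log-abundances,
#' group means shifted linearly by `c1` (group-`k` mean components
#' `c1 * (k-1)/(K-1)`, group 1 at zero) and marginal zero probabilities
#' shifted linearly by `c2` (`pi_jk = pi1 + c2 * (k-1)/(K-1)`, constant
#' over variables).  `c1 = c2 = 0` puts the scenario under the null
#' hypothesis, so the rejection rate estimates the observed level.
#'
#' @param K number of groups (>= 2).
#' @param nk common per-group sample size.
#' @param p number of variables.
#' @param rho common off-diagonal covariance; must keep the
#'   compound-symmetric matrix positive definite (`-1/(p-1) < rho < 1`).
#' @param c1 mean-shift amplitude.
#' @param c2 zero-probability shift amplitude; every `pi_jk` must stay
#'   below 1.
#' @param pi1 marginal zero probability in group 1, in `[0, 1)`.
#' @param alpha nominal level used by [sc_power()].
#' @param B permutations per test.
#' @param R number of replicates.
#' @return An object of class `"sc_scenario"`.
#' @export
sc_scenario <- function(K = 2, nk = 5, p = 50, rho = 0, c1 = 0, c2 = 0,
                        pi1 = 0.2, alpha = 0.05, B = 1000, R = 1000) {
  if (!is.numeric(K) || K < 2 || K != round(K))
    stop_config("`K` must be an integer >= 2 (group shifts are undefined otherwise)")
  if (!is.numeric(nk) || nk < 1 || nk != round(nk))
    stop_config("`nk` must be a positive integer")
  if (!is.numeric(p) || p < 2 || p != round(p))
    stop_config("`p` must be an integer >= 2")
  if (!is.numeric(rho) || rho >= 1 || rho <= max(-1, -1 / (p - 1)))
    stop_config(sprintf(
      "`rho` must lie in (%.4g, 1) for a positive definite compound-symmetric matrix",
      max(-1, -1 / (p - 1))))
  if (!is.numeric(pi1) || pi1 < 0 || pi1 >= 1)
    stop_config("`pi1` must lie in [0, 1)")
  pik <- pi1 + c2 * (seq_len(K) - 1) / (K - 1)
  if (any(pik >= 1))
    stop_config(sprintf(
      "zero probability reaches %.3g >= 1 in group %d; decrease `c2` or `pi1`",
      max(pik), which.max(pik)))
  if (any(pik < 0))
    stop_config("negative zero probability; increase `pi1` or `c2`")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_config("`alpha` must lie in (0, 1)")
  if (!is.numeric(B) || B < 1) stop_config("`B` must be >= 1")
  if (!is.numeric(R) || R < 1) stop_config("`R` must be >= 1")
  structure(list(
    K = as.integer(K), nk = as.integer(nk), p = as.integer(p),
    rho = rho, c1 = c1, c2 = c2, pi1 = pi1,
    pik = pik, muk = c1 * (seq_len(K) - 1) / (K - 1),
    alpha = alpha, B = as.integer(B), R = as.integer(R)
  ), class = "sc_scenario")
}

#' @export
print.sc_scenario <- function(x, ...) {
  cat(sprintf(
    "Scenario: K = %d, nk = %d, p = %d, rho = %g, c1 = %g, c2 = %g, pi1 = %g\n",
    x$K, x$nk, x$p, x$rho, x$c1, x$c2, x$pi1))
  cat(sprintf("  alpha = %g, B = %d permutations, R = %d replicates\n",
              x$alpha, x$B, x$R))
  invisible(x)
}

#' Draw one semicontinuous dataset from a scenario
#'
#' For each group `k`, draws log-abundances from a `p`-variate Gaussian
#' with mean components `c1 * (k-1)/(K-1)`, unit variances and constant
#' covariance `rho`, independently masks each entry with probability
#' `pi_jk` (the presence indicators are independent of the Gaussian draw
#' and of each other), and returns `X = exp(Z) * Y`.  Masking a complete
#' Gaussian draw yields the correct conditional law of the observed
#' sub-vectors by marginalization.
#'
#' @param scenario an [sc_scenario()].
#' @param seed optional integer seed.
#' @return an [sc_dataset()] with groups `g1, ..., gK`.
#' @export
sc_simulate <- function(scenario, seed = NULL) {
  if (!inherits(scenario, "sc_scenario"))
    stop_config("`scenario` must be created by sc_scenario()")
  if (!is.null(seed)) set.seed(seed)
  p <- scenario$p
  sigma <- matrix(scenario$rho, p, p)
  diag(sigma) <- 1
  cs <- chol(sigma)
  Xs <- vector("list", scenario$K)
  for (k in seq_len(scenario$K)) {
    Z <- matrix(rnorm(scenario$nk * p), scenario$nk, p) %*% cs +
      scenario$muk[k]
    pres <- matrix(rbinom(scenario$nk * p, 1, 1 - scenario$pik[k]),
                   scenario$nk, p)
    Xs[[k]] <- exp(Z) * pres
  }
  X <- do.call(rbind, Xs)
  colnames(X) <- paste0("v", seq_len(p))
  sc_dataset(X, rep(paste0("g", seq_len(scenario$K)), each = scenario$nk))
}

#' Rejection rate of the test over simulated replicates
#'
#' Runs the full test pipeline on `R` independent replicates of a scenario
#' and reports the fraction of permutation p-values at or below the
#' nominal level: the observed level when the scenario is under the null
#' (`c1 = c2 = 0`), the observed power otherwise.  Also records the mean
#' retained dimension and the mean selected penalties.  A master seed is
#' split into per-replicate substreams (one for the data draw, one for the
#' permutation stream) so results are reproducible.  Replicates whose
#' observed-data fit degenerates are caught, counted and excluded; the
#' rate refers to completed replicates.
#'
#' @param scenario an [sc_scenario()].
#' @param seed master seed.
#' @param reselect,p_value,penalized_ratio passed to [scmanova()].
#' @param progress emit a progress message every 25 replicates.
#' @return An object of class `"sc_power"`: `rate`, `R_completed`,
#'   `failures`, per-replicate vectors (`p_values`, `p_star`, `lambda`,
#'   `lambda0`), their means, and the scenario.
#' @export
sc_power <- function(scenario, seed = NULL, reselect = TRUE,
                     p_value = "add_one", penalized_ratio = FALSE,
                     progress = FALSE) {
  if (!inherits(scenario, "sc_scenario"))
    stop_config("`scenario` must be created by sc_scenario()")
  if (!is.null(seed)) set.seed(seed)
  R <- scenario$R
  seeds <- matrix(sample.int(.Machine$integer.max, 2L * R), R, 2L)
  pv <- ps <- l1 <- l0 <- rep(NA_real_, R)
  failures <- 0L
  perm_failures <- 0L
  for (r in seq_len(R)) {
    d <- sc_simulate(scenario, seed = seeds[r, 1L])
    # degenerate permuted fits are already counted in the result; the
    # per-replicate warning would only repeat that R times
    res <- tryCatch(
      suppressWarnings(
        scmanova(d, B = scenario$B, seed = seeds[r, 2L],
                 reselect = reselect, p_value = p_value,
                 penalized_ratio = penalized_ratio,
                 keep_perm_stats = FALSE)),
      scman_degenerate_error = function(e) e,
      scman_no_feasible_error = function(e) e)
    if (inherits(res, "condition")) {
      failures <- failures + 1L
    } else {
      pv[r] <- res$p_value
      ps[r] <- res$p_star
      l1[r] <- res$lambda_hat
      l0[r] <- res$lambda0_hat
      perm_failures <- perm_failures + res$perm_failures
    }
    if (progress && r %% 25L == 0L)
      message(sprintf("replicate %d/%d (running rate %.3f)",
                      r, R, mean(pv[seq_len(r)] <= scenario$alpha,
                                 na.rm = TRUE)))
  }
  done <- !is.na(pv)
  structure(list(
    scenario = scenario,
    rate = mean(pv[done] <= scenario$alpha),
    R_completed = sum(done),
    failures = failures,
    perm_failures = perm_failures,
    p_values = pv, p_star = ps, lambda = l1, lambda0 = l0,
    mean_p_star = mean(ps[done]),
    mean_lambda = mean(l1[done]),
    mean_lambda0 = mean(l0[done]),
    seed = seed
  ), class = "sc_power")
}

#' @export
print.sc_power <- function(x, ...) {
  s <- x$scenario
  cat(sprintf(
    "Rejection rate %.3f at alpha = %g (%d/%d replicates completed)\n",
    x$rate, s$alpha, x$R_completed, s$R))
  cat(sprintf(
    "  K=%d nk=%d p=%d rho=%g c1=%g c2=%g pi1=%g | mean p* = %.1f, mean lambda = %.3g, mean lambda0 = %.3g\n",
    s$K, s$nk, s$p, s$rho, s$c1, s$c2, s$pi1,
    x$mean_p_star, x$mean_lambda, x$mean_lambda0))
  if (x$failures > 0L)
    cat(sprintf("  %d replicate(s) failed with degenerate data\n", x$failures))
  invisible(x)
}
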
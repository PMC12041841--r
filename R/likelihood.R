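#' Unpenalized log-likelihood of the two-part model
#'
#' Sum over observations of the log configuration probability of the
#' observed presence pattern plus the Gaussian log-density of the observed
#' log-abundance sub-vector under the corresponding sub-mean and
#' sub-covariance.  An all-absent observation contributes only
#' \eqn{\log \pi(0)}.  The Bernoulli term uses the probability of the
#' observation's specific configuration, \eqn{\pi(s)}, not the probability
#' of seeing some pattern with `s` presences.  The ridge penalty is *not*
#' included; see [sc_penalized_loglik()].
#'
#' @param params an `"sc_params"` object ([sc_fit()]).
#' @param data an [sc_dataset()] with dimensions matching `params`.
#' @return scalar log-likelihood; `-Inf` (with a warning) if some observed
#'   configuration has zero probability under `params`.
#' @export
sc_loglik <- function(params, data) {
  assert_sc_dataset(data)
  if (params$p != data$p)
    stop_data(sprintf("params were fit for p = %d but data has p = %d",
                      params$p, data$p))
  p <- data$p
  glab <- as.integer(data$groups)
  ll <- 0
  for (i in seq_len(data$n)) {
    s <- data$nik[i]
    pi_i <- unname(if (params$null_model) params$pi[s + 1L]
                   else params$pi[glab[i], s + 1L])
    if (pi_i <= 0) {
      warning(sprintf(
        "observation %d has a configuration with zero estimated probability; log-likelihood is -Inf", i))
      return(-Inf)
    }
    ll <- ll + log(pi_i)
    if (s == 0L) next
    v <- which(data$Y[i, ] == 1)
    mu_v <- if (params$null_model) params$mu[v]
            else params$mu[glab[i], v]
    x <- data$Xlog[i, v] - mu_v
    R <- chol(params$sigma[v, v, drop = FALSE])
    u <- backsolve(R, x, transpose = TRUE)
    ll <- ll - 0.5 * (s * log(2 * pi) + 2 * sum(log(diag(R))) + sum(u^2))
  }
  ll
}

#' Ridge penalty term
#'
#' \eqn{P(\lambda, \Sigma) = \sum_k \sum_i tr(\Lambda_{V_{ik}}
#' \Sigma_{V_{ik}}^{-1})}, the sum over observations of the trace of the
#' penalty matrix times the inverse covariance restricted to the
#' observation's support.  Empty supports contribute zero.
#'
#' @param lambda nonnegative scalar or length-`p` vector.
#' @param sigma symmetric positive definite `p x p` matrix (all submatrices
#'   indexed by observed supports must be invertible).
#' @param data an [sc_dataset()].
#' @return scalar penalty value.
#' @export
sc_penalty <- function(lambda, sigma, data) {
  assert_sc_dataset(data)
  lambda <- check_lambda(lambda, data$p)
  if (all(lambda == 0)) return(0)
  pen <- 0
  for (i in seq_len(data$n)) {
    v <- which(data$Y[i, ] == 1)
    if (!length(v)) next
    Sv <- sigma[v, v, drop = FALSE]
    R <- tryCatch(chol(Sv), error = function(e) NULL)
    if (is.null(R))
      scman_error(sprintf(
        "covariance submatrix for presence pattern of observation %d (support {%s}) is singular",
        i, paste(v, collapse = ",")), "scman_singular_error")
    pen <- pen + sum(lambda[v] * diag(chol2inv(R)))
  }
  pen
}

#' Penalized log-likelihood
#'
#' \eqn{\ell_\lambda = \ell - P(\lambda, \Sigma)/2}: the penalized
#' objective underlying the closed-form estimates of [sc_fit()].  On
#' complete data with `lambda = 0` those estimates maximize it exactly;
#' under masking they are the available-case generalization, which trades
#' exact maximization for a closed form.
#'
#' @inheritParams sc_loglik
#' @return scalar.
#' @export
sc_penalized_loglik <- function(params, data) {
  sc_loglik(params, data) -
    0.5 * sc_penalty(params$lambda, params$sigma, data)
}
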
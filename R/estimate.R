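#' Configuration-probability estimates for the exchangeable Bernoulli part
#'
#' Under exchangeability, all presence/absence configurations with the same
#' number `s` of present components share one probability
#' \eqn{\pi(s)}, so the \eqn{2^p - 1} Bernoulli parameters collapse to
#' `p + 1` per group (with one normalization constraint).  The penalized
#' maximum likelihood estimate is
#' \deqn{\hat\pi_k(s) = \frac{s!\,(p-s)!}{p!} \cdot
#'   \frac{\#\{i \in k : n_{ik} = s\}}{n_k},}
#' the empirical frequency of support size `s` divided by the number
#' \eqn{\binom{p}{s}} of configurations carrying it.  Under the null model
#' the frequency is pooled over all groups.
#'
#' @param data an [sc_dataset()].
#' @param null_model pool the groups (`TRUE`) or estimate per group
#'   (`FALSE`, default).
#' @return For the alternative, a `K x (p+1)` matrix with rows indexed by
#'   group and columns by `s = 0, ..., p`; for the null, a named vector of
#'   length `p + 1`.
#' @export
estimate_pi <- function(data, null_model = FALSE) {
  assert_sc_dataset(data)
  p <- data$p
  s_lev <- 0:p
  lch <- lchoose(p, s_lev)
  freq_to_pi <- function(counts, ntot) {
    fr <- counts / ntot
    ifelse(fr > 0, exp(log(fr) - lch), 0)
  }
  if (null_model) {
    counts <- tabulate(data$nik + 1L, nbins = p + 1L)
    out <- freq_to_pi(counts, data$n)
    names(out) <- s_lev
    return(out)
  }
  out <- t(vapply(levels(data$groups), function(g) {
    in_g <- data$groups == g
    freq_to_pi(tabulate(data$nik[in_g] + 1L, nbins = p + 1L), sum(in_g))
  }, numeric(p + 1L)))
  colnames(out) <- s_lev
  out
}

#' Observed-components mean of the log-abundances
#'
#' Mean of \eqn{\log X_{ij}} over the observations where variable `j` is
#' present, per group (alternative) or pooled (null).  Under the
#' alternative every retained variable must be present at least once in
#' every group, otherwise the group mean is undefined; [scmanova()] masks
#' such variables before fitting.
#'
#' @inheritParams estimate_pi
#' @return `K x p` matrix (alternative) or length-`p` vector (null).
#' @export
estimate_mu <- function(data, null_model = FALSE) {
  assert_sc_dataset(data)
  XY <- sc_zmat(data)
  if (null_model) {
    den <- colSums(data$Y)
    if (any(den == 0))
      stop_degenerate(sprintf(
        "variable(s) %s have no presences; run sc_filter() first",
        paste(data$var_names[den == 0], collapse = ", ")))
    return(colSums(XY) / den)
  }
  num <- rowsum(XY, data$groups)
  den <- rowsum(data$Y, data$groups)
  if (any(den == 0)) {
    bad <- which(den == 0, arr.ind = TRUE)[1L, ]
    stop_degenerate(sprintf(
      "variable '%s' has no presences in group '%s'; its group mean is undefined",
      data$var_names[bad[2L]], rownames(den)[bad[1L]]))
  }
  num / den
}

#' Ridge-penalized covariance estimate
#'
#' Closed-form ridge-penalized estimate of the common covariance matrix of
#' the log-abundances, of available-case type: each entry uses exactly the
#' observations where both variables are present.  Entry \eqn{(j_1, j_2)} is the
#' sum over groups and observations of the products of residuals on the
#' co-observed entries, plus the ridge term \eqn{\Lambda = diag(\lambda)}
#' on the diagonal, divided entry-wise by the co-observation counts:
#' \deqn{\hat\Sigma^\lambda = \frac{\sum_k \sum_i Y_{ik} Y_{ik}^\top \circ
#'   (\tilde X_{ik} - \hat\mu_k)(\tilde X_{ik} - \hat\mu_k)^\top + \Lambda}
#'   {\sum_k \sum_i Y_{ik} Y_{ik}^\top}.}
#' With `lambda = 0` this is the unpenalized maximum likelihood estimator.
#'
#' @inheritParams estimate_pi
#' @param mu group means as returned by [estimate_mu()] (matrix for the
#'   alternative, vector for the null).
#' @param lambda nonnegative penalty: a scalar (recycled) or a length-`p`
#'   vector.
#' @return symmetric `p x p` matrix.
#' @export
estimate_sigma <- function(data, mu, lambda = 0, null_model = FALSE) {
  assert_sc_dataset(data)
  p <- data$p
  lambda <- check_lambda(lambda, p)
  if (null_model) {
    mu_mat <- matrix(mu, nrow = data$n, ncol = p, byrow = TRUE)
  } else {
    mu_mat <- mu[as.integer(data$groups), , drop = FALSE]
  }
  Zc <- (sc_zmat(data) - mu_mat) * data$Y
  num <- crossprod(Zc) + diag(lambda, p)
  den <- crossprod(data$Y)
  if (any(den == 0))
    scman_error("zero co-observation count encountered; the pairwise-support filter contract was violated",
                "scman_internal_error")
  sig <- num / den
  dimnames(sig) <- list(data$var_names, data$var_names)
  (sig + t(sig)) / 2
}

check_lambda <- function(lambda, p) {
  if (!is.numeric(lambda) || anyNA(lambda))
    stop_config("`lambda` must be numeric and non-missing")
  if (length(lambda) == 1L) lambda <- rep(lambda, p)
  if (length(lambda) != p)
    stop_config(sprintf("`lambda` must have length 1 or %d", p))
  if (any(lambda < 0))
    stop_config("`lambda` must be nonnegative")
  lambda
}

#' Fit the two-part model at a fixed penalty
#'
#' Convenience wrapper computing all closed-form penalized estimates:
#' configuration probabilities, means and covariance.
#'
#' @inheritParams estimate_sigma
#' @return An object of class `"sc_params"`: list with `pi`, `mu`, `sigma`,
#'   `lambda` (length-`p` vector), `null_model`, `K`, `p`.
#' @export
sc_fit <- function(data, lambda = 0, null_model = FALSE) {
  assert_sc_dataset(data)
  lambda <- check_lambda(lambda, data$p)
  mu <- estimate_mu(data, null_model)
  structure(list(
    pi = estimate_pi(data, null_model),
    mu = mu,
    sigma = estimate_sigma(data, mu, lambda, null_model),
    lambda = lambda,
    null_model = null_model,
    K = data$K,
    p = data$p
  ), class = "sc_params")
}

#' Total number of free parameters of the two-part model
#'
#' `K*p` exchangeable Bernoulli parameters, `K*p` means and `p(p+1)/2`
#' covariance entries under the alternative; the null has one pooled group.
#'
#' @param params an `"sc_params"` object from [sc_fit()].
#' @return integer count.
#' @export
sc_n_params <- function(params) {
  K <- if (params$null_model) 1L else params$K
  p <- params$p
  2L * K * p + (p * (p + 1L)) %/% 2L
}

#' @export
print.sc_params <- function(x, ...) {
  cat(sprintf("Two-part model fit (%s): p = %d, K = %d, %d parameters\n",
              if (x$null_model) "null, pooled groups" else "alternative",
              x$p, x$K, sc_n_params(x)))
  cat(sprintf("Penalty lambda: %s\n",
              if (length(unique(x$lambda)) == 1L) format(x$lambda[1L])
              else paste0("vector [", format(min(x$lambda)), ", ",
                          format(max(x$lambda)), "]")))
  invisible(x)
}
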
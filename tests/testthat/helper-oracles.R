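# Independent reference computations used as oracles.  These deliberately
# avoid the package's code paths: plain loops, solve()/det() instead of
# Cholesky updates, and a general-purpose optimizer instead of closed forms.

# Random semicontinuous dataset with roughly `zero_frac` zeros, guaranteed to
# satisfy pairwise support and per-group presence (retries until it does).
rand_dataset <- function(n, p, K = 2, zero_frac = 0.3, mu_shift = 0) {
  repeat {
    g <- rep(paste0("g", seq_len(K)), length.out = n)
    Z <- matrix(rnorm(n * p), n, p)
    Z <- Z + mu_shift * (as.integer(factor(g)) - 1)
    Y <- matrix(rbinom(n * p, 1, 1 - zero_frac), n, p)
    X <- exp(Z) * Y
    ok <- all(crossprod(Y) > 0) &&
      all(rowsum(Y, g) > 0)
    if (ok) return(sc_dataset(X, g))
  }
}

# Reference unpenalized log-likelihood: per-row multivariate normal density
# via solve()/det() plus the configuration-probability term.
ref_loglik <- function(data, pi_tab, mu, sigma, null_model = FALSE) {
  glab <- as.integer(data$groups)
  ll <- 0
  for (i in seq_len(data$n)) {
    s <- sum(data$Y[i, ])
    pi_i <- if (null_model) pi_tab[s + 1] else pi_tab[glab[i], s + 1]
    if (pi_i <= 0) return(-Inf)
    ll <- ll + log(pi_i)
    if (s == 0) next
    v <- which(data$Y[i, ] == 1)
    mu_v <- if (null_model) mu[v] else mu[glab[i], v]
    x <- data$Xlog[i, v] - mu_v
    Sv <- sigma[v, v, drop = FALSE]
    ll <- ll - 0.5 * (s * log(2 * pi) +
                        determinant(Sv, logarithm = TRUE)$modulus +
                        drop(x %*% solve(Sv, x)))
  }
  as.numeric(ll)
}

# Reference penalty term: naive per-observation loop with explicit inversion.
ref_penalty <- function(lambda, sigma, data) {
  lambda <- rep(lambda, length.out = data$p)
  pen <- 0
  for (i in seq_len(data$n)) {
    v <- which(data$Y[i, ] == 1)
    if (!length(v)) next
    pen <- pen + sum(diag(diag(lambda[v], length(v)) %*%
                            solve(sigma[v, v, drop = FALSE])))
  }
  pen
}

# Reference information criterion: naive loop, explicit submatrix inverses.
ref_ic <- function(lambda, data, null_model = FALSE) {
  fit <- sc_fit(data, lambda, null_model)
  ll <- ref_loglik(data, fit$pi, fit$mu, fit$sigma, null_model)
  trsum <- 0
  for (i in seq_len(data$n)) {
    v <- which(data$Y[i, ] == 1)
    if (!length(v)) next
    trsum <- trsum + sum(diag(solve(fit$sigma[v, v, drop = FALSE])))
  }
  -2 * ll + (log(data$n) + 0.5 * log(data$p)) * trsum
}

# Penalized log-likelihood maximized numerically over (mu, Sigma) with the
# configuration probabilities held at their closed form (they enter the
# objective additively and do not interact with the Gaussian part).
# Returns the best objective value found.
optim_penalized <- function(data, lambda, null_model = FALSE,
                            maxit = 500, start_mu = NULL, start_L = NULL) {
  p <- data$p
  G <- if (null_model) 1L else data$K
  pi_hat <- estimate_pi(data, null_model)
  ltri <- lower.tri(matrix(0, p, p))
  unpack <- function(theta) {
    mu <- matrix(theta[seq_len(G * p)], G, p)
    rest <- theta[-seq_len(G * p)]
    L <- diag(exp(rest[seq_len(p)]), p)
    L[ltri] <- rest[-seq_len(p)]
    list(mu = mu, sigma = L %*% t(L))
  }
  obj <- function(theta) {
    par <- unpack(theta)
    mu <- if (null_model) drop(par$mu) else par$mu
    val <- tryCatch(
      -(ref_loglik(data, pi_hat, mu, par$sigma, null_model) -
          0.5 * ref_penalty(lambda, par$sigma, data)),
      error = function(e) 1e10)   # singular candidate visited by the search
    if (!is.finite(val)) 1e10 else val
  }
  if (is.null(start_mu)) start_mu <- rep(0, G * p)
  if (is.null(start_L)) start_L <- c(rep(0, p), rep(0, sum(ltri)))
  fit <- stats::optim(c(start_mu, start_L), obj, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  list(value = -fit$value, par = unpack(fit$par), convergence = fit$convergence)
}

# Classical Gaussian MANOVA LRT from within-group vs total scatter matrices.
classical_manova_lrt <- function(X, groups) {
  g <- factor(groups)
  n <- nrow(X)
  Xc_within <- X - rowsum(X, g)[as.integer(g), ] / as.vector(table(g))[as.integer(g)]
  Xc_total <- sweep(X, 2, colMeans(X))
  S1 <- crossprod(Xc_within) / n
  S0 <- crossprod(Xc_total) / n
  as.numeric(n * (determinant(S0, logarithm = TRUE)$modulus -
                    determinant(S1, logarithm = TRUE)$modulus))
}

# Greedy pairwise-support rule re-executed independently on a 0/1 matrix;
# returns retained column indices.
ref_greedy_filter <- function(Y) {
  n <- nrow(Y)
  absent <- colSums(Y == 0)
  retained <- which(colSums(Y) > 0)
  repeat {
    if (length(retained) < 2) break
    co <- crossprod(Y[, retained, drop = FALSE])
    diag(co) <- 1
    bad <- which(co == 0, arr.ind = TRUE)
    if (!nrow(bad)) break
    cand <- retained[unique(c(bad[, 1], bad[, 2]))]
    worst <- cand[absent[cand] == max(absent[cand])]
    retained <- setdiff(retained, max(worst))
  }
  retained
}

three_se <- function(rate, R) 3 * sqrt(rate * (1 - rate) / R)
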
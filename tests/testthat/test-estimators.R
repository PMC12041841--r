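test_that("configuration probabilities follow the closed form", {
  # nk = 4, p = 3: two rows fully present, two rows with one presence
  X <- rbind(c(1, 1, 1),
             c(1, 1, 1),
             c(1, 0, 0),
             c(0, 1, 0),
             c(2, 2, 2))  # second group, fully present
  d <- sc_dataset(X, c("a", "a", "a", "a", "b"))
  pi_hat <- estimate_pi(d)
  expect_equal(pi_hat["a", "3"], 0.5)
  expect_equal(pi_hat["a", "1"], (1 / 3) * 0.5)
  expect_equal(pi_hat["b", "3"], 1)
  # multiplying by the number of configurations recovers the frequencies
  expect_equal(sum(choose(3, 0:3) * pi_hat["a", ]), 1)
})

test_that("configuration probabilities normalize for arbitrary data", {
  set.seed(5)
  for (rep in 1:10) {
    d <- rand_dataset(sample(6:14, 1), sample(3:6, 1),
                      zero_frac = runif(1, 0.1, 0.5))
    pi_a <- estimate_pi(d)
    pi_0 <- estimate_pi(d, null_model = TRUE)
    cfg <- choose(d$p, 0:d$p)
    for (k in seq_len(d$K))
      expect_equal(sum(cfg * pi_a[k, ]), 1, tolerance = 1e-12)
    expect_equal(sum(cfg * pi_0), 1, tolerance = 1e-12)
  }
})

test_that("means are observed-components-only averages", {
  X <- cbind(c(0, exp(1), exp(2)), c(1, 1, 1))
  d <- sc_dataset(X, rep("a", 3))
  mu <- estimate_mu(d)
  expect_equal(mu["a", 1], 1.5)          # (1 + 2) / 2, zero skipped
  expect_equal(mu["a", 2], 0)
  # pooled estimate on complete data is the plain column mean of logs
  set.seed(2)
  d2 <- rand_dataset(9, 4, zero_frac = 0)
  expect_equal(estimate_mu(d2, null_model = TRUE), colMeans(d2$Xlog),
               ignore_attr = TRUE)
  # masked data: agreement with a generic weighted mean
  d3 <- rand_dataset(12, 5, zero_frac = 0.3)
  mu3 <- estimate_mu(d3, null_model = TRUE)
  manual <- vapply(seq_len(5), function(j) {
    obs <- d3$Y[, j] == 1
    mean(d3$Xlog[obs, j])
  }, numeric(1))
  expect_equal(unname(mu3), manual)
})

test_that("group-absent variables make the alternative mean undefined", {
  X <- rbind(c(1, 2), c(3, 4), c(0, 1), c(0, 2))
  d <- sc_dataset(X, c("a", "a", "b", "b"))
  expect_error(estimate_mu(d), class = "scman_degenerate_error")
  expect_silent(estimate_mu(d, null_model = TRUE))
})

test_that("unpenalized covariance reduces to the n-divisor MLE on complete data", {
  set.seed(3)
  d <- rand_dataset(10, 4, K = 1, zero_frac = 0)
  mu <- estimate_mu(d)
  sig <- estimate_sigma(d, mu, lambda = 0)
  Xc <- sweep(d$Xlog, 2, colMeans(d$Xlog))
  expect_equal(sig, crossprod(Xc) / 10, ignore_attr = TRUE)
})

test_that("penalty adds lambda/m to each diagonal entry", {
  set.seed(4)
  d <- rand_dataset(8, 3, K = 1, zero_frac = 0.25)
  mu <- estimate_mu(d)
  s0 <- estimate_sigma(d, mu, lambda = 0)
  s2 <- estimate_sigma(d, mu, lambda = 2)
  m <- colSums(d$Y)
  expect_equal(diag(s2), diag(s0) + 2 / m, ignore_attr = TRUE)
  expect_equal(s2[lower.tri(s2)], s0[lower.tri(s0)])
  # single column observed m times: sigma_jj = (sum resid^2 + lambda) / m
  j <- 1
  obs <- d$Y[, j] == 1
  expect_equal(s2[j, j],
               unname((sum((d$Xlog[obs, j] - mu[1, j])^2) + 2) / m[j]))
})

test_that("diagonal grows strictly with each penalty component, off-diagonals fixed", {
  set.seed(6)
  d <- rand_dataset(9, 4, zero_frac = 0.2)
  mu <- estimate_mu(d)
  base <- estimate_sigma(d, mu, lambda = rep(1, 4))
  for (j in 1:4) {
    lam <- rep(1, 4); lam[j] <- 3
    s <- estimate_sigma(d, mu, lam)
    expect_gt(s[j, j], base[j, j])
    expect_equal(s[-j, -j], base[-j, -j])
  }
})

test_that("closed forms match a numerical optimizer on complete data", {
  # with no masking and no penalty the likelihood is the classical Gaussian
  # one, whose exact maximizer the closed forms must reproduce; BFGS from a
  # neutral start converges to the same point
  set.seed(8)
  d <- rand_dataset(12, 3, K = 2, zero_frac = 0)
  fit <- sc_fit(d, 0)
  opt <- optim_penalized(d, 0, maxit = 2000)
  expect_equal(unname(fit$mu), unname(opt$par$mu), tolerance = 1e-4)
  expect_equal(unname(fit$sigma), unname(opt$par$sigma), tolerance = 1e-3)
  expect_gte(sc_penalized_loglik(fit, d) + 1e-6, opt$value)
})

test_that("parameter count follows 2Kp + p(p+1)/2", {
  set.seed(9)
  d <- rand_dataset(8, 4, K = 2, zero_frac = 0.2)
  expect_equal(sc_n_params(sc_fit(d, 1)), 2 * 2 * 4 + 4 * 5 / 2)
  expect_equal(sc_n_params(sc_fit(d, 1, null_model = TRUE)), 2 * 4 + 4 * 5 / 2)
})
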
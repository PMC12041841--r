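test_that("byte-identical groups give a zero statistic", {
  set.seed(31)
  half <- exp(matrix(rnorm(12), 4, 3)) * matrix(rbinom(12, 1, 0.8), 4, 3)
  X <- rbind(half, half)
  d <- sc_dataset(X, rep(c("a", "b"), each = 4))
  expect_equal(sc_lrt_stat(d, lambda = 1, lambda0 = 1), 0, tolerance = 1e-10)
})

test_that("the statistic reduces to the classical MANOVA LRT on complete data", {
  set.seed(32)
  for (K in 2:3) {
    n <- 10 * K
    d <- rand_dataset(n, 3, K = K, zero_frac = 0, mu_shift = 0.5)
    D <- sc_lrt_stat(d, lambda = 0, lambda0 = 0)
    expect_gte(D, 0)
    expect_equal(D, classical_manova_lrt(d$Xlog, d$groups), tolerance = 1e-8)
  }
})

test_that("a mean shift increases the statistic", {
  set.seed(33)
  base <- exp(matrix(rnorm(30), 10, 3))
  g <- rep(c("a", "b"), each = 5)
  shifted <- base
  shifted[6:10, ] <- shifted[6:10, ] * exp(10)
  D0 <- sc_lrt_stat(sc_dataset(base, g), lambda = 0.5)
  D1 <- sc_lrt_stat(sc_dataset(shifted, g), lambda = 0.5)
  expect_gt(D1, D0)
})

test_that("the statistic is invariant to variable order", {
  set.seed(34)
  d <- rand_dataset(10, 4, zero_frac = 0.25)
  lam <- 0.5
  while (!sc_is_feasible(lam, d) || !sc_is_feasible(lam, d, TRUE))
    lam <- lam * 2
  perm <- c(3, 1, 4, 2)
  dperm <- sc_dataset(d$X[, perm], d$groups)
  expect_equal(sc_lrt_stat(d, lam, 2 * lam), sc_lrt_stat(dperm, lam, 2 * lam),
               tolerance = 1e-10)
})

test_that("the p-value is invariant to group relabeling", {
  set.seed(35)
  d <- rand_dataset(10, 4, zero_frac = 0.2)
  swapped <- sc_dataset(d$X, c("b", "a")[as.integer(d$groups)])
  grids <- list(g = sc_lambda_grid(d), g0 = sc_lambda_grid(d, TRUE))
  r1 <- scmanova(d, B = 60, seed = 7,
                 lambda_grid = grids$g, lambda0_grid = grids$g0)
  r2 <- scmanova(swapped, B = 60, seed = 7,
                 lambda_grid = grids$g, lambda0_grid = grids$g0)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("Monte-Carlo p-value agrees with exhaustive label enumeration", {
  # n = 6, K = 2 balanced: 20 possible label assignments; every column has
  # at least 4 presences so each assignment keeps all group means defined
  set.seed(36)
  repeat {
    Z <- matrix(rnorm(18, sd = 1), 6, 3)
    Y <- matrix(1, 6, 3)
    for (j in 1:3) Y[sample.int(6, sample(0:2, 1)), j] <- 0
    if (all(colSums(Y) >= 4) && all(crossprod(Y) > 0)) break
  }
  X <- exp(Z) * Y
  g_obs <- rep(c("a", "b"), each = 3)
  d_obs <- sc_dataset(X, g_obs)
  grid1 <- sc_lambda_grid(d_obs, FALSE)
  grid0 <- sc_lambda_grid(d_obs, TRUE)

  run_D <- function(labels) {
    d <- sc_dataset(X, labels)
    lam <- sc_select_lambda(d, grid = grid1)$lambda
    lam0 <- sc_select_lambda(d, grid = grid0, null_model = TRUE)$lambda
    sc_lrt_stat(d, lam, lam0)
  }
  D_obs <- run_D(g_obs)
  assignments <- utils::combn(6, 3)
  D_all <- apply(assignments, 2, function(idx) {
    labels <- rep("b", 6); labels[idx] <- "a"
    run_D(labels)
  })
  p_exact <- mean(D_all >= D_obs - 1e-12)

  B <- 4000
  res <- scmanova(d_obs, B = B, seed = 37,
                  lambda_grid = grid1, lambda0_grid = grid0)
  # add-one estimator targets (1 + B p) / (B + 1); compare within 3 MC SEs
  target <- (1 + B * p_exact) / (B + 1)
  expect_lt(abs(res$p_value - target), three_se(p_exact, B) + 1e-6)
})

test_that("identical rows across groups force p = 1 in both modes", {
  X <- matrix(rep(c(1.5, 2.0, 0, 3.0), each = 6), 6, 4)
  d <- sc_dataset(X, rep(c("a", "b"), each = 3))
  r_add <- scmanova(d, B = 30, seed = 1)
  r_strict <- scmanova(d, B = 30, seed = 1, p_value = "strict")
  expect_equal(r_add$p_value, 1)
  expect_equal(r_strict$p_value, 1)
  expect_equal(r_add$removed$reason, "never present")  # the all-zero column
})

test_that("the add-one p-value respects its lower bound", {
  set.seed(38)
  d <- rand_dataset(12, 4, zero_frac = 0.2, mu_shift = 8)
  res <- scmanova(d, B = 40, seed = 2)
  expect_gte(res$p_value, 1 / 41)
  expect_lte(res$p_value, 1)
})

test_that("permutation results are reproducible and B is validated", {
  set.seed(39)
  d <- rand_dataset(10, 4, zero_frac = 0.2)
  r1 <- scmanova(d, B = 50, seed = 11)
  r2 <- scmanova(d, B = 50, seed = 11)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$perm_statistics, r2$perm_statistics)
  expect_error(scmanova(d, B = 0), class = "scman_config_error")
})

test_that("reselect = FALSE reuses the observed penalties", {
  set.seed(40)
  d <- rand_dataset(10, 5, zero_frac = 0.25)
  r <- scmanova(d, B = 30, seed = 3, reselect = FALSE)
  expect_true(is.finite(r$statistic))
  expect_gte(r$p_value, 1 / 31)
})
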
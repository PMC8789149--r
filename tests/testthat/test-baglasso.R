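test_that("scatter matrix matches hand arithmetic and the loop oracle", {
  expect_equal(scatter_matrix(matrix(c(1, -1, 0, 0), 2, 2), center = FALSE),
               matrix(c(2, 0, 0, 0), 2, 2))
  const <- matrix(5, 4, 3)
  expect_equal(scatter_matrix(const, center = TRUE), matrix(0, 3, 3))
  set.seed(1)
  Y <- matrix(rnorm(60), 12, 5)
  expect_equal(scatter_matrix(Y, center = FALSE), oracle_scatter(Y))
  Yc <- sweep(Y, 2, colMeans(Y))
  expect_equal(scatter_matrix(Y, center = TRUE), oracle_scatter(Yc))
  expect_error(scatter_matrix(matrix(1, 1, 2), center = TRUE), "2 obs")
})

test_that("latent-scale draws have the inverse-Gaussian mean and survive zeros", {
  # with lambda = 1 and |theta| = 1 the reciprocal scale has mean 1
  theta <- matrix(c(1, 1, 1, 1), 2, 2)
  lam <- matrix(1, 2, 2)
  set.seed(42)
  draws <- replicate(1e5, 1 / sample_tau(theta, lam)[1, 2])
  expect_equal(mean(draws), 1, tolerance = 0.02)

  # zero entry: the clamp keeps the draw finite and positive
  theta0 <- diag(2)
  tau0 <- sample_tau(theta0, lam)
  expect_true(is.finite(tau0[1, 2]) && tau0[1, 2] > 0)

  set.seed(7)
  a <- sample_tau(theta, lam)
  set.seed(7)
  b <- sample_tau(theta, lam)
  expect_identical(a, b)
  expect_equal(a, t(a))
})

test_that("adaptive shrinkage draws match their gamma conditional mean", {
  r <- 1e-2; s <- 1e-6
  theta <- matrix(c(1, .5, .5, 1), 2, 2)
  lam <- matrix(1, 2, 2); diag(lam) <- 9
  set.seed(1)
  draws <- replicate(1e4, sample_lambda_adaptive(theta, lam, r, s)[1, 2])
  expect_equal(mean(draws), (r + 1) / (0.5 + s), tolerance = 0.03)
  # diagonal hyperparameters are never resampled
  out <- sample_lambda_adaptive(theta, lam, r, s)
  expect_equal(diag(out), c(9, 9))
})

test_that("shrinkage adapts: tiny entries are shrunk much harder than large", {
  p <- 3
  theta <- diag(p)
  theta[1, 2] <- theta[2, 1] <- 0.9
  theta[1, 3] <- theta[3, 1] <- 0.01
  lam <- matrix(1, p, p)
  set.seed(2)
  big <- numeric(2000); tiny <- numeric(2000)
  for (k in 1:2000) {
    l <- sample_lambda_adaptive(theta, lam)
    big[k] <- l[1, 2]; tiny[k] <- l[1, 3]
  }
  expect_gt(mean(tiny) / mean(big), 10)
})

test_that("single-lambda draw uses the printed shape and is monotone in ||Theta||_1", {
  set.seed(3)
  # Theta = I_2: shape r + p(p+1) = 7, rate s + ||I||_1/2 = 2, mean 3.5
  draws <- replicate(1e5, sample_lambda_single(diag(2), r = 1, s = 1))
  expect_equal(mean(draws), 3.5, tolerance = 0.02)
  draws_half <- replicate(1e4,
    sample_lambda_single(diag(2), r = 1, s = 1, shape_mode = "half"))
  expect_equal(mean(draws_half), 2, tolerance = 0.05)
  # doubling the entrywise norm lowers the conditional mean
  m1 <- mean(replicate(1e4, sample_lambda_single(diag(2), r = 1, s = 1)))
  m2 <- mean(replicate(1e4, sample_lambda_single(2 * diag(2), r = 1, s = 1)))
  expect_lt(m2, m1)
  set.seed(5); d1 <- sample_lambda_single(diag(3))
  set.seed(5); d2 <- sample_lambda_single(diag(3))
  expect_identical(d1, d2)
})

test_that("a column update preserves positive definiteness", {
  set.seed(4)
  p <- 6; n <- 40
  Y <- rggm(n, prec_structure("ar1", p))
  S <- scatter_matrix(Y)
  theta <- diag(p)
  tau <- matrix(1, p, p); diag(tau) <- 0
  lam <- matrix(1, p, p)
  for (j in seq_len(p)) {
    theta <- gibbs_update_column(theta, tau, lam, S, n, j)
    expect_no_error(chol(theta))
  }
})

test_that("sampler runs are bit-reproducible and rho_tilde is a correlation", {
  Y <- rggm(80, prec_structure("ar1", 4), seed = 10)
  f1 <- baglasso(Y, n_iter = 300, n_burnin = 100, seed = 77)
  f2 <- baglasso(Y, n_iter = 300, n_burnin = 100, seed = 77)
  expect_identical(f1$theta_hat, f2$theta_hat)
  expect_identical(f1$rho_tilde, f2$rho_tilde)
  expect_true(all(abs(f1$rho_tilde) <= 1))
  expect_equal(diag(f1$rho_tilde), rep(1, 4))
  expect_true(isSymmetric(f1$theta_hat, tol = 1e-12))
  expect_error(baglasso(Y, n_iter = 100, n_burnin = 100), "exceed")
  Ybad <- Y; Ybad[1, 1] <- NA
  expect_error(baglasso(Ybad), "non-finite")
})

test_that("posterior mean approaches the MLE precision at large n", {
  theta_true <- matrix(c(1, .4, .4, 1), 2, 2)
  Y <- rggm(2000, theta_true, seed = 11)
  fit <- baglasso(Y, n_iter = 2000, n_burnin = 500, seed = 12)
  mle <- solve(cov(Y) * (2000 - 1) / 2000)
  rel <- sqrt(sum((fit$theta_hat - mle)^2)) / sqrt(sum(mle^2))
  expect_lt(rel, 0.10)
})

test_that("partial correlations match the formula and the loop oracle", {
  expect_equal(partial_cor(matrix(c(2, 1, 1, 2), 2, 2))[1, 2], -0.5)
  expect_equal(partial_cor(diag(c(2, 3, 4))), diag(3))
  set.seed(13)
  A <- crossprod(matrix(rnorm(36), 6, 6)) + diag(6)
  expect_equal(partial_cor(A), oracle_partial_cor(A), tolerance = 1e-12)
  expect_error(partial_cor(diag(c(1, -1))), "positive")
})
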
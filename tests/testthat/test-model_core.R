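# Polar decomposition, model densities, the conditional-density oracle for
# the orthonormal coefficient matrix, and configuration guards.

test_that("polar factor is exact for orthonormal and scaled-orthonormal input", {
  set.seed(1)
  U <- qr.Q(qr(matrix(rnorm(12 * 3), 12, 3)))
  p <- polar_orthonormalize(U)
  expect_equal(p$Psi, U, tolerance = 1e-12)
  expect_equal(p$Pfac, diag(3), tolerance = 1e-12)

  p3 <- polar_orthonormalize(3 * U)
  expect_equal(p3$Psi, U, tolerance = 1e-12)
  expect_equal(p3$Pfac, 3 * diag(3), tolerance = 1e-12)
})

test_that("polar factor agrees with the SVD polar oracle on random matrices", {
  set.seed(99)
  for (r in 1:100) {
    Q <- sample(4:25, 1)
    K <- sample(1:min(4, Q), 1)
    X <- matrix(rnorm(Q * K), Q, K)
    p <- polar_orthonormalize(X)
    sv <- svd(X)
    expect_lt(max(abs(p$Psi - sv$u %*% t(sv$v))), 1e-8)
    expect_lt(max(abs(crossprod(p$Psi) - diag(K))), 1e-10)
    expect_lt(max(abs(p$Psi %*% p$Pfac - X)), 1e-8)
  }
})

test_that("polar decomposition reports rank deficiency", {
  X <- cbind(1:5, 2 * (1:5))
  expect_error(polar_orthonormalize(X), "rank deficient")
  p <- polar_orthonormalize(X, jitter = TRUE)
  expect_true(attr(p, "jittered"))
})

test_that("log-likelihood matches closed forms and a brute-force oracle", {
  b <- fix_basis(12)
  d <- fix_draw(N = 8, K = 2)
  B <- b$eval_matrix
  mu <- drop(B %*% d$w_mu)
  Theta <- d$Xi %*% t(B %*% d$Psi)
  Y0 <- sweep(Theta, 2, mu, `+`)

  # zero residuals at sigma2 = 1
  d1 <- d; d1$sigma2 <- 1
  expect_equal(fpca_loglik(d1, Y0, b), -(8 * 50 / 2) * log(2 * pi),
               tolerance = 1e-10)

  # doubling residuals lowers the log-likelihood by 3/2 sum(resid^2)
  set.seed(3)
  Eres <- matrix(rnorm(8 * 50), 8, 50)
  ll1 <- fpca_loglik(d1, Y0 + Eres, b)
  ll2 <- fpca_loglik(d1, Y0 + 2 * Eres, b)
  expect_equal(ll1 - ll2, 3 / 2 * sum(Eres^2), tolerance = 1e-8)

  # elementwise dnorm oracle on a small case
  set.seed(4)
  Y <- Y0 + matrix(rnorm(8 * 50, sd = sqrt(d$sigma2)), 8, 50)
  oracle <- sum(dnorm(Y, mean = sweep(Theta, 2, mu, `+`),
                      sd = sqrt(d$sigma2), log = TRUE))
  expect_equal(fpca_loglik(d, Y, b), oracle, tolerance = 1e-10)

  expect_error(fpca_loglik(modifyList(d, list(sigma2 = -1)), Y, b), "positive")
})

test_that("log-prior matches a term-by-term density oracle", {
  b <- fix_basis(12)
  pen <- fix_penalty(0.1)
  cfg <- fpca_config(K = 2, Q = 12, seed = 1)
  d <- fix_draw(N = 8, K = 2)
  b_h <- pen$trace / 2 + 0.01

  dinvg <- function(x, a, bb) a * log(bb) - lgamma(a) - (a + 1) * log(x) - bb / x
  oracle <- sum(dgamma(d$H, 0.01, rate = b_h, log = TRUE)) +
    dgamma(d$h_mu, 0.001, rate = 0.001, log = TRUE) +
    sum(dinvg(d$lambda, 0.001, 0.001)) +
    dinvg(d$sigma2, 0.001, 0.001) +
    12 / 2 * log(d$h_mu) - d$h_mu / 2 * drop(t(d$w_mu) %*% pen$P %*% d$w_mu) +
    sum(vapply(1:2, function(k) {
      12 / 2 * log(d$H[k]) -
        d$H[k] / 2 * drop(t(d$Psi[, k]) %*% pen$P %*% d$Psi[, k])
    }, numeric(1))) +
    sum(dnorm(d$X, log = TRUE)) +
    sum(dnorm(d$Xi, mean = 0, sd = rep(sqrt(d$lambda), each = 8), log = TRUE))
  expect_equal(fpca_logprior(d, pen, cfg), oracle, tolerance = 1e-10)

  # unit-entry latent matrix contributes the standard normal at 1
  # (absolute tolerance: the log-prior itself is of order b_h ~ 1e7, so a
  # difference of two evaluations carries that cancellation error)
  d2 <- d; d2$X <- matrix(1, 12, 2)
  delta <- fpca_logprior(d2, pen, cfg) - fpca_logprior(d, pen, cfg)
  expect_lt(abs(delta - (sum(dnorm(1, log = TRUE)) * 24 -
                           sum(dnorm(d$X, log = TRUE)))), 1e-6)
})

test_that("conditional density differences equal joint posterior differences", {
  b <- fix_basis(12)
  pen <- fix_penalty(0.1)
  cfg <- fpca_config(K = 2, Q = 12, seed = 1)
  d <- fix_draw(N = 8, K = 2, seed = 5)
  set.seed(6)
  Y <- matrix(rnorm(8 * 50, 2), 8, 50)

  joint <- function(dd) fpca_loglik(dd, Y, b) + fpca_logprior(dd, pen, cfg)
  cond <- function(Psi) psi_conditional_logdensity(Psi, d, Y, b, pen)

  # identity move
  expect_equal(cond(d$Psi) - cond(d$Psi), 0)

  # sign flip of one column
  d_flip <- d
  d_flip$Psi <- d$Psi %*% diag(c(-1, 1))
  expect_equal(cond(d_flip$Psi) - cond(d$Psi), joint(d_flip) - joint(d),
               tolerance = 1e-6)

  # 20 random Stiefel pairs
  set.seed(7)
  for (r in 1:20) {
    d_new <- d
    d_new$Psi <- polar_orthonormalize(matrix(rnorm(24), 12, 2))$Psi
    expect_equal(cond(d_new$Psi) - cond(d$Psi), joint(d_new) - joint(d),
                 tolerance = 1e-6)
  }

  expect_error(psi_conditional_logdensity(d$Psi * 2, d, Y, b, pen),
               "orthonormal")
})

test_that("likelihood flattens to the pure-noise value as sigma2 grows", {
  b <- fix_basis(12)
  d <- fix_draw(N = 8, K = 2)
  set.seed(8)
  Y <- matrix(rnorm(8 * 50), 8, 50)
  d$sigma2 <- 1e8
  ll <- fpca_loglik(d, Y, b)
  expect_equal(ll, -(8 * 50 / 2) * log(2 * pi * 1e8), tolerance = 1e-3)
})

test_that("configuration guards enforce dimensions and prior propriety", {
  expect_error(fpca_config(K = 15, Q = 12), "exceeds")
  expect_error(fpca_config(n_iter = 100, n_warmup = 100), "smaller")
  expect_error(fpca_config(prior = list(a_sigma = -1)), "> 0")
  expect_error(fpca_config(prior = list(bogus = 1)), "unknown")

  pen <- fix_penalty(0.1)
  # rate exactly at trace/2 violates the propriety condition
  expect_error(
    fpca_config(K = 2, Q = 12, prior = list(b_h = pen$trace / 2),
                penalty = pen),
    "improper")
  # strictly above the bound is accepted
  cfg <- fpca_config(K = 2, Q = 12, prior = list(b_h = pen$trace / 2 + 1),
                     penalty = pen)
  expect_s3_class(cfg, "bfpca_config")
})

test_that("the fitted model rejects invalid data", {
  g <- fix_grid(20)
  cfg <- fpca_config(K = 2, Q = 8, n_iter = 20, n_warmup = 10, n_chains = 1)
  Y <- matrix(rnorm(5 * 20), 5, 20)
  Yna <- Y; Yna[2, 3] <- NA
  expect_error(fit_fpca(Yna, g, cfg), "missing")
  expect_error(fit_fpca(Y[1, , drop = FALSE], g, cfg), "2 curves")
  expect_error(fit_fpca(Y[, 1:10], g, cfg), "grid")
})
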
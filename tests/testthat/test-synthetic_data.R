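# Shifted Legendre polynomials, built-in scenarios, and the simulators.

test_that("shifted Legendre polynomials match closed forms", {
  t <- seq(0, 1, length.out = 11)
  expect_equal(shifted_legendre(0, t), rep(1, 11))
  expect_equal(shifted_legendre(1, t), 2 * t - 1)
  expect_equal(shifted_legendre(2, t), 6 * t^2 - 6 * t + 1)
  expect_equal(shifted_legendre(3, t), 20 * t^3 - 30 * t^2 + 12 * t - 1)
  expect_equal(shifted_legendre(2, 0.5), -0.5)
  for (k in 0:5) expect_equal(shifted_legendre(k, 1), 1)
})

test_that("shifted Legendre polynomials are orthogonal with norm 1/(2k+1)", {
  g <- make_grid(200)
  for (k in 0:4) {
    fk <- shifted_legendre(k, g$points)
    expect_equal(sum(g$weights * fk^2), 1 / (2 * k + 1), tolerance = 1e-10)
    for (j in seq_len(k)) {
      fj <- shifted_legendre(j - 1, g$points)
      expect_lt(abs(sum(g$weights * fj * fk)), 1e-10)
    }
  }
})

test_that("the dense-CGM scenario has the stated truth", {
  s1 <- scenario_s1()
  expect_equal(s1$eigenvalues, c(2250, 450, 150))
  expect_equal(s1$sigma2, 4)
  expect_equal(s1$mean_fn(0.5), 150)  # 140 - 20 * f2(0.5) = 140 + 10

  g <- make_grid(500)
  phi2 <- s1$eigen_fns[[2]](g$points)
  expect_equal(sum(g$weights * phi2^2), 1, tolerance = 1e-10)
  # the normalizer is sqrt(84/31): int (f1 - 0.5 f3)^2 = 1/3 + 1/28 = 31/84
  expect_equal(s1$eigen_fns[[2]](1), sqrt(84 / 31) * 0.5, tolerance = 1e-12)

  # the mean loads only on phi_1 and phi_3: <mu, phi_1> = 140,
  # <mu, phi_3> = 4 sqrt(5), <mu, phi_2> = 0
  mu <- s1$mean_fn(g$points)
  ips <- vapply(s1$eigen_fns,
                function(f) sum(g$weights * mu * f(g$points)), numeric(1))
  expect_equal(ips, c(140, 0, 4 * sqrt(5)), tolerance = 1e-8)
})

test_that("the trigonometric scenario has the stated truth", {
  s2 <- scenario_s2()
  expect_equal(s2$eigenvalues, c(1, 0.5, 0.25))
  expect_equal(s2$sigma2, 0.35)
  g <- make_grid(500)
  expect_equal(sum(g$weights * s2$eigen_fns[[1]](g$points)^2), 1,
               tolerance = 1e-8)
  expect_lt(abs(sum(g$weights * s2$eigen_fns[[2]](g$points) *
                      s2$eigen_fns[[3]](g$points))), 1e-10)
  # pointwise variance of Y(0.25): 1*2 + 0.5*2 + 0.25*0 + 0.35
  v <- sum(s2$eigenvalues * vapply(s2$eigen_fns, function(f) f(0.25)^2,
                                   numeric(1))) + s2$sigma2
  expect_equal(v, 3.35, tolerance = 1e-10)
})

test_that("every built-in eigen-system is orthonormal on a dense quadrature", {
  gl <- make_grid(2000)
  for (spec in list(scenario_s1(), scenario_s2(), scenario_ml1(), scenario_ml2())) {
    Phi <- vapply(spec$eigen_fns, function(f) f(gl$points),
                  numeric(length(gl$points)))
    G <- crossprod(Phi, gl$weights * Phi)
    expect_lt(max(abs(G - diag(spec$K))), 1e-8)
  }
})

test_that("misread normalizing constants fail construction", {
  # the unnormalized combination f1 - 0.5 f3 is not unit norm
  expect_error(new_scenario(
    name = "bad",
    mean_fn = function(t) rep(0, length(t)),
    eigen_fns = list(function(t) shifted_legendre(1, t) - 0.5 * shifted_legendre(3, t)),
    eigenvalues = 1, sigma2 = 1), "orthonormal")
  # amplitude 2 instead of sqrt(2) is not unit norm either
  expect_error(new_scenario(
    name = "bad2",
    mean_fn = function(t) rep(0, length(t)),
    eigen_fns = list(function(t) 2 * sin(2 * pi * t)),
    eigenvalues = 1, sigma2 = 0.35), "orthonormal")
})

test_that("simulation is seed-deterministic and respects the generative model", {
  s1 <- scenario_s1()
  a <- simulate_scenario(s1, seed = 11)
  b <- simulate_scenario(s1, seed = 11)
  expect_identical(a$Y, b$Y)
  expect_identical(a$true_scores, b$true_scores)
  expect_equal(dim(a$Y), c(50, 50))
  expect_equal(a$grid$scheme, "gauss-legendre")

  # score variance matches the top eigenvalue at large N
  big <- simulate_scenario(s1, seed = 12, N = 10000)
  expect_equal(var(big$true_scores[, 1]), 2250, tolerance = 0.05 * 2250)

  # noiseless, scoreless limit returns the mean exactly
  s0 <- s1
  s0$sigma2 <- 1e-300
  s0$eigenvalues <- c(3e-300, 2e-300, 1e-300)
  sim0 <- simulate_scenario(new_scenario("limit", s0$mean_fn, s0$eigen_fns,
                                         s0$eigenvalues, s0$sigma2, N = 4, M = 20),
                            seed = 1)
  mu <- s1$mean_fn(sim0$grid$points)
  expect_equal(sim0$Y, matrix(mu, 4, 20, byrow = TRUE), tolerance = 1e-120)
})

test_that("noise-free curves reproduce the spec eigenvalues empirically", {
  s2 <- scenario_s2()
  s2$sigma2 <- 1e-12
  spec <- new_scenario("s2_nf", s2$mean_fn, s2$eigen_fns, s2$eigenvalues,
                       s2$sigma2, N = 5000, M = 50)
  sim <- simulate_scenario(spec, seed = 21)
  # weighted covariance eigendecomposition oracle
  Yc <- sweep(sim$Y, 2, colMeans(sim$Y))
  W <- sim$grid$weights
  C <- crossprod(Yc) / nrow(Yc)
  A <- sqrt(W) * t(sqrt(W) * t(C))
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values[1:3]
  expect_equal(ev, s2$eigenvalues, tolerance = 0.05)
})

test_that("multilevel simulation nests and degenerates correctly", {
  ml <- simulate_multilevel(N = 20, J = 3, seed = 9)
  expect_equal(nrow(ml$Y), 60)
  expect_identical(ml$subject, rep(1:20, each = 3))
  ml2 <- simulate_multilevel(N = 20, J = 3, seed = 9)
  expect_identical(ml$Y, ml2$Y)

  # J = 1 with no level-2 block equals the single-level generator exactly
  s1 <- scenario_ml1()
  flat <- simulate_multilevel(spec1 = s1, spec2 = NULL, N = 30, J = 1, seed = 4)
  single <- simulate_scenario(s1, seed = 4, N = 30)
  expect_identical(flat$Y, single$Y)
  expect_identical(flat$true_scores1, single$true_scores)
})

test_that("between-subject variance follows the law of total variance", {
  spec1 <- scenario_ml1()
  spec2 <- scenario_ml2()
  J <- 4
  ml <- simulate_multilevel(spec1, spec2, N = 2000, J = J, seed = 31)
  m <- 17 # a grid point
  t_m <- ml$grid$points[m]
  subj_means <- drop(rowsum(ml$Y[, m], ml$subject)) / J
  v_emp <- var(subj_means)
  v_theory <- sum(spec1$eigenvalues *
                    vapply(spec1$eigen_fns, function(f) f(t_m)^2, numeric(1))) +
    (sum(spec2$eigenvalues *
           vapply(spec2$eigen_fns, function(f) f(t_m)^2, numeric(1))) +
       spec1$sigma2) / J
  expect_equal(v_emp, v_theory, tolerance = 0.1 * v_theory)
})
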
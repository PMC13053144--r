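# Quadrature grids, the orthonormal spline basis, and the mixed smoothing
# penalty.

test_that("quadrature grids integrate exactly and match the reference rule", {
  # closed-form 2-point Gauss-Legendre rule on [0, 1]
  g2 <- make_grid(2)
  expect_equal(g2$points, c(0.5 - 1 / (2 * sqrt(3)), 0.5 + 1 / (2 * sqrt(3))),
               tolerance = 1e-12)
  expect_equal(g2$weights, c(0.5, 0.5), tolerance = 1e-12)

  for (M in c(5, 17, 50)) {
    gl <- make_grid(M, "gauss-legendre")
    tr <- make_grid(M, "trapezoid")
    for (g in list(gl, tr)) {
      expect_true(all(diff(g$points) > 0))
      expect_true(all(g$points >= 0 & g$points <= 1))
      expect_true(all(g$weights > 0))
      expect_equal(sum(g$weights), 1, tolerance = 1e-10)
    }
    # Gauss-Legendre integrates polynomials exactly
    expect_equal(sum(gl$weights * gl$points), 0.5, tolerance = 1e-12)
    expect_equal(sum(gl$weights * gl$points^3), 0.25, tolerance = 1e-12)
  }

  skip_if_not_installed("pracma")
  ref <- pracma::gaussLegendre(50, 0, 1)
  g <- make_grid(50)
  expect_equal(g$points, ref$x, tolerance = 1e-13)
  expect_equal(g$weights, ref$w, tolerance = 1e-13)
})

test_that("grid construction rejects bad input", {
  expect_error(make_grid(1), "integer")
  expect_error(make_grid(10, "simpson"), "arg")
})

test_that("the basis is orthonormal with intercept and slope in its span", {
  for (Q in c(8, 20)) {
    b <- fix_basis(Q)
    fg <- b$fine_grid
    Bf <- b$evaluator(fg$points)
    G <- crossprod(Bf, fg$weights * Bf)
    expect_lt(max(abs(G - diag(Q))), 1e-6)

    # projecting the constant and the identity function leaves no residual
    for (f_vals in list(rep(1, length(fg$points)), fg$points)) {
      coef <- drop(crossprod(Bf, fg$weights * f_vals))
      resid <- f_vals - drop(Bf %*% coef)
      expect_lt(max(abs(resid)), 1e-8)
    }

    # unit coefficient norm means unit L2 norm of the function
    set.seed(Q)
    theta <- rnorm(Q); theta <- theta / sqrt(sum(theta^2))
    tt <- seq(0, 1, length.out = 10001)
    fv <- drop(b$evaluator(tt) %*% theta)
    expect_equal(simp_quad(fv^2, tt), 1, tolerance = 1e-6)
  }
})

test_that("vector mode gives exact discrete orthonormality", {
  b <- fix_basis(Q = 10, mode = "vector")
  Bm <- b$eval_matrix
  expect_lt(max(abs(crossprod(Bm) - diag(10))), 1e-8)
})

test_that("basis construction rejects impossible dimensions", {
  g <- fix_grid(8)
  expect_error(build_basis(g, Q = 9), "exceeds")
  expect_error(build_basis(g, Q = 3), ">= 4")
})

test_that("the second-derivative Gram annihilates linear functions and matches quadrature", {
  b <- fix_basis(12)
  S <- second_derivative_gram(b)
  expect_equal(S, t(S))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-10 * max(abs(ev))))

  fg <- b$fine_grid
  Bf <- b$evaluator(fg$points)
  # coefficients of the constant and of the slope function
  for (f_vals in list(rep(1, length(fg$points)), fg$points)) {
    theta <- drop(crossprod(Bf, fg$weights * f_vals))
    expect_lt(abs(drop(crossprod(theta, S %*% theta))), 1e-8)
  }

  # brute-force finite-difference quadrature oracle on a random function
  set.seed(42)
  theta <- rnorm(12)
  tt <- seq(0, 1, length.out = 10000)
  fv <- drop(b$evaluator(tt) %*% theta)
  h <- tt[2] - tt[1]
  f2 <- diff(diff(fv)) / h^2
  oracle <- trap_quad(f2^2, tt[2:(length(tt) - 1)]) # interior second differences
  qf <- drop(crossprod(theta, S %*% theta))
  expect_equal(qf, oracle, tolerance = 1e-4 * abs(qf))
})

test_that("the penalty interpolates between the L2 Gram and the curvature Gram", {
  b <- fix_basis(12)
  P0 <- build_penalty(b, 0)$P
  P1 <- build_penalty(b, 1)$P
  expect_lt(max(abs(P1 - diag(12))), 1e-6) # pure integral penalty of an orthonormal basis
  for (a in c(0.1, 0.5)) {
    Pa <- build_penalty(b, a)$P
    expect_equal(Pa, a * P1 + (1 - a) * P0, tolerance = 1e-12)
  }
  expect_error(build_penalty(b, 1.2), "\\[0, 1\\]")
})

test_that("penalty quadratic forms match dense integration for random functions", {
  b <- fix_basis(12)
  pen <- build_penalty(b, 0.1)
  tt <- seq(0, 1, length.out = 10000)
  Bt <- b$evaluator(tt)
  D2 <- b$deriv2(tt)
  set.seed(11)
  for (r in 1:20) {
    theta <- rnorm(12)
    fv <- drop(Bt %*% theta)
    f2 <- drop(D2 %*% theta)
    oracle <- 0.1 * trap_quad(fv^2, tt) + 0.9 * trap_quad(f2^2, tt)
    qf <- drop(crossprod(theta, pen$P %*% theta))
    expect_lt(abs(qf - oracle) / qf, 1e-3)
  }
})

test_that("penalty records full rank and its trace for positive alpha", {
  pen <- fix_penalty(0.1)
  expect_equal(pen$rank, 12)
  expect_equal(pen$trace, sum(diag(pen$P)))
})

test_that("basis and penalty matrices round-trip through plain text exactly", {
  b <- fix_basis(8)
  pen <- build_penalty(b, 0.1)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_matrix(pen$P, tmp)
  expect_identical(unname(read_matrix(tmp)), unname(pen$P))
  write_matrix(b$eval_matrix, tmp)
  expect_identical(unname(read_matrix(tmp)), unname(b$eval_matrix))
})
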
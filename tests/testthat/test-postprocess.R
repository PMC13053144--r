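# Ordering, sign alignment, orthonormal point estimates, bands, PVE, and
# split-chain diagnostics.

test_that("components are reordered by per-draw score variance", {
  draws <- fake_draws(n = 10, K = 3)
  # scramble: put the small-variance component first everywhere
  perm_in <- c(3, 1, 2)
  for (c in seq_along(draws$chains)) {
    ch <- draws$chains[[c]]
    ch$lambda <- ch$lambda[, perm_in]
    ch$H <- ch$H[, perm_in]
    ch$Psi <- ch$Psi[, , perm_in]
    ch$Xi <- ch$Xi[, , perm_in]
    draws$chains[[c]] <- ch
  }
  al <- order_components(draws)
  for (c in seq_along(al$chains)) {
    v <- t(apply(al$chains[[c]]$Xi, 1, function(m) apply(m, 2, var)))
    expect_true(all(apply(v, 1, function(x) all(diff(x) <= 0))))
  }
  # already sorted draws give the identity permutation
  al2 <- order_components(al)
  for (c in seq_along(al2$chains)) {
    expect_true(all(al2$permutations[[c]] ==
                      matrix(1:3, nrow(al2$permutations[[c]]), 3, byrow = TRUE)))
  }
})

test_that("sign alignment fixes flipped columns and leaves the reference alone", {
  draws <- fake_draws(n = 12, K = 3, perturb = 0.01)
  # flip column 2 of every draw of chain 2
  ch <- draws$chains[[2]]
  ch$Psi[, , 2] <- -ch$Psi[, , 2]
  ch$Xi[, , 2] <- -ch$Xi[, , 2]
  draws$chains[[2]] <- ch
  al <- align_signs(order_components(draws))
  expect_true(all(al$chains[[1]]$signs[1, ] == 1))     # reference draw
  expect_true(all(al$chains[[2]]$signs[, 2] == -1))
  # after alignment both chains agree in sign with the reference
  B <- draws$basis$eval_matrix
  ref <- B %*% al$chains[[1]]$Psi[1, , ]
  for (c in 1:2) for (k in 1:3) {
    Phik <- matrix(al$chains[[c]]$Psi[, , k], 12) %*% t(B)
    expect_true(all(cor(t(Phik), ref[, k]) > 0))
  }
})

test_that("ordering and sign alignment leave every reconstruction unchanged and are idempotent", {
  draws <- fake_draws(n = 8, K = 3)
  rec0 <- reconstruct_all(draws)
  al <- align_signs(order_components(draws))
  rec1 <- reconstruct_all(al)
  for (c in seq_along(rec0)) {
    # invariant up to the last ulp: permuting columns reorders the additions
    # inside the matrix product
    expect_lt(max(abs(rec0[[c]] - rec1[[c]])),
              1e-13 * max(1, max(abs(rec0[[c]]))))
  }
  al2 <- align_signs(order_components(al))
  for (c in seq_along(al$chains)) {
    expect_identical(al$chains[[c]]$Psi, al2$chains[[c]]$Psi)
    expect_identical(al$chains[[c]]$Xi, al2$chains[[c]]$Xi)
  }
})

test_that("recorded permutations and signs reproduce aligned draws from raw draws", {
  draws <- fake_draws(n = 6, K = 3)
  al <- align_signs(order_components(draws))
  for (c in seq_along(draws$chains)) {
    raw <- draws$chains[[c]]
    fixed <- al$chains[[c]]
    for (j in seq_len(6)) {
      p <- al$permutations[[c]][j, ]
      s <- fixed$signs[j, ]
      expect_identical(sweep(raw$Psi[j, , p], 2, s, `*`), fixed$Psi[j, , ])
      expect_identical(sweep(raw$Xi[j, , p], 2, s, `*`), fixed$Xi[j, , ])
      expect_identical(raw$lambda[j, p], fixed$lambda[j, ])
    }
  }
})

test_that("orthonormalized mean is exactly orthonormal and matches the SVD polar oracle", {
  draws <- fake_draws(n = 100, K = 3)
  al <- align_signs(order_components(draws))
  om <- orthonormalized_mean(al)
  expect_lt(max(abs(crossprod(om$Psi_hat) - diag(3))), 1e-10)

  Psi_bar <- (apply(al$chains[[1]]$Psi, c(2, 3), sum) +
                apply(al$chains[[2]]$Psi, c(2, 3), sum)) / 200
  sv <- svd(Psi_bar)
  expect_lt(max(abs(om$Psi_hat - sv$u %*% t(sv$v))), 1e-8)

  # identical draws: the estimate is that draw
  dr1 <- fake_draws(n = 5, K = 2, perturb = 0)
  al1 <- align_signs(order_components(dr1))
  om1 <- orthonormalized_mean(al1)
  expect_equal(om1$Psi_hat, al1$chains[[1]]$Psi[1, , ], tolerance = 1e-10)
})

test_that("credible bands follow the order-statistics quantile convention", {
  draws <- fake_draws(n = 500, K = 2, N = 4)
  al <- align_signs(order_components(draws))
  bands <- credible_bands(al, level = 0.9)
  lam_draws <- rbind(al$chains[[1]]$lambda, al$chains[[2]]$lambda)
  for (k in 1:2) {
    expect_equal(bands$eigenvalues$lower[k],
                 unname(quantile(lam_draws[, k], 0.05, type = 7)))
    expect_equal(bands$eigenvalues$upper[k],
                 unname(quantile(lam_draws[, k], 0.95, type = 7)))
  }
  # bands contain the estimates
  with(bands$fpcs, expect_true(all(lower <= estimate & estimate <= upper)))
  with(bands$mean_curve, expect_true(all(lower <= estimate & estimate <= upper)))
  expect_error(credible_bands(al, level = 1.2), "\\(0, 1\\)")

  # standard-normal sanity: 95% interval close to +/- 1.96
  set.seed(1)
  x <- rnorm(10000)
  q <- quantile(x, c(0.025, 0.975), type = 7)
  expect_equal(unname(q), c(-1.96, 1.96), tolerance = 0.08)
})

test_that("constant draws give zero-width intervals", {
  draws <- fake_draws(n = 30, K = 2, perturb = 0)
  for (c in 1:2) {
    draws$chains[[c]]$lambda <- matrix(rep(c(400, 20), each = 30), 30)
    draws$chains[[c]]$w_mu <- matrix(1, 30, 12)
    # deterministic score columns with exactly ordered variances, so the
    # per-draw permutation is the identity for every draw
    base <- scale(seq_len(12))[, 1]
    draws$chains[[c]]$Xi[, , 1] <- matrix(20 * base, 30, 12, byrow = TRUE)
    draws$chains[[c]]$Xi[, , 2] <- matrix(4 * base, 30, 12, byrow = TRUE)
  }
  al <- align_signs(order_components(draws))
  bands <- credible_bands(al)
  expect_equal(bands$eigenvalues$lower, bands$eigenvalues$upper)
  expect_equal(bands$mean_curve$lower, bands$mean_curve$upper)
})

test_that("percent variance explained matches closed-form arithmetic", {
  p <- pve(matrix(c(1, 0.5, 0.25), 1))
  expect_equal(p$estimate, 100 * c(1, 0.5, 0.25) / 1.75, tolerance = 1e-12)

  p1 <- pve(matrix(5, 1))
  expect_equal(p1$estimate, 100)

  pn <- pve(matrix(c(2250, 450, 150), 1), include_noise = TRUE,
            sigma2_draws = 4)
  expect_equal(pn$estimate[1], 2250 / 2854 * 100, tolerance = 1e-12)

  expect_error(pve(matrix(1:3, 1), include_noise = TRUE), "sigma2")
})

test_that("split-chain RHat detects convergence and divergence", {
  set.seed(42)
  # two independent stationary chains: RHat near 1
  m1 <- matrix(rnorm(1000), 1000, 1)
  m2 <- matrix(rnorm(1000), 1000, 1)
  expect_lt(split_rhat_matrix(list(m1, m2)), 1.01)
  # an offset of +5 between chains blows the statistic up
  expect_gt(split_rhat_matrix(list(m1, m2 + 5)), 1.5)
  # constant identical chains: 1 by convention
  expect_equal(split_rhat_matrix(list(matrix(2, 50, 1), matrix(2, 50, 1))),
               1)
})

test_that("rhat() covers all monitored blocks and warns on a single chain", {
  draws <- fake_draws(n = 40, K = 2, N = 4)
  al <- align_signs(order_components(draws))
  r <- rhat(al)
  M <- draws$dims$M
  expect_setequal(unique(r$table$block),
                  c("phi_1", "phi_2", "scores_1", "scores_2", "lambda", "sigma2"))
  expect_equal(nrow(r$table), 2 * M + 2 * 4 + 2 + 1)
  expect_equal(r$max, max(r$table$rhat))

  dr1 <- fake_draws(n = 40, K = 2, N = 4, n_chains = 1)
  al1 <- align_signs(order_components(dr1))
  expect_warning(rhat(al1), "single chain")
})

test_that("postprocess_fpca assembles a complete result", {
  draws <- fake_draws(n = 60, K = 3, N = 5)
  res <- postprocess_fpca(draws)
  expect_s3_class(res, "bfpca_result")
  expect_equal(dim(res$fpc_estimates), c(50, 3))
  expect_lt(max(abs(crossprod(res$Psi_hat) - diag(3))), 1e-10)
  expect_equal(nrow(res$eigenvalues), 3)
  expect_true(all(res$pve$estimate >= 0 & res$pve$estimate <= 100))
  expect_lte(sum(res$pve$estimate), 100 + 1e-8)
  expect_true(is.finite(res$rhat$max))
})
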
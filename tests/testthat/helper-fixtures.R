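# Shared small fixtures, built once per test run.

fix_grid <- function(M = 50) make_grid(M)

# memoize the default basis/penalty used across test files
.fix_env <- new.env()

fix_basis <- function(Q = 12, M = 50, mode = "functional") {
  key <- paste(Q, M, mode, sep = "_")
  if (is.null(.fix_env[[key]])) {
    .fix_env[[key]] <- build_basis(fix_grid(M), Q, mode)
  }
  .fix_env[[key]]
}

fix_penalty <- function(alpha = 0.1, Q = 12, M = 50) {
  key <- paste("pen", alpha, Q, M, sep = "_")
  if (is.null(.fix_env[[key]])) {
    .fix_env[[key]] <- build_penalty(fix_basis(Q, M), alpha)
  }
  .fix_env[[key]]
}

# a valid random parameter draw for density tests
fix_draw <- function(N = 8, K = 2, Q = 12, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(Q * K), Q, K)
  pol <- polar_orthonormalize(X)
  list(sigma2 = 0.7,
       w_mu = rnorm(Q),
       h_mu = 1.3,
       lambda = sort(rexp(K) + 0.5),
       H = rexp(K) + 0.1,
       X = X,
       Psi = pol$Psi,
       Xi = matrix(rnorm(N * K), N, K))
}

# dense trapezoid quadrature oracle on [0,1]
trap_quad <- function(f_vals, t_grid) {
  h <- diff(t_grid)
  sum((f_vals[-1] + f_vals[-length(f_vals)]) / 2 * h)
}

# composite Simpson oracle (equally spaced, odd number of points)
simp_quad <- function(f_vals, t_grid) {
  n <- length(t_grid)
  stopifnot(n %% 2 == 1)
  h <- t_grid[2] - t_grid[1]
  w <- c(1, rep(c(4, 2), length.out = n - 2), 1)
  w[n] <- 1
  sum(w * f_vals) * h / 3
}

# hand-built draws object (no sampling) with known structure, for exercising
# the post-processing machinery deterministically
fake_draws <- function(n = 40, K = 3, Q = 12, N = 12, n_chains = 2, seed = 2,
                       perturb = 0.02) {
  basis <- fix_basis(Q)
  set.seed(seed)
  Psi0 <- polar_orthonormalize(matrix(rnorm(Q * K), Q, K))$Psi
  # well separated so per-draw variance ordering is stable at small N
  lam0 <- c(400, 20, 1)[seq_len(K)]
  chains <- lapply(seq_len(n_chains), function(c) {
    Psi <- array(0, c(n, Q, K))
    Xi <- array(0, c(n, N, K))
    lambda <- matrix(0, n, K)
    for (j in seq_len(n)) {
      Pj <- polar_orthonormalize(Psi0 + perturb * matrix(rnorm(Q * K), Q, K))$Psi
      Psi[j, , ] <- Pj
      Xi[j, , ] <- matrix(rnorm(N * K), N, K) %*% diag(sqrt(lam0), K)
      lambda[j, ] <- sort(lam0 * exp(rnorm(K, 0, 0.05)), decreasing = TRUE)
    }
    list(sigma2 = exp(rnorm(n, 0, 0.05)), h_mu = rexp(n) + 0.5,
         w_mu = matrix(rnorm(n * Q, sd = 0.2), n, Q),
         lambda = lambda, H = matrix(rexp(n * K) + 0.1, n, K),
         Psi = Psi, Xi = Xi,
         diagnostics = list(accept_rate = 1, step_size = 1, divergences = 0))
  })
  structure(list(chains = chains,
                 config = fpca_config(K = K, Q = Q, n_iter = 2 * n,
                                      n_warmup = n, n_chains = n_chains),
                 basis = basis, penalty = fix_penalty(0.1, Q),
                 grid = basis$grid,
                 dims = list(N = N, M = length(basis$grid$points), K = K, Q = Q)),
            class = "bfpca_draws")
}

# reconstruction Xi t(B Psi) for every draw of every chain, as one array
reconstruct_all <- function(draws) {
  B <- draws$basis$eval_matrix
  lapply(draws$chains, function(ch) {
    n <- length(ch$sigma2)
    sapply(seq_len(n), function(j) {
      matrix(ch$Xi[j, , ], draws$dims$N) %*% t(B %*% ch$Psi[j, , ])
    }, simplify = "array")
  })
}

# small, fast sampler config for tests that need a real fit
fix_small_config <- function(...) {
  fpca_config(K = 3, Q = 12, n_iter = 300, n_warmup = 150, n_chains = 2,
              seed = 7, ...)
}
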
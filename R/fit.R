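#' Fit the Bayesian functional principal components model
#'
#' Draws from the joint posterior of the single-level model: error variance,
#' mean spline coefficients and their smoothing parameter, ordered
#' eigenvalues, component smoothing parameters, scores, and the orthonormal
#' spline coefficient matrix of the eigenfunctions. The coefficient matrix is
#' parameter-expanded: an unconstrained latent matrix `X` with independent
#' `N(0, 1)` entries is sampled and mapped to the Stiefel manifold by the
#' polar decomposition inside the density evaluation, so every retained draw
#' of `Psi` is exactly orthonormal. Eigenvalues are kept strictly increasing
#' during sampling; post-processing re-indexes components to
#' decreasing-variance order for reporting.
#'
#' The sampler is a blocked Gibbs scheme: all conditionals with analytic
#' form (mean coefficients, scores, variances, smoothing parameters, and
#' order-truncated eigenvalues) are drawn exactly, while the latent matrix
#' `X` is updated by Hamiltonian Monte Carlo with analytic gradients through
#' the polar decomposition and dual-averaging step-size adaptation during
#' warm-up.
#'
#' @param Y `N x M` data matrix, one row per curve, no missing values.
#' @param grid `bfpca_grid` matching the columns of `Y`.
#' @param config a `bfpca_config`.
#' @param basis,penalty optional prebuilt `bfpca_basis` / `bfpca_penalty`
#'   (must match `config`); built from `config` when `NULL`.
#' @param verbose print per-chain progress.
#' @return An object of class `bfpca_draws`: per-chain retained draws
#'   (`sigma2`, `h_mu`, `w_mu`, `lambda`, `H`, `Psi`, `Xi`), the
#'   configuration, basis, penalty, grid, and sampler diagnostics
#'   (acceptance rate, step size, divergence count per chain).
#' @examples
#' \donttest{
#' sim <- simulate_scenario(scenario_s2(), seed = 1)
#' cfg <- fpca_config(K = 3, Q = 12, n_iter = 300, n_warmup = 150,
#'                    n_chains = 2, seed = 1)
#' fit <- fit_fpca(sim$Y, sim$grid, cfg)
#' }
#' @export
fit_fpca <- function(Y, grid, config = fpca_config(), basis = NULL,
                     penalty = NULL, verbose = FALSE) {
  Y <- as.matrix(Y)
  stopifnot(inherits(grid, "bfpca_grid"), inherits(config, "bfpca_config"))
  if (anyNA(Y)) stop("`Y` contains missing values", call. = FALSE)
  N <- nrow(Y); M <- ncol(Y)
  if (M != length(grid$points)) stop("ncol(Y) does not match the grid", call. = FALSE)
  if (N < 2) stop("at least 2 curves are required", call. = FALSE)
  if (config$Q > M) stop(sprintf("Q = %d exceeds M = %d", config$Q, M), call. = FALSE)
  if (is.null(basis)) basis <- build_basis(grid, config$Q, config$mode)
  if (is.null(penalty)) penalty <- build_penalty(basis, config$alpha)
  b_h <- check_propriety(config, penalty)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_seed(old_seed))
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)

  chains <- vector("list", config$n_chains)
  for (c in seq_len(config$n_chains)) {
    if (verbose) message(sprintf("chain %d/%d (seed %d)", c, config$n_chains,
                                 chain_seeds[c]))
    chains[[c]] <- run_fpca_chain(Y, basis, penalty, config, b_h,
                                  chain_seeds[c], verbose)
  }
  structure(list(chains = chains, config = config, basis = basis,
                 penalty = penalty, grid = grid,
                 dims = list(N = N, M = M, K = config$K, Q = config$Q),
                 chain_seeds = chain_seeds),
            class = "bfpca_draws")
}

#' @export
print.bfpca_draws <- function(x, ...) {
  n_keep <- x$config$n_iter - x$config$n_warmup
  div <- sum(vapply(x$chains, function(ch) ch$diagnostics$divergences, numeric(1)))
  cat(sprintf(paste0("<bfpca_draws> N = %d curves, M = %d points, K = %d, Q = %d\n",
                     "  %d chains x %d retained draws; %d divergent trajectories\n"),
              x$dims$N, x$dims$M, x$dims$K, x$dims$Q,
              x$config$n_chains, n_keep, div))
  invisible(x)
}

# ---- single chain ----------------------------------------------------------

run_fpca_chain <- function(Y, basis, penalty, config, b_h, seed, verbose) {
  set.seed(seed)
  B <- basis$eval_matrix
  P <- penalty$P
  N <- nrow(Y); M <- ncol(Y); Q <- config$Q; K <- config$K
  hp <- config$prior
  BtB <- crossprod(B)

  st <- init_fpca_state(Y, basis, config)
  n_keep <- config$n_iter - config$n_warmup
  keep <- list(sigma2 = numeric(n_keep), h_mu = numeric(n_keep),
               w_mu = matrix(0, n_keep, Q), lambda = matrix(0, n_keep, K),
               H = matrix(0, n_keep, K),
               Psi = array(0, c(n_keep, Q, K)),
               Xi = array(0, c(n_keep, N, K)))

  da <- da_init(eps0 = 0.5, target = config$target_accept)
  n_div <- 0L; acc_sum <- 0
  ones_mu <- function(mu) matrix(mu, N, M, byrow = TRUE)

  for (iter in seq_len(config$n_iter)) {
    Phi <- B %*% st$Psi

    ## mean coefficients (Gaussian conditional)
    R <- Y - st$Xi %*% t(Phi)
    A <- N * BtB / st$sigma2 + st$h_mu * P
    bvec <- drop(crossprod(B, colSums(R))) / st$sigma2
    st$w_mu <- draw_gaussian_canonical(A, bvec)

    ## mean smoothing parameter
    qf_mu <- drop(crossprod(st$w_mu, P %*% st$w_mu))
    st$h_mu <- stats::rgamma(1, shape = hp$a_hmu + Q / 2,
                             rate = hp$b_hmu + qf_mu / 2)

    mu <- drop(B %*% st$w_mu)
    R0 <- Y - ones_mu(mu)

    ## scores (rows conditionally independent Gaussians, common precision)
    Cmat <- crossprod(Phi) / st$sigma2 + diag(1 / st$lambda, K)
    U <- chol(Cmat)
    Mean <- t(backsolve(U, forwardsolve(t(U), t(R0 %*% Phi) / st$sigma2)))
    st$Xi <- Mean + t(backsolve(U, matrix(stats::rnorm(N * K), K, N)))

    ## ordered eigenvalues (truncated inverse-gamma)
    ss <- colSums(st$Xi^2)
    for (k in seq_len(K)) {
      lo <- if (k == 1) 0 else st$lambda[k - 1]
      up <- if (k == K) Inf else st$lambda[k + 1]
      st$lambda[k] <- rinvgamma_trunc(hp$a_lambda + N / 2,
                                      hp$b_lambda + ss[k] / 2,
                                      lo, up, st$lambda[k])
    }

    ## component smoothing parameters
    qf_psi <- diag(crossprod(st$Psi, P %*% st$Psi))
    st$H <- stats::rgamma(K, shape = hp$a_h + Q / 2, rate = b_h + qf_psi / 2)

    ## error variance
    SSR <- sum((R0 - st$Xi %*% t(Phi))^2)
    st$sigma2 <- 1 / stats::rgamma(1, shape = hp$a_sigma + N * M / 2,
                                   rate = hp$b_sigma + SSR / 2)

    ## exact moves along the likelihood-invariant valleys (cheap relative to
    ## the gradient update, so several sweeps per scan)
    for (sweep_i in 1:3) {
      tr <- translate_mean_scores(st$w_mu, st$Xi, st$Psi, st$h_mu, st$lambda, P)
      st$w_mu <- tr$w_mu; st$Xi <- tr$Xi
      rot <- rotate_pair_move(st$Psi, st$Xi, st$X, st$lambda, st$H, P)
      st$Psi <- rot$Psi; st$Xi <- rot$Xi; st$X <- rot$X
    }
    R0 <- Y - ones_mu(drop(B %*% st$w_mu))

    ## latent coefficient matrix and mean coefficients: exact refresh of the
    ## PSD polar factor (prior-only, independent of Psi under the N(0,1)
    ## measure), then a joint HMC update of (X, w_mu) through the polar map -
    ## jointly, because eigenfunction shape and mean shape are strongly
    ## coupled whenever the mean loads on an eigenfunction
    st$X <- refresh_polar_radius(st$Psi)
    eps <- if (iter <= config$n_warmup) exp(da$log_eps) else exp(da$log_eps_bar)
    mass <- build_x_mass(st$Xi, st$sigma2, st$H, BtB, P)
    mass_w <- chol(N * BtB / st$sigma2 + st$h_mu * P)
    hmc <- hmc_update_xw(st$X, st$w_mu, eps, config$n_leapfrog, Y, st$Xi,
                         st$sigma2, st$h_mu, st$H, B, P, mass, mass_w)
    st$X <- hmc$X; st$Psi <- hmc$Psi; st$w_mu <- hmc$w
    n_div <- n_div + hmc$divergent
    acc_sum <- acc_sum + hmc$accept_prob
    if (iter <= config$n_warmup) {
      da <- da_update(da, iter, hmc$accept_prob)
    }

    if (iter > config$n_warmup) {
      j <- iter - config$n_warmup
      keep$sigma2[j] <- st$sigma2
      keep$h_mu[j] <- st$h_mu
      keep$w_mu[j, ] <- st$w_mu
      keep$lambda[j, ] <- st$lambda
      keep$H[j, ] <- st$H
      keep$Psi[j, , ] <- st$Psi
      keep$Xi[j, , ] <- st$Xi
    }
  }
  keep$diagnostics <- list(accept_rate = acc_sum / config$n_iter,
                           step_size = exp(da$log_eps_bar),
                           divergences = n_div, seed = seed)
  keep
}

# Data-driven initial state: project curves on the basis, eigendecompose the
# coefficient covariance, and overdisperse across chains by random column
# sign flips and jitter on the latent matrix.
init_fpca_state <- function(Y, basis, config) {
  B <- basis$eval_matrix
  K <- config$K; Q <- config$Q
  w <- basis$grid$weights
  Cf <- if (basis$mode == "functional") Y %*% (w * B) else Y %*% B
  w_mu <- colMeans(Cf)
  Cc <- sweep(Cf, 2, w_mu)
  eg <- eigen(crossprod(Cc) / nrow(Y), symmetric = TRUE)
  Psi0 <- eg$vectors[, K:1, drop = FALSE]        # increasing-eigenvalue order
  lam0 <- pmax(rev(eg$values[seq_len(K)]), 1e-6)
  signs <- sample(c(-1, 1), K, replace = TRUE)
  Psi0 <- sweep(Psi0, 2, signs, `*`)
  lam0 <- lam0 * exp(stats::rnorm(K, 0, 0.1))
  lam0 <- sort(lam0)
  lam0 <- lam0 * cumprod(c(1, rep(1 + 1e-8, K - 1)))  # strictly increasing
  Xi0 <- Cc %*% Psi0
  resid <- Y - matrix(drop(B %*% w_mu), nrow(Y), ncol(Y), byrow = TRUE) -
    Xi0 %*% t(B %*% Psi0)
  sigma2 <- max(mean(resid^2), 1e-6)
  X0 <- Psi0 + matrix(stats::rnorm(Q * K, 0, 0.1), Q, K)
  Psi0 <- polar_orthonormalize(X0, jitter = TRUE)$Psi
  list(sigma2 = sigma2, w_mu = w_mu, h_mu = 1,
       lambda = lam0, H = rep(1, K), X = X0, Psi = Psi0, Xi = Xi0)
}

# draw from N(A^{-1} b, A^{-1}) given canonical parameters
draw_gaussian_canonical <- function(A, b) {
  U <- chol(A)
  mean <- backsolve(U, forwardsolve(t(U), b))
  drop(mean + backsolve(U, stats::rnorm(length(b))))
}

# inverse-gamma(shape a, scale s) truncated to (lo, up); returns `current` if
# the interval carries no numerically resolvable mass
rinvgamma_trunc <- function(a, s, lo, up, current) {
  p_lo <- if (is.finite(up)) stats::pgamma(1 / up, a, rate = s) else 0
  p_hi <- if (lo > 0) stats::pgamma(1 / lo, a, rate = s) else 1
  if (!(p_hi - p_lo > 1e-14)) return(current)
  u <- stats::runif(1, p_lo, p_hi)
  x <- 1 / stats::qgamma(u, a, rate = s)
  if (!is.finite(x) || x <= lo || x >= up) return(current)
  x
}

# Exact Gibbs move along the mean/score translation valley: shifting every
# score of component k by -c while adding c * psi_k to the mean coefficients
# leaves the likelihood unchanged (the mean can absorb a constant multiple of
# an eigenfunction). Conditionally on everything else, c is Gaussian with
# precision h_mu * psi_k' P psi_k + N / lambda_k, so the valley - which is
# very flat when the true mean loads on an eigenfunction - is traversed in a
# single exact draw per component.
translate_mean_scores <- function(w_mu, Xi, Psi, h_mu, lambda, P) {
  N <- nrow(Xi)
  for (k in seq_along(lambda)) {
    psi_k <- Psi[, k]
    Ppsi <- P %*% psi_k
    prec <- h_mu * drop(crossprod(psi_k, Ppsi)) + N / lambda[k]
    lin <- -h_mu * drop(crossprod(w_mu, Ppsi)) + sum(Xi[, k]) / lambda[k]
    c_k <- stats::rnorm(1, lin / prec, 1 / sqrt(prec))
    w_mu <- w_mu + c_k * psi_k
    Xi[, k] <- Xi[, k] - c_k
  }
  list(w_mu = w_mu, Xi = Xi)
}

# Exact Gibbs rotation moves along the likelihood-invariant valley: jointly
# rotating a pair of coefficient columns and their score columns by an angle
# theta leaves Xi t(B Psi) unchanged (and the N(0,1) prior on X, rotations
# being orthogonal), so only the score priors and the smoothing penalties
# depend on theta - and both are linear in cos(2 theta) and sin(2 theta).
# The conditional of theta is therefore von Mises in 2 theta (with a uniform
# binary branch, since the density has period pi) and is sampled exactly.
# These moves equilibrate the rotation ambiguity between components, which
# gradient updates cross only by diffusion.
rotate_pair_move <- function(Psi, Xi, X, lambda, H, P) {
  K <- length(lambda)
  if (K < 2) return(list(Psi = Psi, Xi = Xi, X = X))
  pairs <- utils::combn(K, 2)
  for (jj in seq_len(ncol(pairs))) {
    idx <- pairs[, jj]
    xj <- Xi[, idx[1]]; xk <- Xi[, idx[2]]
    a <- sum(xj^2); b <- sum(xk^2); cc <- sum(xj * xk)
    d <- 1 / lambda[idx[1]] - 1 / lambda[idx[2]]
    Pj <- P %*% Psi[, idx[1]]
    qjj <- drop(crossprod(Psi[, idx[1]], Pj))
    qjk <- drop(crossprod(Psi[, idx[2]], Pj))
    qkk <- drop(crossprod(Psi[, idx[2]], P %*% Psi[, idx[2]]))
    e <- H[idx[1]] - H[idx[2]]
    A <- -(a - b) * d / 4 - (qjj - qkk) * e / 4
    Bc <- -cc * d / 2 - qjk * e / 2
    kappa <- sqrt(A^2 + Bc^2)
    omega <- rvonmises(atan2(Bc, A), kappa)
    th <- omega / 2 + sample(c(0, pi), 1)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    Psi[, idx] <- Psi[, idx, drop = FALSE] %*% R
    Xi[, idx] <- Xi[, idx, drop = FALSE] %*% R
    X[, idx] <- X[, idx, drop = FALSE] %*% R
  }
  list(Psi = Psi, Xi = Xi, X = X)
}

# Best-Fisher (1979) rejection sampler for the von Mises distribution on
# (-pi, pi]; degenerates to uniform as the concentration vanishes
rvonmises <- function(mu, kappa) {
  if (!is.finite(kappa) || kappa < 1e-10) return(stats::runif(1, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  repeat {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cst <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cst * (2 - cst) - u2 > 0 || log(cst / u2) + 1 - cst >= 0) {
      th <- sign(stats::runif(1) - 0.5) * acos(f)
      return((th + mu + pi) %% (2 * pi) - pi)
    }
  }
}

# Exact Gibbs refresh of the radial (PSD) polar factor: under independent
# N(0,1) entries the orthonormal and PSD factors of X are independent, so the
# PSD factor of a fresh standard-normal matrix has exactly the conditional
# distribution of the radius given Psi. Only the tangential (Stiefel)
# directions are left to the HMC update, which removes the worst scale
# anisotropy of the expanded parameterization.
refresh_polar_radius <- function(Psi) {
  Z <- matrix(stats::rnorm(length(Psi)), nrow(Psi), ncol(Psi))
  Psi %*% polar_orthonormalize(Z, jitter = TRUE)$Pfac
}

# ---- HMC for the latent matrix --------------------------------------------

# negative log conditional (up to constants) of (X, w_mu) given everything
# else, and its gradient; Psi = polar(X). The mean coefficients ride in the
# same Hamiltonian because eigenfunction shape and mean shape are strongly
# coupled whenever the mean loads on an eigenfunction.
xw_potential <- function(X, w, Y, Xi, sigma2, h_mu, H, B, P) {
  pol <- polar_orthonormalize(X, jitter = TRUE)
  Psi <- pol$Psi
  mu <- drop(B %*% w)
  E <- sweep(Y, 2, mu) - Xi %*% t(B %*% Psi)
  qf <- diag(crossprod(Psi, P %*% Psi))
  U <- 0.5 * sum(X^2) + sum(E^2) / (2 * sigma2) + 0.5 * sum(H * qf) +
    0.5 * h_mu * drop(crossprod(w, P %*% w))
  list(U = U, Psi = Psi)
}

xw_grad <- function(X, w, Y, Xi, sigma2, h_mu, H, B, P) {
  pol <- polar_orthonormalize(X, jitter = TRUE)
  Psi <- pol$Psi
  mu <- drop(B %*% w)
  E <- sweep(Y, 2, mu) - Xi %*% t(B %*% Psi)
  G <- t(crossprod(Xi, E) %*% B) / sigma2 - P %*% sweep(Psi, 2, H, `*`)
  gX <- X - polar_pullback_grad(X, G)      # gradient of the potential
  gw <- -drop(crossprod(B, colSums(E))) / sigma2 + h_mu * drop(P %*% w)
  list(gX = gX, gw = gw)
}

# Block-diagonal mass matrix for the X update: per component column, the
# conditional precision of the likelihood + smoothing + latent prior,
# M_k = (Xi'Xi)_kk / sigma2 * B'B + H_k * P + I. All ingredients are fixed
# during the X block, so preconditioning with them leaves the conditional
# invariant while equalizing the scale across components of very different
# eigenvalue. The mean block is preconditioned by its own conditional
# precision N * B'B / sigma2 + h_mu * P.
build_x_mass <- function(Xi, sigma2, H, BtB, P) {
  ss <- colSums(Xi^2)
  IQ <- diag(nrow(P))
  lapply(seq_along(H), function(k) {
    chol(ss[k] / sigma2 * BtB + H[k] * P + IQ)
  })
}

# apply M^{-1} columnwise from the per-column Cholesky factors
mass_solve <- function(mass, Pmat) {
  out <- Pmat
  for (k in seq_along(mass)) {
    out[, k] <- backsolve(mass[[k]], forwardsolve(t(mass[[k]]), Pmat[, k]))
  }
  out
}

mass_momentum <- function(mass, Q) {
  vapply(mass, function(U) drop(crossprod(U, stats::rnorm(Q))), numeric(Q))
}

hmc_update_xw <- function(X, w, eps, L_max, Y, Xi, sigma2, h_mu, H, B, P,
                          mass, mass_w) {
  L <- sample(seq(max(1L, ceiling(L_max / 2)), L_max), 1)
  Q <- nrow(X)
  pX <- mass_momentum(mass, Q)
  if (is.null(dim(pX))) pX <- matrix(pX, Q)
  pw <- drop(crossprod(mass_w, stats::rnorm(Q)))
  solve_w <- function(v) backsolve(mass_w, forwardsolve(t(mass_w), v))
  cur <- xw_potential(X, w, Y, Xi, sigma2, h_mu, H, B, P)
  H0 <- cur$U + 0.5 * sum(pX * mass_solve(mass, pX)) +
    0.5 * sum(pw * solve_w(pw))
  x <- X; wv <- w
  g <- xw_grad(x, wv, Y, Xi, sigma2, h_mu, H, B, P)
  divergent <- FALSE
  for (l in seq_len(L)) {
    pX <- pX - eps / 2 * g$gX
    pw <- pw - eps / 2 * g$gw
    x <- x + eps * mass_solve(mass, pX)
    wv <- wv + eps * solve_w(pw)
    g <- xw_grad(x, wv, Y, Xi, sigma2, h_mu, H, B, P)
    pX <- pX - eps / 2 * g$gX
    pw <- pw - eps / 2 * g$gw
    if (!all(is.finite(x)) || !all(is.finite(pX)) || !all(is.finite(wv))) {
      divergent <- TRUE; break
    }
  }
  if (!divergent) {
    prop <- xw_potential(x, wv, Y, Xi, sigma2, h_mu, H, B, P)
    H1 <- prop$U + 0.5 * sum(pX * mass_solve(mass, pX)) +
      0.5 * sum(pw * solve_w(pw))
    if (!is.finite(H1) || (H1 - H0) > 1000) divergent <- TRUE
  }
  if (divergent) {
    return(list(X = X, w = w, Psi = cur$Psi, accept_prob = 0,
                divergent = TRUE))
  }
  a <- min(1, exp(H0 - H1))
  if (stats::runif(1) < a) {
    list(X = x, w = wv, Psi = prop$Psi, accept_prob = a, divergent = FALSE)
  } else {
    list(X = X, w = w, Psi = cur$Psi, accept_prob = a, divergent = FALSE)
  }
}

# Nesterov dual averaging for the HMC step size
da_init <- function(eps0, target) {
  list(log_eps = log(eps0), log_eps_bar = log(eps0), h_bar = 0,
       mu = log(10 * eps0), target = target, gamma = 0.05, t0 = 10,
       kappa = 0.75)
}

da_update <- function(da, t, accept_prob) {
  frac <- 1 / (t + da$t0)
  da$h_bar <- (1 - frac) * da$h_bar + frac * (da$target - accept_prob)
  da$log_eps <- da$mu - sqrt(t) / da$gamma * da$h_bar
  w <- t^(-da$kappa)
  da$log_eps_bar <- w * da$log_eps + (1 - w) * da$log_eps_bar
  da
}
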
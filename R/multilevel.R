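#' Nested functional dataset
#'
#' Container for two-level functional data: curves `Y_ij(t)` on a common
#' grid, indexed by subject `i` and visit `j` within subject. Every subject
#' must have at least one visit and all rows share the grid.
#'
#' @param Y `n_obs x M` matrix, one row per subject-visit curve.
#' @param subject integer (or factor) subject index per row.
#' @param visit visit index within subject per row (defaults to occurrence
#'   order).
#' @param grid a `bfpca_grid` matching the columns of `Y`.
#' @return An object of class `bfpca_mldata`.
#' @export
mfpca_data <- function(Y, subject, visit = NULL, grid) {
  Y <- as.matrix(Y)
  stopifnot(inherits(grid, "bfpca_grid"))
  if (anyNA(Y)) stop("`Y` contains missing values", call. = FALSE)
  if (ncol(Y) != length(grid$points)) stop("ncol(Y) does not match the grid", call. = FALSE)
  if (length(subject) != nrow(Y)) stop("`subject` must index every row", call. = FALSE)
  subject <- as.integer(factor(subject, levels = unique(subject)))
  if (is.null(visit)) {
    visit <- stats::ave(subject, subject, FUN = seq_along)
  }
  if (length(visit) != nrow(Y)) stop("`visit` must index every row", call. = FALSE)
  structure(list(Y = Y, subject = subject, visit = as.integer(visit),
                 grid = grid, N = max(subject),
                 J = as.integer(table(subject)), n_obs = nrow(Y)),
            class = "bfpca_mldata")
}

#' @export
print.bfpca_mldata <- function(x, ...) {
  cat(sprintf("<bfpca_mldata> %d subjects, %d curves (J in [%d, %d]), M = %d\n",
              x$N, x$n_obs, min(x$J), max(x$J), length(x$grid$points)))
  invisible(x)
}

#' Gaussian log-likelihood of the two-level model
#'
#' Evaluates the log-likelihood of every observation around
#' `mu + eta_j + U_i + W_ij` with variance `sigma2`, where
#' `U_i = Phi1 xi_i` are the subject-level deviations and `W_ij = Phi2
#' zeta_ij` the subject/visit-level deviations. With one visit per subject
#' and no visit-level block the expression reduces to the single-level
#' likelihood.
#'
#' @param draw list with `sigma2`, `w_mu`, `Psi1`, `Xi` (`N x K1`), and
#'   optionally `Psi2`, `Zeta` (`n_obs x K2`), `eta` (`Q x n_visits`
#'   coefficient matrix; omitted or `NULL` means no visit deviations).
#' @param data a `bfpca_mldata`.
#' @param basis a `bfpca_basis`.
#' @return Scalar log-likelihood.
#' @export
mfpca_loglik <- function(draw, data, basis) {
  stopifnot(inherits(data, "bfpca_mldata"))
  B <- basis$eval_matrix
  if (draw$sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  mu <- drop(B %*% draw$w_mu)
  fitted <- matrix(mu, data$n_obs, ncol(data$Y), byrow = TRUE)
  if (!is.null(draw$eta)) {
    fitted <- fitted + t(B %*% draw$eta)[data$visit, , drop = FALSE]
  }
  fitted <- fitted +
    draw$Xi[data$subject, , drop = FALSE] %*% t(B %*% draw$Psi1)
  if (!is.null(draw$Psi2) && ncol(draw$Psi2) > 0) {
    fitted <- fitted + draw$Zeta %*% t(B %*% draw$Psi2)
  }
  R <- data$Y - fitted
  n <- length(data$Y)
  -n / 2 * log(2 * pi * draw$sigma2) - sum(R^2) / (2 * draw$sigma2)
}

#' Fit the two-level (multilevel) model
#'
#' Extends [fit_fpca()] to nested curves: subject-level and
#' subject/visit-level eigenfunction systems share the basis and penalty,
#' each with its own latent matrix, polar decomposition, ordered
#' eigenvalues, and smoothing parameters. No orthogonality is imposed
#' between the two systems. Visit-specific mean deviations `eta_j(t)` are
#' penalized splines with a shared smoothing parameter, disabled by default.
#'
#' @param data a `bfpca_mldata` (see [mfpca_data()]).
#' @param config a `bfpca_mconfig` (see [mfpca_config()]).
#' @param basis,penalty optional prebuilt objects.
#' @param verbose print per-chain progress.
#' @return An object of class `bfpca_mdraws` with per-chain draws of both
#'   level blocks.
#' @export
fit_mfpca <- function(data, config = mfpca_config(), basis = NULL,
                      penalty = NULL, verbose = FALSE) {
  stopifnot(inherits(data, "bfpca_mldata"), inherits(config, "bfpca_mconfig"))
  M <- ncol(data$Y)
  if (config$Q > M) stop(sprintf("Q = %d exceeds M = %d", config$Q, M), call. = FALSE)
  if (is.null(basis)) basis <- build_basis(data$grid, config$Q, config$mode)
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
    chains[[c]] <- run_mfpca_chain(data, basis, penalty, config, b_h,
                                   chain_seeds[c])
  }
  structure(list(chains = chains, config = config, basis = basis,
                 penalty = penalty, grid = data$grid,
                 subject = data$subject, visit = data$visit,
                 dims = list(N = data$N, n_obs = data$n_obs, M = M,
                             K1 = config$K1, K2 = config$K2, Q = config$Q),
                 chain_seeds = chain_seeds),
            class = "bfpca_mdraws")
}

#' @export
print.bfpca_mdraws <- function(x, ...) {
  cat(sprintf(paste0("<bfpca_mdraws> %d subjects, %d curves, K1 = %d, K2 = %d, Q = %d\n",
                     "  %d chains x %d retained draws\n"),
              x$dims$N, x$dims$n_obs, x$dims$K1, x$dims$K2, x$dims$Q,
              x$config$n_chains, x$config$n_iter - x$config$n_warmup))
  invisible(x)
}

run_mfpca_chain <- function(data, basis, penalty, config, b_h, seed) {
  set.seed(seed)
  B <- basis$eval_matrix
  P <- penalty$P
  Y <- data$Y
  N <- data$N; n_obs <- data$n_obs; M <- ncol(Y)
  Q <- config$Q; K1 <- config$K1; K2 <- config$K2
  hp <- config$prior
  BtB <- crossprod(B)
  subj <- data$subject
  subj_rows <- split(seq_len(n_obs), subj)
  J <- data$J
  use_eta <- isTRUE(config$eta)
  n_visits <- if (use_eta) max(data$visit) else 0L
  visit_rows <- if (use_eta) split(seq_len(n_obs), data$visit) else NULL

  st <- init_mfpca_state(data, basis, config)
  n_keep <- config$n_iter - config$n_warmup
  keep <- list(sigma2 = numeric(n_keep), h_mu = numeric(n_keep),
               w_mu = matrix(0, n_keep, Q),
               lambda1 = matrix(0, n_keep, K1), H1 = matrix(0, n_keep, K1),
               Psi1 = array(0, c(n_keep, Q, K1)),
               Xi = array(0, c(n_keep, N, K1)),
               lambda2 = matrix(0, n_keep, max(K2, 1) * (K2 > 0)),
               H2 = matrix(0, n_keep, K2),
               Psi2 = array(0, c(n_keep, Q, K2)),
               Zeta = array(0, c(n_keep, n_obs, K2)))
  if (use_eta) keep$eta <- array(0, c(n_keep, Q, n_visits))

  da1 <- da_init(0.5, config$target_accept)
  n_div <- 0L; acc_sum <- 0

  for (iter in seq_len(config$n_iter)) {
    Phi1 <- B %*% st$Psi1
    Phi2 <- if (K2 > 0) B %*% st$Psi2 else matrix(0, M, 0)
    U_rows <- st$Xi[subj, , drop = FALSE] %*% t(Phi1)
    W_rows <- if (K2 > 0) st$Zeta %*% t(Phi2) else 0
    eta_rows <- if (use_eta) t(B %*% st$eta)[data$visit, , drop = FALSE] else 0

    ## mean
    R <- Y - eta_rows - U_rows - W_rows
    A <- n_obs * BtB / st$sigma2 + st$h_mu * P
    bvec <- drop(crossprod(B, colSums(R))) / st$sigma2
    st$w_mu <- draw_gaussian_canonical(A, bvec)
    qf_mu <- drop(crossprod(st$w_mu, P %*% st$w_mu))
    st$h_mu <- stats::rgamma(1, shape = hp$a_hmu + Q / 2,
                             rate = hp$b_hmu + qf_mu / 2)
    mu_rows <- matrix(drop(B %*% st$w_mu), n_obs, M, byrow = TRUE)

    ## visit-specific deviations (optional)
    if (use_eta) {
      Rf <- Y - mu_rows - U_rows - W_rows
      qf_eta <- 0
      for (j in seq_len(n_visits)) {
        rows <- visit_rows[[j]]
        Aj <- length(rows) * BtB / st$sigma2 + st$h_eta * P
        bj <- drop(crossprod(B, colSums(Rf[rows, , drop = FALSE]))) / st$sigma2
        st$eta[, j] <- draw_gaussian_canonical(Aj, bj)
        qf_eta <- qf_eta + drop(crossprod(st$eta[, j], P %*% st$eta[, j]))
      }
      st$h_eta <- stats::rgamma(1, shape = hp$a_hmu + n_visits * Q / 2,
                                rate = hp$b_hmu + qf_eta / 2)
      eta_rows <- t(B %*% st$eta)[data$visit, , drop = FALSE]
    }

    base_rows <- mu_rows + eta_rows

    ## subject-level scores
    R1 <- Y - base_rows - W_rows
    PtP1 <- crossprod(Phi1)
    for (i in seq_len(N)) {
      rows <- subj_rows[[i]]
      Ci <- J[i] * PtP1 / st$sigma2 + diag(1 / st$lambda1, K1)
      Ui <- chol(Ci)
      bi <- drop(crossprod(Phi1, colSums(R1[rows, , drop = FALSE]))) / st$sigma2
      mean_i <- backsolve(Ui, forwardsolve(t(Ui), bi))
      st$Xi[i, ] <- mean_i + backsolve(Ui, stats::rnorm(K1))
    }
    U_rows <- st$Xi[subj, , drop = FALSE] %*% t(Phi1)

    ## visit-level scores
    if (K2 > 0) {
      R2 <- Y - base_rows - U_rows
      C2 <- crossprod(Phi2) / st$sigma2 + diag(1 / st$lambda2, K2)
      U2 <- chol(C2)
      Mean <- t(backsolve(U2, forwardsolve(t(U2), t(R2 %*% Phi2) / st$sigma2)))
      st$Zeta <- Mean + t(backsolve(U2, matrix(stats::rnorm(n_obs * K2), K2, n_obs)))
      W_rows <- st$Zeta %*% t(Phi2)

      ## exact cross-level score translation (per subject, per shape pair)
      E0 <- Y - base_rows - U_rows - W_rows
      ctr <- translate_cross_level(st$Xi, st$Zeta, E0, Phi1, Phi2,
                                   st$lambda1, st$lambda2, st$sigma2,
                                   subj, J)
      st$Xi <- ctr$Xi; st$Zeta <- ctr$Zeta
      U_rows <- st$Xi[subj, , drop = FALSE] %*% t(Phi1)
      W_rows <- st$Zeta %*% t(Phi2)
    }

    ## eigenvalues, smoothing, error variance
    ss1 <- colSums(st$Xi^2)
    for (k in seq_len(K1)) {
      lo <- if (k == 1) 0 else st$lambda1[k - 1]
      up <- if (k == K1) Inf else st$lambda1[k + 1]
      st$lambda1[k] <- rinvgamma_trunc(hp$a_lambda + N / 2,
                                       hp$b_lambda + ss1[k] / 2,
                                       lo, up, st$lambda1[k])
    }
    if (K2 > 0) {
      ss2 <- colSums(st$Zeta^2)
      for (k in seq_len(K2)) {
        lo <- if (k == 1) 0 else st$lambda2[k - 1]
        up <- if (k == K2) Inf else st$lambda2[k + 1]
        st$lambda2[k] <- rinvgamma_trunc(hp$a_lambda + n_obs / 2,
                                         hp$b_lambda + ss2[k] / 2,
                                         lo, up, st$lambda2[k])
      }
    }
    qf1 <- diag(crossprod(st$Psi1, P %*% st$Psi1))
    st$H1 <- stats::rgamma(K1, shape = hp$a_h + Q / 2, rate = b_h + qf1 / 2)
    if (K2 > 0) {
      qf2 <- diag(crossprod(st$Psi2, P %*% st$Psi2))
      st$H2 <- stats::rgamma(K2, shape = hp$a_h + Q / 2, rate = b_h + qf2 / 2)
    }
    SSR <- sum((Y - base_rows - U_rows - W_rows)^2)
    st$sigma2 <- 1 / stats::rgamma(1, shape = hp$a_sigma + n_obs * M / 2,
                                   rate = hp$b_sigma + SSR / 2)

    ## latent matrices via HMC through the polar map (per level)
    ## exact translation moves along the mean/score valleys, then rotation
    ## moves within each level
    tr1 <- translate_mean_scores(st$w_mu, st$Xi, st$Psi1, st$h_mu,
                                 st$lambda1, P)
    st$w_mu <- tr1$w_mu; st$Xi <- tr1$Xi
    if (K2 > 0) {
      tr2 <- translate_mean_scores(st$w_mu, st$Zeta, st$Psi2, st$h_mu,
                                   st$lambda2, P)
      st$w_mu <- tr2$w_mu; st$Zeta <- tr2$Xi
      rot2 <- rotate_pair_move(st$Psi2, st$Zeta, st$X2, st$lambda2, st$H2, P)
      st$Psi2 <- rot2$Psi; st$Zeta <- rot2$Xi; st$X2 <- rot2$X
      W_rows <- st$Zeta %*% t(B %*% st$Psi2)
    }
    rot1 <- rotate_pair_move(st$Psi1, st$Xi, st$X1, st$lambda1, st$H1, P)
    st$Psi1 <- rot1$Psi; st$Xi <- rot1$Xi; st$X1 <- rot1$X
    mu_rows <- matrix(drop(B %*% st$w_mu), n_obs, M, byrow = TRUE)
    base_rows <- mu_rows + eta_rows
    U_rows <- st$Xi[subj, , drop = FALSE] %*% t(B %*% st$Psi1)

    st$X1 <- refresh_polar_radius(st$Psi1)
    if (K2 > 0) st$X2 <- refresh_polar_radius(st$Psi2)
    eps <- if (iter <= config$n_warmup) exp(da1$log_eps) else exp(da1$log_eps_bar)
    Xi_exp <- st$Xi[subj, , drop = FALSE]
    mass1 <- build_x_mass(Xi_exp, st$sigma2, st$H1, BtB, P)
    mass2 <- if (K2 > 0) build_x_mass(st$Zeta, st$sigma2, st$H2, BtB, P) else list()
    mass_w <- chol(n_obs * BtB / st$sigma2 + st$h_mu * P)
    hmc <- hmc_update_ml(st$X1, st$X2, st$w_mu, eps, config$n_leapfrog,
                         Y - eta_rows, Xi_exp, st$Zeta, st$sigma2, st$h_mu,
                         st$H1, st$H2, B, P, mass1, mass2, mass_w)
    st$X1 <- hmc$X1; st$Psi1 <- hmc$Psi1
    if (K2 > 0) { st$X2 <- hmc$X2; st$Psi2 <- hmc$Psi2 }
    st$w_mu <- hmc$w
    n_div <- n_div + hmc$divergent
    acc_sum <- acc_sum + hmc$accept_prob
    if (iter <= config$n_warmup) da1 <- da_update(da1, iter, hmc$accept_prob)

    if (iter > config$n_warmup) {
      j <- iter - config$n_warmup
      keep$sigma2[j] <- st$sigma2
      keep$h_mu[j] <- st$h_mu
      keep$w_mu[j, ] <- st$w_mu
      keep$lambda1[j, ] <- st$lambda1
      keep$H1[j, ] <- st$H1
      keep$Psi1[j, , ] <- st$Psi1
      keep$Xi[j, , ] <- st$Xi
      if (K2 > 0) {
        keep$lambda2[j, ] <- st$lambda2
        keep$H2[j, ] <- st$H2
        keep$Psi2[j, , ] <- st$Psi2
        keep$Zeta[j, , ] <- st$Zeta
      }
      if (use_eta) keep$eta[j, , ] <- st$eta
    }
  }
  keep$diagnostics <- list(accept_rate = acc_sum / config$n_iter,
                           step_size = exp(da1$log_eps_bar),
                           divergences = n_div, seed = seed)
  keep
}

# Exact Gibbs move along the cross-level score valley: when a level-1 shape
# phi1_k and a level-2 shape phi2_l are similar, per-subject score mass can
# sit at either level almost equivalently (add c_i to xi_ik, subtract c_i
# from every zeta_ijl of subject i). The vector of subject shifts c is
# conditionally Gaussian given everything else - the likelihood enters
# through the shape difference d = phi1_k - phi2_l - so the valley is
# traversed in one exact draw per component pair.
translate_cross_level <- function(Xi, Zeta, E, Phi1, Phi2, lambda1, lambda2,
                                  sigma2, subj, J) {
  N <- nrow(Xi)
  for (k in seq_len(ncol(Xi))) {
    for (l in seq_len(ncol(Zeta))) {
      d <- Phi1[, k] - Phi2[, l]
      dd <- sum(d^2)
      prec <- J * dd / sigma2 + 1 / lambda1[k] + J / lambda2[l]
      lin <- drop(rowsum(drop(E %*% d), subj)) / sigma2 -
        Xi[, k] / lambda1[k] + drop(rowsum(Zeta[, l], subj)) / lambda2[l]
      cvec <- stats::rnorm(N, lin / prec, 1 / sqrt(prec))
      Xi[, k] <- Xi[, k] + cvec
      Zeta[, l] <- Zeta[, l] - cvec[subj]
      E <- E - outer(cvec[subj], d)
    }
  }
  list(Xi = Xi, Zeta = Zeta)
}

# Joint Hamiltonian update of (X1, X2, w_mu): both latent matrices and the
# mean coefficients move together so cross-level couplings (shapes that could
# be attributed to either level, and mean/eigenfunction leakage) are
# traversed by the gradient dynamics rather than by alternation.
ml_potential <- function(X1, X2, w, Ybase, Xi_exp, Zeta, sigma2, h_mu,
                         H1, H2, B, P) {
  p1 <- polar_orthonormalize(X1, jitter = TRUE)
  Psi1 <- p1$Psi
  K2 <- ncol(X2)
  Psi2 <- if (K2 > 0) polar_orthonormalize(X2, jitter = TRUE)$Psi else X2
  mu <- drop(B %*% w)
  E <- sweep(Ybase, 2, mu) - Xi_exp %*% t(B %*% Psi1)
  if (K2 > 0) E <- E - Zeta %*% t(B %*% Psi2)
  U <- 0.5 * sum(X1^2) + 0.5 * sum(X2^2) + sum(E^2) / (2 * sigma2) +
    0.5 * sum(H1 * diag(crossprod(Psi1, P %*% Psi1))) +
    0.5 * h_mu * drop(crossprod(w, P %*% w))
  if (K2 > 0) U <- U + 0.5 * sum(H2 * diag(crossprod(Psi2, P %*% Psi2)))
  list(U = U, Psi1 = Psi1, Psi2 = Psi2, E = E)
}

ml_grad <- function(X1, X2, w, Ybase, Xi_exp, Zeta, sigma2, h_mu,
                    H1, H2, B, P) {
  pot <- ml_potential(X1, X2, w, Ybase, Xi_exp, Zeta, sigma2, h_mu,
                      H1, H2, B, P)
  E <- pot$E
  G1 <- t(crossprod(Xi_exp, E) %*% B) / sigma2 -
    P %*% sweep(pot$Psi1, 2, H1, `*`)
  gX1 <- X1 - polar_pullback_grad(X1, G1)
  gX2 <- X2
  if (ncol(X2) > 0) {
    G2 <- t(crossprod(Zeta, E) %*% B) / sigma2 -
      P %*% sweep(pot$Psi2, 2, H2, `*`)
    gX2 <- X2 - polar_pullback_grad(X2, G2)
  }
  gw <- -drop(crossprod(B, colSums(E))) / sigma2 + h_mu * drop(P %*% w)
  list(gX1 = gX1, gX2 = gX2, gw = gw)
}

hmc_update_ml <- function(X1, X2, w, eps, L_max, Ybase, Xi_exp, Zeta, sigma2,
                          h_mu, H1, H2, B, P, mass1, mass2, mass_w) {
  L <- sample(seq(max(1L, ceiling(L_max / 2)), L_max), 1)
  Q <- nrow(X1)
  K2 <- ncol(X2)
  draw_p <- function(mass) {
    p <- mass_momentum(mass, Q)
    if (is.null(dim(p))) matrix(p, Q) else p
  }
  p1 <- draw_p(mass1)
  p2 <- if (K2 > 0) draw_p(mass2) else X2
  pw <- drop(crossprod(mass_w, stats::rnorm(Q)))
  solve_w <- function(v) backsolve(mass_w, forwardsolve(t(mass_w), v))
  kin <- function(p1, p2, pw) {
    0.5 * sum(p1 * mass_solve(mass1, p1)) +
      (if (K2 > 0) 0.5 * sum(p2 * mass_solve(mass2, p2)) else 0) +
      0.5 * sum(pw * solve_w(pw))
  }
  cur <- ml_potential(X1, X2, w, Ybase, Xi_exp, Zeta, sigma2, h_mu,
                      H1, H2, B, P)
  H0 <- cur$U + kin(p1, p2, pw)
  x1 <- X1; x2 <- X2; wv <- w
  g <- ml_grad(x1, x2, wv, Ybase, Xi_exp, Zeta, sigma2, h_mu, H1, H2, B, P)
  divergent <- FALSE
  for (l in seq_len(L)) {
    p1 <- p1 - eps / 2 * g$gX1
    if (K2 > 0) p2 <- p2 - eps / 2 * g$gX2
    pw <- pw - eps / 2 * g$gw
    x1 <- x1 + eps * mass_solve(mass1, p1)
    if (K2 > 0) x2 <- x2 + eps * mass_solve(mass2, p2)
    wv <- wv + eps * solve_w(pw)
    g <- ml_grad(x1, x2, wv, Ybase, Xi_exp, Zeta, sigma2, h_mu, H1, H2, B, P)
    p1 <- p1 - eps / 2 * g$gX1
    if (K2 > 0) p2 <- p2 - eps / 2 * g$gX2
    pw <- pw - eps / 2 * g$gw
    if (!all(is.finite(x1)) || !all(is.finite(wv)) ||
        (K2 > 0 && !all(is.finite(x2)))) {
      divergent <- TRUE; break
    }
  }
  if (!divergent) {
    prop <- ml_potential(x1, x2, wv, Ybase, Xi_exp, Zeta, sigma2, h_mu,
                         H1, H2, B, P)
    H1e <- prop$U + kin(p1, p2, pw)
    if (!is.finite(H1e) || (H1e - H0) > 1000) divergent <- TRUE
  }
  if (divergent) {
    return(list(X1 = X1, X2 = X2, w = w, Psi1 = cur$Psi1, Psi2 = cur$Psi2,
                accept_prob = 0, divergent = TRUE))
  }
  a <- min(1, exp(H0 - H1e))
  if (stats::runif(1) < a) {
    list(X1 = x1, X2 = x2, w = wv, Psi1 = prop$Psi1, Psi2 = prop$Psi2,
         accept_prob = a, divergent = FALSE)
  } else {
    list(X1 = X1, X2 = X2, w = w, Psi1 = cur$Psi1, Psi2 = cur$Psi2,
         accept_prob = a, divergent = FALSE)
  }
}

# Initial state: subject means drive the level-1 eigen-system, within-subject
# deviations the level-2 system; overdispersed across chains as in the
# single-level initializer.
init_mfpca_state <- function(data, basis, config) {
  B <- basis$eval_matrix
  Q <- config$Q; K1 <- config$K1; K2 <- config$K2
  w <- basis$grid$weights
  Y <- data$Y
  proj <- function(Ymat) if (basis$mode == "functional") Ymat %*% (w * B) else Ymat %*% B
  Cf <- proj(Y)
  w_mu <- colMeans(Cf)
  subj_means <- rowsum(Cf, data$subject) / as.vector(data$J)
  Cc1 <- sweep(subj_means, 2, w_mu)
  eg1 <- eigen(crossprod(Cc1) / nrow(Cc1), symmetric = TRUE)
  Psi1 <- eg1$vectors[, K1:1, drop = FALSE]
  lam1 <- pmax(rev(eg1$values[seq_len(K1)]), 1e-6)
  s1 <- sample(c(-1, 1), K1, replace = TRUE)
  Psi1 <- sweep(Psi1, 2, s1, `*`)
  lam1 <- sort(lam1 * exp(stats::rnorm(K1, 0, 0.1)))
  Xi <- Cc1 %*% Psi1
  Cc2 <- Cf - subj_means[data$subject, , drop = FALSE]
  state <- list(sigma2 = 1, w_mu = w_mu, h_mu = 1,
                lambda1 = lam1, H1 = rep(1, K1), Xi = Xi)
  X1 <- Psi1 + matrix(stats::rnorm(Q * K1, 0, 0.1), Q, K1)
  state$X1 <- X1
  state$Psi1 <- polar_orthonormalize(X1, jitter = TRUE)$Psi
  if (K2 > 0) {
    eg2 <- eigen(crossprod(Cc2) / nrow(Cc2), symmetric = TRUE)
    Psi2 <- eg2$vectors[, K2:1, drop = FALSE]
    lam2 <- pmax(rev(eg2$values[seq_len(K2)]), 1e-6)
    s2 <- sample(c(-1, 1), K2, replace = TRUE)
    Psi2 <- sweep(Psi2, 2, s2, `*`)
    lam2 <- sort(lam2 * exp(stats::rnorm(K2, 0, 0.1)))
    state$Zeta <- Cc2 %*% Psi2
    state$lambda2 <- lam2
    state$H2 <- rep(1, K2)
    X2 <- Psi2 + matrix(stats::rnorm(Q * K2, 0, 0.1), Q, K2)
    state$X2 <- X2
    state$Psi2 <- polar_orthonormalize(X2, jitter = TRUE)$Psi
  } else {
    state$Zeta <- matrix(0, data$n_obs, 0)
    state$lambda2 <- numeric(0)
    state$H2 <- numeric(0)
    state$X2 <- matrix(0, Q, 0)
    state$Psi2 <- matrix(0, Q, 0)
  }
  resid <- Y - matrix(drop(B %*% w_mu), data$n_obs, ncol(Y), byrow = TRUE) -
    Xi[data$subject, , drop = FALSE] %*% t(B %*% state$Psi1) -
    (if (K2 > 0) state$Zeta %*% t(B %*% state$Psi2) else 0)
  state$sigma2 <- max(mean(resid^2), 1e-6)
  if (isTRUE(config$eta)) {
    state$eta <- matrix(0, Q, max(data$visit))
    state$h_eta <- 1
  }
  state
}

#' Post-process multilevel draws
#'
#' Applies ordering, sign alignment, orthonormal point estimation, credible
#' bands, percent variance explained, and split-chain diagnostics separately
#' to each level (each level is aligned on its own, sharing the error
#' variance).
#'
#' @param draws a `bfpca_mdraws`.
#' @param level credible level.
#' @param pve_include_noise include `sigma2` in the PVE denominator.
#' @return A list of class `bfpca_mresult` with elements `level1` and
#'   `level2` (each a `bfpca_result`; `level2` is `NULL` when `K2 = 0`),
#'   shared `sigma2` summary, and `max_rhat` across both levels.
#' @export
postprocess_mfpca <- function(draws, level = 0.95, pve_include_noise = FALSE) {
  stopifnot(inherits(draws, "bfpca_mdraws"))
  lvl1 <- as_level_draws(draws, 1L)
  res1 <- postprocess_fpca(lvl1, level = level,
                           pve_include_noise = pve_include_noise)
  res2 <- NULL
  if (draws$dims$K2 > 0) {
    lvl2 <- as_level_draws(draws, 2L)
    res2 <- postprocess_fpca(lvl2, level = level,
                             pve_include_noise = pve_include_noise)
  }
  max_rhat <- max(res1$rhat$max, if (!is.null(res2)) res2$rhat$max else -Inf)
  structure(list(level1 = res1, level2 = res2, sigma2 = res1$sigma2,
                 max_rhat = max_rhat),
            class = "bfpca_mresult")
}

#' @export
print.bfpca_mresult <- function(x, ...) {
  cat(sprintf("<bfpca_mresult> max RHat = %.3f\n-- level 1 --\n", x$max_rhat))
  print(x$level1)
  if (!is.null(x$level2)) { cat("-- level 2 --\n"); print(x$level2) }
  invisible(x)
}

# view one level of multilevel draws as single-level draws so the
# post-processing machinery applies unchanged
as_level_draws <- function(draws, level_idx) {
  pick <- function(ch) {
    if (level_idx == 1L) {
      list(sigma2 = ch$sigma2, h_mu = ch$h_mu, w_mu = ch$w_mu,
           lambda = ch$lambda1, H = ch$H1, Psi = ch$Psi1, Xi = ch$Xi,
           diagnostics = ch$diagnostics)
    } else {
      list(sigma2 = ch$sigma2, h_mu = ch$h_mu, w_mu = ch$w_mu,
           lambda = ch$lambda2, H = ch$H2, Psi = ch$Psi2, Xi = ch$Zeta,
           diagnostics = ch$diagnostics)
    }
  }
  K <- if (level_idx == 1L) draws$dims$K1 else draws$dims$K2
  Nk <- if (level_idx == 1L) draws$dims$N else draws$dims$n_obs
  structure(list(chains = lapply(draws$chains, pick), config = draws$config,
                 basis = draws$basis, penalty = draws$penalty,
                 grid = draws$grid,
                 dims = list(N = Nk, M = draws$dims$M, K = K,
                             Q = draws$dims$Q)),
            class = "bfpca_draws")
}
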
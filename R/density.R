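# Joint posterior density components of the single-level model. A "draw" is a
# named list with elements sigma2, w_mu (Q), h_mu, lambda (K, increasing as
# sampled), H (K), X (Q x K), Psi (Q x K orthonormal), Xi (N x K).

# log density of inverse-Gamma(shape a, scale b) at x > 0
dinvgamma_log <- function(x, a, b) {
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

#' Gaussian log-likelihood of the functional model
#'
#' Evaluates `sum_{i,m} log N(Y[i, m]; mu(t_m) + Theta[i, m], sigma2)` where
#' `mu = B w_mu` and `Theta = Xi t(B Psi)` is the matrix of component
#' contributions.
#'
#' @param draw list with at least `sigma2`, `w_mu`, `Psi`, `Xi`.
#' @param Y `N x M` data matrix on the basis grid.
#' @param basis a `bfpca_basis` whose grid matches `ncol(Y)`.
#' @return The log-likelihood (a scalar).
#' @export
fpca_loglik <- function(draw, Y, basis) {
  B <- basis$eval_matrix
  if (ncol(Y) != nrow(B)) stop("grid mismatch between data and basis", call. = FALSE)
  if (draw$sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  mu <- drop(B %*% draw$w_mu)
  Theta <- draw$Xi %*% t(B %*% draw$Psi)
  R <- sweep(Y, 2, mu) - Theta
  n <- length(Y)
  -n / 2 * log(2 * pi * draw$sigma2) - sum(R^2) / (2 * draw$sigma2)
}

#' Joint log-prior of the single-level model
#'
#' Sum of all prior terms: Gamma priors on the smoothing parameters,
#' inverse-Gamma priors on the eigenvalues and error variance, the mean and
#' component smoothing penalties `(Q/2) log h - (h/2) theta' P_alpha theta`,
#' independent standard-normal terms on the latent matrix `X` (the uniform
#' Stiefel component of the parameter expansion), and `N(0, lambda_k)` terms
#' on the score columns.
#'
#' @param draw parameter draw (see [fpca_loglik()]; additionally `h_mu`,
#'   `lambda`, `H`, `X`).
#' @param penalty a `bfpca_penalty`.
#' @param config a `bfpca_config`.
#' @return The log-prior (a scalar; normalizing constants of the smoothing
#'   penalties beyond the `(Q/2) log h` factor, and the Stiefel volume, are
#'   omitted as in the target posterior).
#' @export
fpca_logprior <- function(draw, penalty, config) {
  P <- penalty$P
  Q <- config$Q
  hp <- config$prior
  b_h <- resolve_b_h(config, penalty)
  if (draw$sigma2 <= 0 || draw$h_mu <= 0 || any(draw$lambda <= 0) ||
      any(draw$H <= 0)) {
    stop("variance and smoothing parameters must be positive", call. = FALSE)
  }
  lp <- sum(stats::dgamma(draw$H, shape = hp$a_h, rate = b_h, log = TRUE))
  lp <- lp + stats::dgamma(draw$h_mu, shape = hp$a_hmu, rate = hp$b_hmu, log = TRUE)
  lp <- lp + sum(dinvgamma_log(draw$lambda, hp$a_lambda, hp$b_lambda))
  lp <- lp + dinvgamma_log(draw$sigma2, hp$a_sigma, hp$b_sigma)
  lp <- lp + Q / 2 * log(draw$h_mu) -
    draw$h_mu / 2 * drop(crossprod(draw$w_mu, P %*% draw$w_mu))
  for (k in seq_along(draw$H)) {
    psi_k <- draw$Psi[, k]
    lp <- lp + Q / 2 * log(draw$H[k]) -
      draw$H[k] / 2 * drop(crossprod(psi_k, P %*% psi_k))
  }
  lp <- lp + sum(stats::dnorm(draw$X, 0, 1, log = TRUE))
  for (k in seq_along(draw$lambda)) {
    lp <- lp + sum(stats::dnorm(draw$Xi[, k], 0, sqrt(draw$lambda[k]), log = TRUE))
  }
  lp
}

#' Conditional log-density of the orthonormal coefficient matrix
#'
#' Evaluates, up to an additive constant, the conditional posterior density of
#' the orthonormal coefficient matrix `Psi` given every other parameter:
#' the exponential-trace expression
#' `tr(t(Xi) R0 B Psi)/sigma2 - tr(t(Psi) t(B) B Psi t(Xi) Xi)/(2 sigma2)
#'  - tr(diag(H) t(Psi) P Psi)/2`
#' with `R0 = Y - 1_N t(B w_mu)` the mean-centered data. This function exists
#' as an independent oracle: for two orthonormal matrices with all other
#' parameters fixed, its difference must equal the difference of the full
#' joint log posterior.
#'
#' @param Psi orthonormal `Q x K` matrix (checked within `1e-6`).
#' @param draw remaining parameters (`sigma2`, `w_mu`, `H`, `Xi`).
#' @param Y data matrix.
#' @param basis a `bfpca_basis`.
#' @param penalty a `bfpca_penalty`.
#' @return Scalar log-density up to an additive constant.
#' @export
psi_conditional_logdensity <- function(Psi, draw, Y, basis, penalty) {
  if (max(abs(crossprod(Psi) - diag(ncol(Psi)))) > 1e-6) {
    stop("Psi is not orthonormal within 1e-6", call. = FALSE)
  }
  B <- basis$eval_matrix
  R0 <- sweep(Y, 2, drop(B %*% draw$w_mu))
  s2 <- draw$sigma2
  term1 <- sum(diag(crossprod(draw$Xi, R0 %*% B %*% Psi))) / s2
  BPsi <- B %*% Psi
  term2 <- -sum(diag(crossprod(BPsi) %*% crossprod(draw$Xi))) / (2 * s2)
  term3 <- -sum(draw$H * diag(crossprod(Psi, penalty$P %*% Psi))) / 2
  term1 + term2 + term3
}
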
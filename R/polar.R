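#' Orthonormal factor of the polar decomposition
#'
#' Factors a full-column-rank `Q x K` matrix `X` as `X = Psi %*% Pfac` with
#' `Psi` orthonormal (a point on the Stiefel manifold) and `Pfac` symmetric
#' positive semi-definite. The computation follows the eigendecomposition
#' route: with `t(X) X = Z D t(Z)`, `Psi = X Z D^{-1/2} t(Z)` and
#' `Pfac = t(Psi) X`. When the entries of `X` are independent standard
#' normals, `Psi` is uniformly distributed on the Stiefel manifold, which is
#' the basis of the parameter-expansion sampler.
#'
#' @param X numeric matrix with `nrow(X) >= ncol(X)` and full column rank.
#' @param jitter if `TRUE`, a relative `1e-12` ridge is added to the spectrum
#'   of `t(X) X` instead of failing when `X` is numerically rank deficient
#'   (used inside the sampler); the event is signalled via the
#'   `"jittered"` attribute of the result.
#' @return A list with components `Psi` (orthonormal `Q x K`) and `Pfac`
#'   (symmetric PSD `K x K`).
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' p <- polar_orthonormalize(X)
#' max(abs(crossprod(p$Psi) - diag(4)))       # ~1e-15
#' max(abs(p$Psi %*% p$Pfac - X))             # ~1e-15
#' @export
polar_orthonormalize <- function(X, jitter = FALSE) {
  X <- as.matrix(X)
  K <- ncol(X)
  if (nrow(X) < K) stop("X must have at least as many rows as columns", call. = FALSE)
  A <- crossprod(X)
  e <- eigen(A, symmetric = TRUE)
  d <- e$values
  jittered <- FALSE
  if (d[K] <= 1e-12 * max(d[1], .Machine$double.eps)) {
    if (!jitter) {
      stop(sprintf(
        "X is numerically rank deficient: smallest eigenvalue of t(X)X is %.3e (largest %.3e)",
        d[K], d[1]), call. = FALSE)
    }
    d <- d + 1e-12 * max(d[1], 1)
    jittered <- TRUE
  }
  Z <- e$vectors
  inv_sqrt <- Z %*% (t(Z) * (1 / sqrt(d)))
  Psi <- X %*% inv_sqrt
  Pfac <- crossprod(Psi, X)
  Pfac <- (Pfac + t(Pfac)) / 2
  out <- list(Psi = Psi, Pfac = Pfac)
  attr(out, "jittered") <- jittered
  out
}

# Gradient of a scalar function of Psi(X) with respect to X, where Psi is the
# orthonormal polar factor. `G` is d(loss)/d(Psi). Uses the Fréchet derivative
# of A^{-1/2} (A = t(X)X = Z D t(Z)) via divided differences of f(x) = x^{-1/2}
# on the spectrum.
polar_pullback_grad <- function(X, G) {
  A <- crossprod(X)
  e <- eigen(A, symmetric = TRUE)
  d <- pmax(e$values, 1e-300)
  Z <- e$vectors
  s <- 1 / sqrt(d)
  Sm <- Z %*% (t(Z) * s)              # A^{-1/2}
  # divided-difference matrix for f(x) = x^{-1/2}
  K <- length(d)
  F_mat <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (abs(d[i] - d[j]) > 1e-12 * max(d[i], d[j])) {
        F_mat[i, j] <- (s[i] - s[j]) / (d[i] - d[j])
      } else {
        dm <- (d[i] + d[j]) / 2
        F_mat[i, j] <- -0.5 * dm^(-1.5)
      }
    }
  }
  M0 <- crossprod(X, G)               # K x K
  Nbar <- Z %*% (F_mat * (crossprod(Z, M0) %*% Z)) %*% t(Z)
  G %*% Sm + X %*% (Nbar + t(Nbar))
}
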
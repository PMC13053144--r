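#' Orthonormal spline basis with explicit intercept and slope
#'
#' Constructs a `Q`-dimensional basis for functions on `[0, 1]` whose first two
#' elements span constants and linear trends and whose remaining elements are
#' cubic B-splines on equally spaced interior knots, orthonormalized against
#' the chosen inner product. In `"functional"` mode (the default) the inner
#' product is the `L2([0,1])` scalar product evaluated on an internal fine
#' Gauss-Legendre quadrature, so the Gram matrix of the basis functions is the
#' identity; in `"vector"` mode the inner product is the plain Euclidean one on
#' the data grid, so the evaluation matrix `B` satisfies `t(B) %*% B = I`.
#'
#' Starting from the raw design `[1, t, B-splines of dimension Q]` (which has
#' rank exactly `Q` because the full B-spline system already contains constants
#' and linear trends), a modified Gram-Schmidt sweep in that order keeps the
#' first `Q` independent directions; the two redundant spline columns are
#' dropped. The output therefore retains the temporal localization of
#' B-splines away from the two leading polynomial terms.
#'
#' @param grid a `bfpca_grid` (see [make_grid()]).
#' @param Q basis dimension, `4 <= Q <= M`.
#' @param mode `"functional"` (L2 orthonormality) or `"vector"` (`t(B) B = I`
#'   on the data grid).
#' @param fine_n number of Gauss-Legendre nodes of the internal fine quadrature
#'   used for orthonormalization and integrals; default `max(1000, 20 * Q)`.
#' @return An object of class `bfpca_basis` with elements `Q`, `mode`,
#'   `eval_matrix` (M x Q), `evaluator(t)` returning basis values at arbitrary
#'   `t`, `deriv2(t)` returning second derivatives, `fine_grid`
#'   (nodes/weights), `grid`, and the transform from the raw design.
#' @examples
#' g <- make_grid(50)
#' b <- build_basis(g, Q = 12)
#' Bf <- b$evaluator(b$fine_grid$points)
#' max(abs(crossprod(Bf, b$fine_grid$weights * Bf) - diag(12))) # ~1e-14
#' @export
build_basis <- function(grid, Q = 20,
                        mode = c("functional", "vector"),
                        fine_n = NULL) {
  stopifnot(inherits(grid, "bfpca_grid"))
  mode <- match.arg(mode)
  M <- length(grid$points)
  if (!is.numeric(Q) || length(Q) != 1L || Q < 4 || Q != round(Q)) {
    stop("`Q` must be a single integer >= 4", call. = FALSE)
  }
  if (Q > M) {
    stop(sprintf("basis dimension Q = %d exceeds grid size M = %d", Q, M),
         call. = FALSE)
  }
  if (is.null(fine_n)) fine_n <- max(1000L, 20L * Q)

  # Raw design: intercept, slope, full cubic B-spline system of dimension Q
  # (Q - 4 equally spaced interior knots).
  n_interior <- Q - 4L
  interior <- if (n_interior > 0) seq(0, 1, length.out = n_interior + 2L)[-c(1L, n_interior + 2L)] else numeric(0)
  knots <- c(rep(0, 4), interior, rep(1, 4))
  design <- function(t) {
    t <- pmin(pmax(t, 0), 1)
    cbind(1, t, splines::splineDesign(knots, t, ord = 4L, outer.ok = FALSE))
  }
  design_d2 <- function(t) {
    t <- pmin(pmax(t, 0), 1)
    cbind(0, 0, splines::splineDesign(knots, t, ord = 4L, derivs = 2L))
  }

  fine_grid <- gauss_legendre_rule(fine_n)

  if (mode == "functional") {
    ip_eval <- design(fine_grid$points)
    ip_w <- fine_grid$weights
  } else {
    ip_eval <- design(grid$points)
    ip_w <- rep(1, M)
  }

  T_mat <- gram_schmidt_transform(ip_eval, ip_w, Q)

  eval_matrix <- design(grid$points) %*% T_mat
  evaluator <- function(t) design(t) %*% T_mat
  deriv2 <- function(t) design_d2(t) %*% T_mat

  structure(list(Q = Q, mode = mode,
                 eval_matrix = eval_matrix,
                 evaluator = evaluator,
                 deriv2 = deriv2,
                 transform = T_mat,
                 knots = knots,
                 fine_grid = fine_grid,
                 grid = grid),
            class = "bfpca_basis")
}

# Modified Gram-Schmidt (two passes per column for numerical stability) on the
# columns of `E` under the inner product <u, v> = sum(w * u * v). Keeps the
# first `Q` independent directions and returns the (ncol(E) x Q) coefficient
# matrix T such that E %*% T has orthonormal columns.
gram_schmidt_transform <- function(E, w, Q) {
  p <- ncol(E)
  kept_vec <- matrix(0, nrow(E), 0)
  kept_T <- matrix(0, p, 0)
  tol <- 1e-10
  for (j in seq_len(p)) {
    v <- E[, j]
    e <- numeric(p); e[j] <- 1
    nrm0 <- sum(w * v * v)
    for (pass in 1:2) {
      if (ncol(kept_vec) > 0) {
        cf <- drop(crossprod(kept_vec, w * v))
        v <- v - drop(kept_vec %*% cf)
        e <- e - drop(kept_T %*% cf)
      }
    }
    nrm <- sum(w * v * v)
    if (nrm > tol * max(nrm0, 1)) {
      v <- v / sqrt(nrm)
      e <- e / sqrt(nrm)
      kept_vec <- cbind(kept_vec, v)
      kept_T <- cbind(kept_T, e)
      if (ncol(kept_T) == Q) break
    }
  }
  if (ncol(kept_T) != Q) {
    stop(sprintf(
      "orthonormalization found only %d independent directions (needed %d); the design is rank deficient on this grid",
      ncol(kept_T), Q), call. = FALSE)
  }
  kept_T
}

#' @export
print.bfpca_basis <- function(x, ...) {
  cat(sprintf("<bfpca_basis> Q = %d, mode = %s, grid M = %d\n",
              x$Q, x$mode, length(x$grid$points)))
  invisible(x)
}

#' Gram matrix of second derivatives of the basis
#'
#' Computes `S[i, j] = \int_0^1 B_i''(t) B_j''(t) dt` by fine Gauss-Legendre
#' quadrature of the analytically differentiated basis (second derivatives of
#' cubic splines are piecewise linear, so the quadrature is essentially exact).
#' This is the curvature block of the mixed smoothing penalty.
#'
#' @param basis a `bfpca_basis`.
#' @return A symmetric positive semi-definite `Q x Q` matrix.
#' @export
second_derivative_gram <- function(basis) {
  stopifnot(inherits(basis, "bfpca_basis"))
  # piecewise-linear integrand: use a dedicated dense rule so segment
  # boundaries are well resolved
  n <- max(2000L, 40L * basis$Q)
  gl <- gauss_legendre_rule(n)
  D2 <- basis$deriv2(gl$points)
  S <- crossprod(D2, gl$weights * D2)
  (S + t(S)) / 2
}

#' Mixed smoothing-penalty matrix
#'
#' Assembles `P_alpha = alpha * G0 + (1 - alpha) * S`, the matrix of the
#' quadratic form `alpha \int f(t)^2 dt + (1 - alpha) \int f''(t)^2 dt` in the
#' basis coefficients, where `G0` is the L2 Gram matrix of the basis (the
#' identity in functional mode) and `S` the second-derivative Gram matrix.
#' `alpha = 0` is the classic penalized-spline curvature penalty; the model
#' default is `alpha = 0.1`.
#'
#' @param basis a `bfpca_basis`.
#' @param alpha penalty weight in `[0, 1]`.
#' @return An object of class `bfpca_penalty` with elements `P` (symmetric
#'   `Q x Q`), `alpha`, `rank`, and `trace`.
#' @export
build_penalty <- function(basis, alpha = 0.1) {
  stopifnot(inherits(basis, "bfpca_basis"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single value in [0, 1]", call. = FALSE)
  }
  fg <- basis$fine_grid
  Bf <- basis$evaluator(fg$points)
  G0 <- crossprod(Bf, fg$weights * Bf)
  G0 <- (G0 + t(G0)) / 2
  S <- second_derivative_gram(basis)
  P <- alpha * G0 + (1 - alpha) * S
  P <- (P + t(P)) / 2
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  rank <- sum(ev > max(abs(ev)) * 1e-10)
  structure(list(P = P, alpha = alpha, rank = rank, trace = sum(diag(P))),
            class = "bfpca_penalty")
}

#' @export
print.bfpca_penalty <- function(x, ...) {
  cat(sprintf("<bfpca_penalty> alpha = %.3g, Q = %d, rank = %d, trace = %.6g\n",
              x$alpha, nrow(x$P), x$rank, x$trace))
  invisible(x)
}

#' Write or read a numeric matrix as plain text
#'
#' Basis evaluations and penalty matrices round-trip through plain
#' comma-separated files (one row per line, full double precision) so that a
#' fit is reproducible bit-for-bit across runs.
#'
#' @param x numeric matrix.
#' @param path file path.
#' @return `read_matrix` returns the matrix; `write_matrix` the path,
#'   invisibly.
#' @export
write_matrix <- function(x, path) {
  utils::write.table(format(x, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                              colClasses = "numeric"))
}
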
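#' Shifted Legendre polynomials on the unit interval
#'
#' Evaluates the (unnormalized) shifted Legendre polynomial
#' `P_k(2t - 1)` at points of `[0, 1]`: `f_0 = 1`, `f_1(t) = 2t - 1`,
#' `f_2(t) = 6t^2 - 6t + 1`, `f_3(t) = 20t^3 - 30t^2 + 12t - 1`, and so on by
#' the Bonnet recurrence. These satisfy `\int_0^1 f_k^2 = 1 / (2k + 1)` and
#' mutual orthogonality, and are the building blocks of the simulation truth.
#'
#' @param k polynomial degree (nonnegative integer).
#' @param t evaluation points in `[0, 1]`.
#' @return Numeric vector of values.
#' @export
shifted_legendre <- function(k, t) {
  if (k < 0 || k != round(k)) stop("`k` must be a nonnegative integer", call. = FALSE)
  u <- 2 * t - 1
  p_prev <- rep(1, length(u))
  if (k == 0) return(p_prev)
  p <- u
  if (k == 1) return(p)
  for (n in 1:(k - 1)) {
    p_next <- ((2 * n + 1) * u * p - n * p_prev) / (n + 1)
    p_prev <- p
    p <- p_next
  }
  p
}

#' Built-in simulation scenarios
#'
#' `scenario_s1()` emulates dense continuous glucose monitoring curves: mean
#' `mu(t) = 140 - 20 f_2(t)`, error variance `sigma2 = 4`, eigenvalues
#' `(2250, 450, 150)`, and eigenfunctions `phi_1 = f_0`,
#' `phi_2 = sqrt(84/31) (f_1 - 0.5 f_3)`, `phi_3 = -sqrt(5) f_2` built from
#' shifted Legendre polynomials (the normalizing constants make each function
#' unit-norm in L2). The mean is a linear combination of `phi_1` and `phi_3`
#' (`mu = 140 phi_1 + 4 sqrt(5) phi_3`), which makes the third component
#' deliberately hard. `scenario_s2()` is the canonical trigonometric example:
#' zero mean, `sigma2 = 0.35`, eigenvalues `(1, 0.5, 0.25)`, eigenfunctions
#' `sqrt(2) sin(2 pi t)`, `sqrt(2) cos(4 pi t)`, `sqrt(2) sin(4 pi t)`.
#' Orthonormality of every built-in eigen-system is asserted at construction
#' on a dense quadrature, so a misread constant cannot pass silently.
#'
#' @param N number of curves (default 50).
#' @param M grid size (default 50).
#' @param grid_scheme quadrature scheme for the observation grid.
#' @return An object of class `bfpca_scenario`: list with `mean_fn`,
#'   `eigen_fns` (list of K functions), `eigenvalues`, `sigma2`, `N`, `M`,
#'   `grid_scheme`, `name`.
#' @export
scenario_s1 <- function(N = 50, M = 50, grid_scheme = "gauss-legendre") {
  phi2_const <- sqrt(84 / 31)
  spec <- new_scenario(
    name = "s1",
    mean_fn = function(t) 140 - 20 * shifted_legendre(2, t),
    eigen_fns = list(
      function(t) shifted_legendre(0, t),
      function(t) phi2_const * (shifted_legendre(1, t) - 0.5 * shifted_legendre(3, t)),
      function(t) -sqrt(5) * shifted_legendre(2, t)
    ),
    eigenvalues = c(2250, 450, 150),
    sigma2 = 4, N = N, M = M, grid_scheme = grid_scheme)
  spec
}

#' @rdname scenario_s1
#' @export
scenario_s2 <- function(N = 50, M = 50, grid_scheme = "gauss-legendre") {
  new_scenario(
    name = "s2",
    mean_fn = function(t) rep(0, length(t)),
    eigen_fns = list(
      function(t) sqrt(2) * sin(2 * pi * t),
      function(t) sqrt(2) * cos(4 * pi * t),
      function(t) sqrt(2) * sin(4 * pi * t)
    ),
    eigenvalues = c(1, 0.5, 0.25),
    sigma2 = 0.35, N = N, M = M, grid_scheme = grid_scheme)
}

#' Assemble and validate a simulation truth
#'
#' Builds a scenario object from arbitrary mean/eigenfunction specifications
#' and verifies on a 10000-point Gauss-Legendre quadrature that the
#' eigenfunctions are orthonormal in L2 within `1e-6`, that the eigenvalues
#' are strictly decreasing and positive, and that `sigma2 > 0`.
#'
#' @param name scenario label.
#' @param mean_fn vectorized mean function on `[0, 1]`.
#' @param eigen_fns list of vectorized eigenfunctions.
#' @param eigenvalues strictly decreasing positive values, one per function.
#' @param sigma2 error variance.
#' @param N,M default curve count and grid size.
#' @param grid_scheme quadrature scheme label.
#' @return A `bfpca_scenario`.
#' @export
new_scenario <- function(name, mean_fn, eigen_fns, eigenvalues, sigma2,
                         N = 50, M = 50, grid_scheme = "gauss-legendre") {
  K <- length(eigen_fns)
  stopifnot(length(eigenvalues) == K)
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  if (any(eigenvalues <= 0) || any(diff(eigenvalues) >= 0)) {
    stop("eigenvalues must be positive and strictly decreasing", call. = FALSE)
  }
  gl <- gauss_legendre_rule(10000)
  Phi <- vapply(eigen_fns, function(f) f(gl$points), numeric(length(gl$points)))
  G <- crossprod(Phi, gl$weights * Phi)
  if (max(abs(G - diag(K))) > 1e-6) {
    stop(sprintf(
      "eigen-system is not orthonormal in L2: max Gram deviation %.3e",
      max(abs(G - diag(K)))), call. = FALSE)
  }
  structure(list(name = name, mean_fn = mean_fn, eigen_fns = eigen_fns,
                 eigenvalues = eigenvalues, sigma2 = sigma2,
                 N = N, M = M, grid_scheme = grid_scheme, K = K),
            class = "bfpca_scenario")
}

#' @export
print.bfpca_scenario <- function(x, ...) {
  cat(sprintf("<bfpca_scenario> %s: K = %d, lambda = (%s), sigma2 = %.3g, N = %d, M = %d\n",
              x$name, x$K, paste(x$eigenvalues, collapse = ", "), x$sigma2,
              x$N, x$M))
  invisible(x)
}

#' Simulate a dataset from a scenario
#'
#' Draws `Y = 1 mu' + Xi t(Phi) + E` on the scenario's observation grid:
#' scores `xi_ik ~ N(0, lambda_k)`, noise `N(0, sigma2)` i.i.d. The result is
#' bit-reproducible given `seed`.
#'
#' @param spec a `bfpca_scenario`.
#' @param seed integer seed.
#' @param N,M optional overrides of the scenario's defaults.
#' @return A list of class `bfpca_simdata`: `Y` (`N x M`), `grid`,
#'   `true_scores` (`N x K`), `truth` (the scenario), `seed`.
#' @export
simulate_scenario <- function(spec, seed, N = NULL, M = NULL) {
  stopifnot(inherits(spec, "bfpca_scenario"))
  if (!is.null(N)) spec$N <- N
  if (!is.null(M)) spec$M <- M
  grid <- make_grid(spec$M, spec$grid_scheme)
  mu <- spec$mean_fn(grid$points)
  Phi <- vapply(spec$eigen_fns, function(f) f(grid$points), numeric(spec$M))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_seed(old_seed))
  set.seed(seed)
  Xi <- matrix(stats::rnorm(spec$N * spec$K), spec$N, spec$K) %*%
    diag(sqrt(spec$eigenvalues), spec$K)
  E <- matrix(stats::rnorm(spec$N * spec$M, sd = sqrt(spec$sigma2)),
              spec$N, spec$M)
  Y <- matrix(mu, spec$N, spec$M, byrow = TRUE) + Xi %*% t(Phi) + E
  structure(list(Y = Y, grid = grid, true_scores = Xi, truth = spec,
                 seed = seed),
            class = "bfpca_simdata")
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Simulate nested two-level functional data
#'
#' Draws `Y_ij = mu + U_i + W_ij + eps` for subjects `i = 1..N` with `J`
#' visits each, where `U_i` uses the level-1 eigen-system of `spec1` and
#' `W_ij` the level-2 eigen-system of `spec2`; the mean and error variance
#' are taken from `spec1`. The two levels are mutually independent. The
#' default truths (documented stand-ins modeled on the dense-CGM scenario)
#' use `lambda1 = (2250, 450)`, `lambda2 = (900, 300, 100)`, `sigma2 = 4`.
#'
#' @param spec1 level-1 truth (`bfpca_scenario`).
#' @param spec2 level-2 truth (`bfpca_scenario`); its `sigma2` is ignored.
#'   `NULL` drops the visit-level deviations entirely, in which case the
#'   generator with `J = 1` coincides draw-for-draw with
#'   [simulate_scenario()] at the same seed.
#' @param N subjects; `J` visits per subject (scalar or length-`N`).
#' @param seed integer seed.
#' @param M grid size override.
#' @return A list of class `bfpca_simdata_ml`: `Y` (`sum(J) x M`), `subject`,
#'   `visit`, `grid`, `true_scores1` (`N x K1`), `true_scores2`
#'   (`sum(J) x K2`), `truth1`, `truth2`, `seed`.
#' @export
simulate_multilevel <- function(spec1 = scenario_ml1(), spec2 = scenario_ml2(),
                                N = 50, J = 3, seed = 1, M = NULL) {
  stopifnot(inherits(spec1, "bfpca_scenario"))
  has_l2 <- !is.null(spec2)
  if (has_l2) stopifnot(inherits(spec2, "bfpca_scenario"))
  if (!is.null(M)) { spec1$M <- M; if (has_l2) spec2$M <- M }
  if (has_l2 && spec1$M != spec2$M) {
    stop("level truths must share the grid", call. = FALSE)
  }
  J <- rep(J, length.out = N)
  n_obs <- sum(J)
  grid <- make_grid(spec1$M, spec1$grid_scheme)
  mu <- spec1$mean_fn(grid$points)
  Phi1 <- vapply(spec1$eigen_fns, function(f) f(grid$points), numeric(spec1$M))
  Phi2 <- if (has_l2) {
    vapply(spec2$eigen_fns, function(f) f(grid$points), numeric(spec2$M))
  } else {
    matrix(0, spec1$M, 0)
  }
  subject <- rep(seq_len(N), J)
  visit <- unlist(lapply(J, seq_len))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_seed(old_seed))
  set.seed(seed)
  Xi <- matrix(stats::rnorm(N * spec1$K), N, spec1$K) %*%
    diag(sqrt(spec1$eigenvalues), spec1$K)
  Zeta <- if (has_l2) {
    matrix(stats::rnorm(n_obs * spec2$K), n_obs, spec2$K) %*%
      diag(sqrt(spec2$eigenvalues), spec2$K)
  } else {
    matrix(0, n_obs, 0)
  }
  E <- matrix(stats::rnorm(n_obs * spec1$M, sd = sqrt(spec1$sigma2)),
              n_obs, spec1$M)
  Y <- matrix(mu, n_obs, spec1$M, byrow = TRUE) +
    Xi[subject, , drop = FALSE] %*% t(Phi1) + Zeta %*% t(Phi2) + E
  structure(list(Y = Y, subject = subject, visit = visit, grid = grid,
                 true_scores1 = Xi, true_scores2 = Zeta,
                 truth1 = spec1, truth2 = spec2, seed = seed),
            class = "bfpca_simdata_ml")
}

#' @rdname simulate_multilevel
#' @export
scenario_ml1 <- function(N = 50, M = 50) {
  phi2_const <- sqrt(84 / 31)
  new_scenario(
    name = "ml1",
    mean_fn = function(t) 140 - 20 * shifted_legendre(2, t),
    eigen_fns = list(
      function(t) shifted_legendre(0, t),
      function(t) phi2_const * (shifted_legendre(1, t) - 0.5 * shifted_legendre(3, t))
    ),
    eigenvalues = c(2250, 450), sigma2 = 4, N = N, M = M)
}

#' @rdname simulate_multilevel
#' @export
scenario_ml2 <- function(N = 50, M = 50) {
  new_scenario(
    name = "ml2",
    mean_fn = function(t) rep(0, length(t)),
    eigen_fns = list(
      function(t) sqrt(2) * sin(2 * pi * t),
      function(t) sqrt(2) * cos(4 * pi * t),
      function(t) sqrt(2) * sin(4 * pi * t)
    ),
    eigenvalues = c(900, 300, 100), sigma2 = 4, N = N, M = M)
}
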
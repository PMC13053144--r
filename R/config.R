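#' Sampler and prior configuration
#'
#' Collects every tunable of the single-level model and sampler. Defaults
#' follow the model's reference settings: `K = 3` components, `Q = 20` basis
#' functions, mixed-penalty weight `alpha = 0.1`, 4 chains of 1500 iterations
#' with the first 1000 discarded as warm-up.
#'
#' Prior hyperparameters (shape/rate parameterization throughout):
#' inverse-Gamma(0.001, 0.001) on the error variance and each eigenvalue,
#' Gamma(0.001, 0.001) on the mean smoothing parameter, and
#' Gamma(0.01, trace(P_alpha)/2 + 0.01) on each component smoothing
#' parameter. The component-smoothing rate `b_h` must exceed
#' `trace(P_alpha)/2` for the joint prior on the coefficient matrix and its
#' smoothing parameters to be proper; this is enforced whenever the penalty
#' is known (at construction if `penalty` is supplied, and always at fit
#' time).
#'
#' @param K number of principal components.
#' @param Q basis dimension (`K <= Q`).
#' @param alpha penalty weight in `[0, 1]`.
#' @param n_iter total iterations per chain.
#' @param n_warmup warm-up iterations discarded (`n_warmup < n_iter`).
#' @param n_chains number of chains.
#' @param seed integer master seed; per-chain seeds are derived from it.
#' @param mode basis orthonormality mode, `"functional"` or `"vector"`.
#' @param prior optional named list overriding hyperparameters `a_sigma`,
#'   `b_sigma`, `a_lambda`, `b_lambda`, `a_hmu`, `b_hmu`, `a_h`, `b_h`
#'   (`b_h = NULL` means `trace(P_alpha)/2 + 0.01`, resolved at fit time).
#' @param n_leapfrog leapfrog steps of the Hamiltonian update for the latent
#'   coefficient matrix.
#' @param target_accept dual-averaging target acceptance rate.
#' @param penalty optional `bfpca_penalty`; if given, the propriety condition
#'   on `b_h` is checked immediately.
#' @return An object of class `bfpca_config`.
#' @export
fpca_config <- function(K = 3, Q = 20, alpha = 0.1,
                        n_iter = 1500, n_warmup = 1000, n_chains = 4,
                        seed = 1, mode = c("functional", "vector"),
                        prior = list(), n_leapfrog = 16,
                        target_accept = 0.8, penalty = NULL) {
  mode <- match.arg(mode)
  if (K < 1 || K != round(K)) stop("`K` must be a positive integer", call. = FALSE)
  if (K > Q) stop(sprintf("K = %d exceeds the basis dimension Q = %d", K, Q), call. = FALSE)
  if (n_warmup >= n_iter) stop("`n_warmup` must be smaller than `n_iter`", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  hyper <- list(a_sigma = 0.001, b_sigma = 0.001,
                a_lambda = 0.001, b_lambda = 0.001,
                a_hmu = 0.001, b_hmu = 0.001,
                a_h = 0.01, b_h = NULL)
  unknown <- setdiff(names(prior), names(hyper))
  if (length(unknown)) stop("unknown prior hyperparameters: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  hyper[names(prior)] <- prior
  fixed <- hyper[setdiff(names(hyper), "b_h")]
  if (any(unlist(fixed) <= 0)) stop("all prior hyperparameters must be > 0", call. = FALSE)
  cfg <- structure(list(K = as.integer(K), Q = as.integer(Q), alpha = alpha,
                        n_iter = as.integer(n_iter),
                        n_warmup = as.integer(n_warmup),
                        n_chains = as.integer(n_chains),
                        seed = as.integer(seed), mode = mode,
                        prior = hyper, n_leapfrog = as.integer(n_leapfrog),
                        target_accept = target_accept),
                   class = "bfpca_config")
  if (!is.null(penalty)) check_propriety(cfg, penalty)
  cfg
}

# Propriety of the joint prior on (Psi, H): the Gamma rate on the component
# smoothing parameters must exceed trace(P_alpha)/2.
check_propriety <- function(config, penalty) {
  b_h <- resolve_b_h(config, penalty)
  if (b_h <= penalty$trace / 2) {
    stop(sprintf(
      paste0("improper joint prior on the coefficient matrix and its smoothing ",
             "parameters: the smoothing-rate hyperparameter b_h = %.6g must ",
             "exceed trace(P_alpha)/2 = %.6g"),
      b_h, penalty$trace / 2), call. = FALSE)
  }
  invisible(b_h)
}

resolve_b_h <- function(config, penalty) {
  b_h <- config$prior$b_h
  if (is.null(b_h)) b_h <- penalty$trace / 2 + 0.01
  b_h
}

#' @export
print.bfpca_config <- function(x, ...) {
  cat(sprintf(paste0("<bfpca_config> K = %d, Q = %d, alpha = %.3g, mode = %s\n",
                     "  %d chains x %d iterations (%d warm-up), seed %d\n"),
              x$K, x$Q, x$alpha, x$mode,
              x$n_chains, x$n_iter, x$n_warmup, x$seed))
  invisible(x)
}

#' Multilevel model configuration
#'
#' Same tunables as [fpca_config()] with two component counts: `K1`
#' subject-level and `K2` visit-level components (`K1 + K2 <= Q`). Both
#' levels reuse the single-level smoothing hyperpriors. `K2 = 0` drops the
#' visit-level block entirely. `eta` enables penalized-spline visit-specific
#' mean deviations (disabled by default).
#'
#' @inheritParams fpca_config
#' @param K1,K2 components at the subject and subject/visit level.
#' @param eta logical: include visit-specific mean deviation curves.
#' @return An object of class `bfpca_mconfig` (also `bfpca_config`).
#' @export
mfpca_config <- function(K1 = 2, K2 = 3, Q = 20, alpha = 0.1,
                         n_iter = 1500, n_warmup = 1000, n_chains = 4,
                         seed = 1, mode = c("functional", "vector"),
                         prior = list(), n_leapfrog = 16,
                         target_accept = 0.8, eta = FALSE, penalty = NULL) {
  if (K2 < 0 || K2 != round(K2)) stop("`K2` must be a nonnegative integer", call. = FALSE)
  if (K1 + K2 > Q) {
    stop(sprintf("K1 + K2 = %d exceeds the basis dimension Q = %d", K1 + K2, Q),
         call. = FALSE)
  }
  cfg <- fpca_config(K = max(K1, 1), Q = Q, alpha = alpha, n_iter = n_iter,
                     n_warmup = n_warmup, n_chains = n_chains, seed = seed,
                     mode = mode, prior = prior, n_leapfrog = n_leapfrog,
                     target_accept = target_accept, penalty = penalty)
  cfg$K1 <- as.integer(K1)
  cfg$K2 <- as.integer(K2)
  cfg$K <- NULL
  cfg$eta <- isTRUE(eta)
  class(cfg) <- c("bfpca_mconfig", "bfpca_config")
  cfg
}
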
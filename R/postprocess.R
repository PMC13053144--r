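# Post-processing: the FPCA likelihood is invariant to permuting components
# (with their eigenvalues, smoothing parameters, and score columns) and to
# jointly negating an eigenfunction and its scores. Draws are therefore
# re-indexed by decreasing score variance and sign-aligned to a common
# reference before any summary or diagnostic is computed.

#' Re-order components by score variance
#'
#' Within each retained draw, components are permuted (eigenvalues,
#' smoothing parameters, coefficient columns, and score columns jointly)
#' into decreasing order of the draw's cross-sectional score sample
#' variance `var_i(xi_ik)`. A per-draw permutation - rather than one global
#' reordering - also repairs label switching between components of similar
#' eigenvalue within a chain. Ties are broken by the original index. The
#' reconstruction `Xi t(B Psi)` of every draw is exactly invariant.
#'
#' @param draws a `bfpca_draws` (or already aligned draws).
#' @return Aligned draws of class `bfpca_aligned` carrying the applied
#'   permutations (`$permutations`, per chain an `n_draws x K` matrix) and,
#'   after [align_signs()], the per-draw sign vectors.
#' @export
order_components <- function(draws) {
  stopifnot(inherits(draws, c("bfpca_draws", "bfpca_aligned")))
  K <- draws$dims$K
  out <- draws
  out$permutations <- list()
  for (c in seq_along(out$chains)) {
    ch <- out$chains[[c]]
    n <- length(ch$sigma2)
    N <- dim(ch$Xi)[2]
    v <- matrix(0, n, K)
    for (k in seq_len(K)) {
      m <- matrix(ch$Xi[, , k], n)
      v[, k] <- (rowSums(m^2) - N * rowMeans(m)^2) / (N - 1)
    }
    perms <- matrix(0L, n, K)
    for (j in seq_len(n)) {
      p <- order(v[j, ], decreasing = TRUE)
      perms[j, ] <- p
      if (!identical(p, seq_len(K))) {
        ch$lambda[j, ] <- ch$lambda[j, p]
        ch$H[j, ] <- ch$H[j, p]
        ch$Psi[j, , ] <- ch$Psi[j, , p]
        ch$Xi[j, , ] <- ch$Xi[j, , p]
      }
    }
    ch$permutations <- perms
    out$chains[[c]] <- ch
    out$permutations[[c]] <- perms
  }
  if (!inherits(out, "bfpca_aligned")) class(out) <- c("bfpca_aligned", class(out))
  out
}

#' Align eigenfunction signs across draws
#'
#' For every retained draw and component, applies the sign that maximizes the
#' Pearson correlation (over grid points) between the drawn eigenfunction and
#' the reference eigenfunction - the first retained draw of the first chain,
#' used across all chains so that chains are mutually comparable in
#' between-chain diagnostics. A zero-variance eigenfunction sample falls back
#' to the sign of the quadrature inner product with the reference. Signs are
#' applied jointly to the coefficient column and the score column, leaving
#' every reconstruction unchanged.
#'
#' @param draws aligned draws from [order_components()].
#' @return The draws with signs fixed and `$signs` recorded per chain
#'   (`n_draws x K` matrices).
#' @export
align_signs <- function(draws) {
  stopifnot(inherits(draws, "bfpca_aligned"))
  B <- draws$basis$eval_matrix
  w <- draws$grid$weights
  K <- draws$dims$K
  Phi_ref <- B %*% draws$chains[[1]]$Psi[1, , ]
  if (K == 1) Phi_ref <- matrix(Phi_ref, ncol = 1)
  ref_centered <- sweep(Phi_ref, 2, colMeans(Phi_ref))
  ref_sd0 <- colSums(ref_centered^2) == 0
  out <- draws
  for (c in seq_along(out$chains)) {
    ch <- out$chains[[c]]
    n <- length(ch$sigma2)
    signs <- matrix(1, n, K)
    for (k in seq_len(K)) {
      Phik <- matrix(ch$Psi[, , k], n) %*% t(B)   # n x M eigenfunction draws
      cen <- Phik - rowMeans(Phik)                # center each draw over t
      num <- drop(cen %*% ref_centered[, k])
      degen <- ref_sd0[k] | rowSums(cen^2) == 0
      if (any(degen)) {
        ip <- drop(Phik %*% (w * Phi_ref[, k]))
        num[degen] <- ip[degen]
      }
      s <- ifelse(num >= 0, 1, -1)
      signs[, k] <- s
      ch$Psi[, , k] <- ch$Psi[, , k] * s
      ch$Xi[, , k] <- ch$Xi[, , k] * s
    }
    ch$signs <- signs
    out$chains[[c]] <- ch
    out$signs[[c]] <- signs
  }
  out
}

#' Orthonormal point estimate of the eigenfunctions
#'
#' Takes the element-wise mean of the aligned coefficient-matrix draws and
#' orthonormalizes it with the polar factor, so that the resulting estimate
#' `Phi_hat = B Psi_hat` has exactly orthonormal coefficient columns (and
#' L2-orthonormal functions in functional mode).
#'
#' @param draws aligned draws.
#' @param basis the basis used in the fit (defaults to the one stored in
#'   `draws`).
#' @return List with `Psi_hat` (`Q x K`, orthonormal) and `Phi_hat`
#'   (`M x K`).
#' @export
orthonormalized_mean <- function(draws, basis = draws$basis) {
  stopifnot(inherits(draws, "bfpca_aligned"))
  K <- draws$dims$K
  Q <- dim(draws$chains[[1]]$Psi)[2]
  Psi_bar <- matrix(0, Q, K)
  n_tot <- 0
  for (ch in draws$chains) {
    Psi_bar <- Psi_bar + apply(ch$Psi, c(2, 3), sum)
    n_tot <- n_tot + length(ch$sigma2)
  }
  Psi_bar <- Psi_bar / n_tot
  pol <- tryCatch(polar_orthonormalize(Psi_bar),
                  error = function(e) stop(
                    "the mean coefficient matrix is rank deficient, which signals catastrophic misalignment of draws: ",
                    conditionMessage(e), call. = FALSE))
  list(Psi_hat = pol$Psi, Phi_hat = basis$eval_matrix %*% pol$Psi)
}

#' Equal-tail credible bands
#'
#' Pointwise equal-tail intervals from the empirical `(1 - level)/2` and
#' `1 - (1 - level)/2` quantiles of the aligned draws, for the mean curve,
#' each eigenfunction at each grid point, each eigenvalue, and each score.
#' Quantiles use the linear-interpolation convention (type 7), fixed so bands
#' are bit-reproducible.
#'
#' @param draws aligned draws.
#' @param level interval probability in (0, 1), default 0.95.
#' @return A list of data frames: `mean_curve` (`t`, `estimate`, `lower`,
#'   `upper`), `fpcs` (`component`, `t`, ...), `eigenvalues` (`component`,
#'   ...), `scores` (`curve`, `component`, ...). Estimates are pointwise
#'   posterior means.
#' @export
credible_bands <- function(draws, level = 0.95) {
  stopifnot(inherits(draws, "bfpca_aligned"))
  if (level <= 0 || level >= 1) stop("`level` must lie in (0, 1)", call. = FALSE)
  B <- draws$basis$eval_matrix
  K <- draws$dims$K; M <- draws$dims$M; N <- draws$dims$N
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  mu_draws <- do.call(rbind, lapply(draws$chains, function(ch) ch$w_mu %*% t(B)))
  qs <- apply(mu_draws, 2, stats::quantile, probs = probs, type = 7)
  mean_curve <- data.frame(t = draws$grid$points,
                           estimate = colMeans(mu_draws),
                           lower = qs[1, ], upper = qs[2, ])
  fpcs <- do.call(rbind, lapply(seq_len(K), function(k) {
    Phik <- do.call(rbind, lapply(draws$chains, function(ch) {
      matrix(ch$Psi[, , k], dim(ch$Psi)[1]) %*% t(B)
    }))
    qs <- apply(Phik, 2, stats::quantile, probs = probs, type = 7)
    data.frame(component = k, t = draws$grid$points,
               estimate = colMeans(Phik), lower = qs[1, ], upper = qs[2, ])
  }))
  lam_draws <- do.call(rbind, lapply(draws$chains, function(ch) ch$lambda))
  qs <- apply(lam_draws, 2, stats::quantile, probs = probs, type = 7)
  eigenvalues <- data.frame(component = seq_len(K),
                            estimate = colMeans(lam_draws),
                            lower = qs[1, ], upper = qs[2, ])
  scores <- do.call(rbind, lapply(seq_len(K), function(k) {
    Xik <- do.call(rbind, lapply(draws$chains, function(ch) {
      matrix(ch$Xi[, , k], dim(ch$Xi)[1])
    }))
    qs <- apply(Xik, 2, stats::quantile, probs = probs, type = 7)
    data.frame(curve = seq_len(N), component = k, estimate = colMeans(Xik),
               lower = qs[1, ], upper = qs[2, ])
  }))
  list(mean_curve = mean_curve, fpcs = fpcs, eigenvalues = eigenvalues,
       scores = scores, level = level)
}

#' Percent variance explained
#'
#' Per draw, `pve_k = 100 lambda_k / (sum_j lambda_j [+ sigma2])`; the noise
#' variance enters the denominator only when `include_noise = TRUE` (both
#' conventions are in use; the default excludes it). Summaries are posterior
#' means with equal-tail intervals.
#'
#' @param lambda_draws matrix of eigenvalue draws (rows = draws) or aligned
#'   draws, in which case eigenvalue and variance draws are extracted.
#' @param include_noise logical.
#' @param sigma2_draws vector of error-variance draws (required when
#'   `include_noise = TRUE` and `lambda_draws` is a matrix).
#' @param level interval probability.
#' @return Data frame with `component`, `estimate`, `lower`, `upper` (in
#'   percent).
#' @export
pve <- function(lambda_draws, include_noise = FALSE, sigma2_draws = NULL,
                level = 0.95) {
  if (inherits(lambda_draws, "bfpca_aligned") || inherits(lambda_draws, "bfpca_draws")) {
    dr <- lambda_draws
    sigma2_draws <- unlist(lapply(dr$chains, function(ch) ch$sigma2))
    lambda_draws <- do.call(rbind, lapply(dr$chains, function(ch) ch$lambda))
  }
  lambda_draws <- as.matrix(lambda_draws)
  denom <- rowSums(lambda_draws)
  if (include_noise) {
    if (is.null(sigma2_draws)) stop("sigma2 draws required when include_noise = TRUE", call. = FALSE)
    denom <- denom + sigma2_draws
  }
  p <- 100 * lambda_draws / denom
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(p, 2, stats::quantile, probs = probs, type = 7)
  data.frame(component = seq_len(ncol(p)), estimate = colMeans(p),
             lower = qs[1, ], upper = qs[2, ])
}

# ---- convergence diagnostics ----------------------------------------------

# classic split-chain Gelman-Rubin statistic for each column of the per-chain
# draw matrices; constant-everywhere scalars return 1 by convention
split_rhat_matrix <- function(mats) {
  halves <- list()
  for (m in mats) {
    n <- nrow(m)
    n2 <- floor(n / 2)
    if (n2 < 2) stop("need at least 4 draws per chain for split RHat", call. = FALSE)
    halves[[length(halves) + 1]] <- m[seq_len(n2), , drop = FALSE]
    halves[[length(halves) + 1]] <- m[(n - n2 + 1):n, , drop = FALSE]
  }
  n <- nrow(halves[[1]])
  mns <- vapply(halves, colMeans, numeric(ncol(halves[[1]])))
  vrs <- vapply(halves, function(h) {
    (colSums(h^2) - n * colMeans(h)^2) / (n - 1)
  }, numeric(ncol(halves[[1]])))
  if (is.null(dim(mns))) { mns <- matrix(mns, nrow = 1); vrs <- matrix(vrs, nrow = 1) }
  W <- rowMeans(vrs)
  Bn <- apply(mns, 1, stats::var)            # between-half variance of means
  var_plus <- (n - 1) / n * W + Bn
  r <- sqrt(var_plus / W)
  r[W < .Machine$double.eps & Bn < .Machine$double.eps] <- 1
  r
}

#' Split-chain Gelman-Rubin diagnostics
#'
#' Potential scale reduction statistics for every monitored scalar, computed
#' on aligned draws (sign and ordering non-identifiability would otherwise
#' inflate between-chain variance spuriously): each eigenfunction value at
#' each grid point, each score, each eigenvalue, and the error variance.
#' Each chain is split in half, so the statistic detects both between-chain
#' and within-chain drift. With a single chain the two halves of that chain
#' are compared, with a warning. All chains constant and identical yields 1
#' by convention.
#'
#' @param draws aligned draws.
#' @return List with `table` (data frame `block`, `parameter`, `rhat`),
#'   `max` (largest statistic), and `by_block` (per-block maxima).
#' @export
rhat <- function(draws) {
  stopifnot(inherits(draws, "bfpca_aligned"))
  if (length(draws$chains) < 2) {
    warning("single chain: RHat computed from the two chain halves only")
  }
  B <- draws$basis$eval_matrix
  K <- draws$dims$K
  blocks <- list()
  for (k in seq_len(K)) {
    mats <- lapply(draws$chains, function(ch) {
      matrix(ch$Psi[, , k], dim(ch$Psi)[1]) %*% t(B)
    })
    r <- split_rhat_matrix(mats)
    blocks[[length(blocks) + 1]] <- data.frame(
      block = sprintf("phi_%d", k),
      parameter = sprintf("phi_%d(t_%d)", k, seq_along(r)), rhat = r)
  }
  for (k in seq_len(K)) {
    mats <- lapply(draws$chains, function(ch) matrix(ch$Xi[, , k], dim(ch$Xi)[1]))
    r <- split_rhat_matrix(mats)
    blocks[[length(blocks) + 1]] <- data.frame(
      block = sprintf("scores_%d", k),
      parameter = sprintf("xi_%d_%d", seq_along(r), k), rhat = r)
  }
  r <- split_rhat_matrix(lapply(draws$chains, function(ch) ch$lambda))
  blocks[[length(blocks) + 1]] <- data.frame(
    block = "lambda", parameter = sprintf("lambda_%d", seq_len(K)), rhat = r)
  r <- split_rhat_matrix(lapply(draws$chains, function(ch) matrix(ch$sigma2, ncol = 1)))
  blocks[[length(blocks) + 1]] <- data.frame(
    block = "sigma2", parameter = "sigma2", rhat = r)
  tab <- do.call(rbind, blocks)
  by_block <- tapply(tab$rhat, tab$block, max)
  list(table = tab, max = max(tab$rhat), by_block = by_block)
}

#' Full post-processing of posterior draws
#'
#' Runs [order_components()], [align_signs()], [orthonormalized_mean()],
#' [credible_bands()], [pve()], and [rhat()] and collects the results.
#'
#' @param draws a `bfpca_draws` from [fit_fpca()].
#' @param level credible level for all intervals.
#' @param pve_include_noise include the error variance in the percent
#'   variance explained denominator.
#' @return An object of class `bfpca_result`: `mean_curve`, `fpcs`,
#'   `fpc_estimates` (orthonormal `Phi_hat` with `Psi_hat`), `eigenvalues`,
#'   `scores`, `pve`, `rhat`, `aligned` (the aligned draws), and sampler
#'   `diagnostics`.
#' @export
postprocess_fpca <- function(draws, level = 0.95, pve_include_noise = FALSE) {
  aligned <- align_signs(order_components(draws))
  om <- orthonormalized_mean(aligned)
  bands <- credible_bands(aligned, level)
  pv <- pve(aligned, include_noise = pve_include_noise, level = level)
  rh <- rhat(aligned)
  sig <- unlist(lapply(aligned$chains, function(ch) ch$sigma2))
  structure(list(
    mean_curve = bands$mean_curve,
    fpcs = bands$fpcs,
    fpc_estimates = om$Phi_hat,
    Psi_hat = om$Psi_hat,
    eigenvalues = bands$eigenvalues,
    scores = bands$scores,
    sigma2 = c(estimate = mean(sig),
               lower = unname(stats::quantile(sig, (1 - level) / 2, type = 7)),
               upper = unname(stats::quantile(sig, 1 - (1 - level) / 2, type = 7))),
    pve = pv,
    rhat = rh,
    aligned = aligned,
    level = level,
    diagnostics = lapply(aligned$chains, function(ch) ch$diagnostics)),
    class = "bfpca_result")
}

#' @export
print.bfpca_result <- function(x, ...) {
  cat(sprintf("<bfpca_result> K = %d components, max RHat = %.3f\n",
              nrow(x$eigenvalues), x$rhat$max))
  cat("eigenvalues (posterior mean [equal-tail interval]):\n")
  for (k in seq_len(nrow(x$eigenvalues))) {
    e <- x$eigenvalues[k, ]
    cat(sprintf("  lambda_%d = %.4g [%.4g, %.4g], pve %.1f%%\n", k,
                e$estimate, e$lower, e$upper, x$pve$estimate[k]))
  }
  cat(sprintf("sigma2 = %.4g [%.4g, %.4g]\n", x$sigma2["estimate"],
              x$sigma2["lower"], x$sigma2["upper"]))
  invisible(x)
}
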
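# Scoring fitted results against a known simulation truth: integrated squared
# error by quadrature, pointwise coverage of credible bands, and score
# accuracy/coverage.

#' Integrated squared error by quadrature
#'
#' `ISE(f, g) = \int_0^1 (f - g)^2 dt`, approximated by the grid's quadrature
#' weights: `sum_m w(t_m) (f(t_m) - g(t_m))^2`.
#'
#' @param estimate,truth function values on the grid.
#' @param grid a `bfpca_grid`.
#' @return Nonnegative scalar.
#' @export
ise <- function(estimate, truth, grid) {
  stopifnot(inherits(grid, "bfpca_grid"))
  if (length(estimate) != length(grid$points) ||
      length(truth) != length(grid$points)) {
    stop("estimate/truth length does not match the grid", call. = FALSE)
  }
  sum(grid$weights * (estimate - truth)^2)
}

#' Match estimated component signs to a known truth
#'
#' For evaluation only: per component, applies the sign minimizing the ISE
#' against the true eigenfunction to the estimated eigenfunction, its bands,
#' and its scores (columnwise, independently across components).
#'
#' @param result a `bfpca_result`.
#' @param truth a `bfpca_scenario` with the same number of components.
#' @return The result with signs matched to the truth; the applied sign
#'   vector is stored as `$truth_signs`.
#' @export
align_to_truth <- function(result, truth) {
  stopifnot(inherits(result, "bfpca_result"), inherits(truth, "bfpca_scenario"))
  K <- nrow(result$eigenvalues)
  if (truth$K != K) stop("component count mismatch", call. = FALSE)
  grid <- result$aligned$grid
  signs <- numeric(K)
  for (k in seq_len(K)) {
    phi_true <- truth$eigen_fns[[k]](grid$points)
    rows <- result$fpcs$component == k
    est <- result$fpcs$estimate[rows]
    signs[k] <- if (ise(est, phi_true, grid) <= ise(-est, phi_true, grid)) 1 else -1
    if (signs[k] < 0) {
      lo <- result$fpcs$lower[rows]
      result$fpcs$estimate[rows] <- -est
      result$fpcs$lower[rows] <- -result$fpcs$upper[rows]
      result$fpcs$upper[rows] <- -lo
      result$fpc_estimates[, k] <- -result$fpc_estimates[, k]
      result$Psi_hat[, k] <- -result$Psi_hat[, k]
      srows <- result$scores$component == k
      slo <- result$scores$lower[srows]
      result$scores$estimate[srows] <- -result$scores$estimate[srows]
      result$scores$lower[srows] <- -result$scores$upper[srows]
      result$scores$upper[srows] <- slo * -1
    }
  }
  result$truth_signs <- signs
  result
}

#' Pointwise coverage of a band
#'
#' Fraction of grid points at which `lower <= truth <= upper` (closed
#' intervals, so a band touching the truth counts as covering).
#'
#' @param lower,upper band limits on the grid.
#' @param truth true function values on the grid.
#' @return Proportion in `[0, 1]`.
#' @export
pointwise_coverage <- function(lower, upper, truth) {
  if (length(lower) != length(truth) || length(upper) != length(truth)) {
    stop("band/truth length mismatch", call. = FALSE)
  }
  mean(lower <= truth & truth <= upper)
}

#' Score accuracy and interval coverage
#'
#' Per component: mean squared error of the posterior-mean scores against the
#' true scores, and the fraction of curves whose true score lies inside its
#' equal-tail interval.
#'
#' @param result a (truth-aligned) `bfpca_result`.
#' @param truth_scores `N x K` matrix of true scores.
#' @return Data frame with `component`, `mse`, `coverage`.
#' @export
score_metrics <- function(result, truth_scores) {
  K <- nrow(result$eigenvalues)
  truth_scores <- as.matrix(truth_scores)
  if (ncol(truth_scores) != K) stop("component count mismatch", call. = FALSE)
  out <- data.frame(component = seq_len(K), mse = NA_real_, coverage = NA_real_)
  for (k in seq_len(K)) {
    rows <- result$scores$component == k
    est <- result$scores$estimate[rows]
    out$mse[k] <- mean((est - truth_scores[, k])^2)
    out$coverage[k] <- mean(result$scores$lower[rows] <= truth_scores[, k] &
                              truth_scores[, k] <= result$scores$upper[rows])
  }
  out
}

#' Simulate-fit-score replicate study
#'
#' For each replicate: simulate a dataset from the scenario, fit the model,
#' post-process, align signs to the truth, and record per-component ISE of
#' the eigenfunction estimates, ISE of the mean, pointwise band coverage,
#' and score MSE/coverage. Replicates whose fit fails are recorded and
#' excluded from summaries. Fully deterministic given `seed` (replicate
#' seeds are `seed + 1, ..., seed + B`; fit seeds are derived from them).
#'
#' @param scenario a `bfpca_scenario`.
#' @param B number of replicates.
#' @param config a `bfpca_config` used for every fit.
#' @param seed master seed.
#' @param level credible level of the bands.
#' @return An object of class `bfpca_evaluation`: `replicates` (tidy data
#'   frame: one row per replicate x component x metric), `summary` (medians
#'   and interquartile ranges per component x metric), `failures`.
#' @export
run_replicate_study <- function(scenario, B, config = fpca_config(),
                                seed = 1, level = 0.95) {
  stopifnot(inherits(scenario, "bfpca_scenario"), B >= 1)
  if (config$K != scenario$K) {
    stop(sprintf("config fits K = %d components but the scenario truth has %d",
                 config$K, scenario$K), call. = FALSE)
  }
  rows <- list()
  failures <- integer(0)
  for (b in seq_len(B)) {
    rep_seed <- seed + b
    sim <- simulate_scenario(scenario, seed = rep_seed)
    cfg <- config
    cfg$seed <- as.integer((rep_seed * 7919L) %% (.Machine$integer.max - 1L)) + 1L
    res <- tryCatch({
      fit <- fit_fpca(sim$Y, sim$grid, cfg)
      align_to_truth(postprocess_fpca(fit, level = level), scenario)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, b)
      next
    }
    grid <- sim$grid
    mu_true <- scenario$mean_fn(grid$points)
    sm <- score_metrics(res, sim$true_scores)
    for (k in seq_len(scenario$K)) {
      phi_true <- scenario$eigen_fns[[k]](grid$points)
      frows <- res$fpcs$component == k
      rows[[length(rows) + 1]] <- data.frame(
        replicate = b, component = k,
        metric = c("ise_fpc", "coverage_fpc", "score_mse", "score_coverage"),
        value = c(ise(res$fpcs$estimate[frows], phi_true, grid),
                  pointwise_coverage(res$fpcs$lower[frows],
                                     res$fpcs$upper[frows], phi_true),
                  sm$mse[k], sm$coverage[k]))
    }
    rows[[length(rows) + 1]] <- data.frame(
      replicate = b, component = 0,
      metric = c("ise_mean", "coverage_mean", "max_rhat", "sigma2_mean"),
      value = c(ise(res$mean_curve$estimate, mu_true, grid),
                pointwise_coverage(res$mean_curve$lower,
                                   res$mean_curve$upper, mu_true),
                res$rhat$max, unname(res$sigma2["estimate"])))
  }
  reps <- do.call(rbind, rows)
  summ <- NULL
  if (!is.null(reps)) {
    agg_med <- stats::aggregate(value ~ component + metric, reps, stats::median)
    agg_iqr <- stats::aggregate(value ~ component + metric, reps, stats::IQR)
    summ <- merge(agg_med, agg_iqr, by = c("component", "metric"),
                  suffixes = c("_median", "_iqr"))
  }
  structure(list(replicates = reps, summary = summ, failures = failures,
                 scenario = scenario$name, B = B, seed = seed),
            class = "bfpca_evaluation")
}

#' @export
print.bfpca_evaluation <- function(x, ...) {
  cat(sprintf("<bfpca_evaluation> scenario %s, B = %d (%d failed)\n",
              x$scenario, x$B, length(x$failures)))
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}
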
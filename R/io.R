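# Plain-text interchange: comma-separated curve tables (wide or long), run
# configurations in YAML, columnar draw files, and JSON manifests so every
# output directory is reconstructible from config + seeds + input digests.

#' Read a curve table
#'
#' Wide layout: first column is the curve id, remaining columns hold the
#' values with the header giving the time stamps. Long layout: columns
#' `id`, optional `group`, `time`, `value`; the table is pivoted to wide and
#' all curves must share an identical time vector. Time stamps are affinely
#' rescaled to `[0, 1]`; the map is stored for reporting on the original
#' axis.
#'
#' @param path file path of a comma-separated table.
#' @param layout `"wide"` or `"long"`.
#' @return A list of class `bfpca_curves`: `Y` (`N x M`), `ids`, `grid`
#'   (trapezoid weights on the rescaled time stamps), `time_map`
#'   (`offset`, `scale`), and for grouped long input `subject`/`visit`
#'   indices.
#' @export
read_curves <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (layout == "wide") {
    ids <- tab[[1]]
    Y <- as.matrix(tab[, -1, drop = FALSE])
    times <- suppressWarnings(as.numeric(colnames(Y)))
    if (anyNA(times)) stop("wide header must give numeric time stamps", call. = FALSE)
    if (anyNA(Y)) {
      bad <- which(rowSums(is.na(Y)) > 0)[1]
      stop(sprintf("missing cells in curve row %d", bad), call. = FALSE)
    }
    if (any(diff(times) <= 0)) stop("time stamps must be strictly increasing", call. = FALSE)
    tm <- rescale_times(times)
    grid <- grid_from_points(tm$points)
    return(structure(list(Y = unname(Y), ids = ids, grid = grid,
                          time_map = tm[c("offset", "scale")]),
                     class = "bfpca_curves"))
  }
  need <- c("id", "time", "value")
  if (!all(need %in% names(tab))) {
    stop("long layout requires columns id, time, value (optional group)", call. = FALSE)
  }
  has_group <- "group" %in% names(tab)
  if (anyNA(tab$value)) stop("missing cells in long table", call. = FALSE)
  key <- if (has_group) paste(tab$group, tab$id) else as.character(tab$id)
  key <- factor(key, levels = unique(key))
  times <- sort(unique(tab$time))
  split_t <- split(tab$time, key)
  same <- vapply(split_t, function(tt) identical(sort(tt), times), logical(1))
  if (!all(same)) {
    stop("curve '", names(split_t)[which(!same)[1]],
         "' does not share the common time grid", call. = FALSE)
  }
  ord <- order(key, tab$time)
  Y <- matrix(tab$value[ord], nrow = nlevels(key), byrow = TRUE)
  tm <- rescale_times(times)
  grid <- grid_from_points(tm$points)
  out <- list(Y = Y, ids = levels(key), grid = grid,
              time_map = tm[c("offset", "scale")])
  if (has_group) {
    first <- !duplicated(key)
    out$subject <- as.integer(factor(tab$group[ord][first],
                                     levels = unique(tab$group[ord][first])))
    out$visit <- stats::ave(out$subject, out$subject, FUN = seq_along)
  }
  structure(out, class = "bfpca_curves")
}

# trapezoid-type weights for arbitrary strictly increasing points in [0,1]
grid_from_points <- function(points) {
  M <- length(points)
  d <- diff(points)
  w <- c(d[1] / 2, (d[-1] + d[-(M - 1)]) / 2, d[M - 1] / 2)
  # extend to the full unit interval so weights integrate constants exactly
  w[1] <- w[1] + points[1]
  w[M] <- w[M] + 1 - points[M]
  structure(list(points = points, weights = w, scheme = "trapezoid"),
            class = "bfpca_grid")
}

#' Write a curve table (wide layout)
#'
#' @param Y `N x M` matrix.
#' @param times time stamps (header).
#' @param path output path.
#' @param ids optional curve ids.
#' @return `path`, invisibly.
#' @export
write_curves <- function(Y, times, path, ids = seq_len(nrow(Y))) {
  vals <- format(Y, digits = 17, scientific = TRUE, trim = TRUE)
  df <- data.frame(id = ids, vals, check.names = FALSE)
  colnames(df) <- c("id", format(times, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a run configuration
#'
#' Run configurations round-trip losslessly through YAML and are recorded
#' verbatim in every output directory.
#'
#' @param config a `bfpca_config` (or plain named list).
#' @param path file path.
#' @return `read_run_config` returns a `bfpca_config`.
#' @export
write_run_config <- function(config, path) {
  lst <- unclass(config)
  lst$is_multilevel <- inherits(config, "bfpca_mconfig")
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  ml <- isTRUE(lst$is_multilevel)
  lst$is_multilevel <- NULL
  prior <- lst$prior
  if (!is.null(prior)) prior <- prior[!vapply(prior, is.null, logical(1))]
  args <- list(Q = lst$Q, alpha = lst$alpha, n_iter = lst$n_iter,
               n_warmup = lst$n_warmup, n_chains = lst$n_chains,
               seed = lst$seed, mode = lst$mode,
               prior = if (length(prior)) prior else list(),
               n_leapfrog = lst$n_leapfrog, target_accept = lst$target_accept)
  if (ml) {
    args$K1 <- lst$K1; args$K2 <- lst$K2; args$eta <- isTRUE(lst$eta)
    do.call(mfpca_config, args)
  } else {
    args$K <- lst$K
    do.call(fpca_config, args)
  }
}

#' Serialize posterior draws as plain text
#'
#' One comma-separated file per chain (one column per scalar parameter with
#' names like `lambda.1`, `Psi.3.2`, `Scores.17.1`) plus a JSON sidecar with
#' the configuration, seeds, and sampler diagnostics.
#'
#' @param draws a `bfpca_draws`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_draws <- function(draws, dir) {
  stopifnot(inherits(draws, "bfpca_draws"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  K <- draws$dims$K; Q <- draws$dims$Q; N <- draws$dims$N
  for (c in seq_along(draws$chains)) {
    ch <- draws$chains[[c]]
    n <- length(ch$sigma2)
    flat <- cbind(ch$sigma2, ch$h_mu, ch$w_mu, ch$lambda, ch$H,
                  matrix(ch$Psi, n), matrix(ch$Xi, n))
    colnames(flat) <- c("sigma2", "h_mu",
                        sprintf("w_mu.%d", seq_len(Q)),
                        sprintf("lambda.%d", seq_len(K)),
                        sprintf("H.%d", seq_len(K)),
                        sprintf("Psi.%d.%d", rep(seq_len(Q), K), rep(seq_len(K), each = Q)),
                        sprintf("Scores.%d.%d", rep(seq_len(N), K), rep(seq_len(K), each = N)))
    flat_chr <- format(flat, digits = 17, scientific = TRUE, trim = TRUE)
    utils::write.csv(as.data.frame(flat_chr, check.names = FALSE),
                     file.path(dir, sprintf("chain_%d.csv", c)),
                     row.names = FALSE, quote = FALSE)
  }
  side <- list(config = unclass(draws$config), dims = draws$dims,
               chain_seeds = draws$chain_seeds,
               diagnostics = lapply(draws$chains, function(ch) ch$diagnostics))
  jsonlite::write_json(side, file.path(dir, "draws.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_draws
#' @export
read_draws <- function(dir, grid) {
  side <- jsonlite::read_json(file.path(dir, "draws.json"), simplifyVector = TRUE)
  dims <- side$dims
  cfg <- do.call(fpca_config, side$config[c("K", "Q", "alpha", "n_iter",
                                            "n_warmup", "n_chains", "seed",
                                            "mode", "n_leapfrog",
                                            "target_accept")])
  basis <- build_basis(grid, dims$Q, cfg$mode)
  penalty <- build_penalty(basis, cfg$alpha)
  files <- sort(list.files(dir, pattern = "^chain_\\d+\\.csv$", full.names = TRUE))
  chains <- lapply(seq_along(files), function(c) {
    flat <- as.matrix(utils::read.csv(files[c]))
    n <- nrow(flat)
    K <- dims$K; Q <- dims$Q; N <- dims$N
    list(sigma2 = unname(flat[, "sigma2"]), h_mu = unname(flat[, "h_mu"]),
         w_mu = unname(flat[, sprintf("w_mu.%d", seq_len(Q)), drop = FALSE]),
         lambda = unname(flat[, sprintf("lambda.%d", seq_len(K)), drop = FALSE]),
         H = unname(flat[, sprintf("H.%d", seq_len(K)), drop = FALSE]),
         Psi = array(flat[, grep("^Psi\\.", colnames(flat))], c(n, Q, K)),
         Xi = array(flat[, grep("^Scores\\.", colnames(flat))], c(n, N, K)),
         diagnostics = side$diagnostics[[c]])
  })
  structure(list(chains = chains, config = cfg, basis = basis,
                 penalty = penalty, grid = grid, dims = dims,
                 chain_seeds = side$chain_seeds),
            class = "bfpca_draws")
}

# manifest written into every CLI output directory
write_manifest <- function(dir, command, config, seed, inputs = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(command = command,
                   package = "bfpca",
                   version = tryCatch(as.character(utils::packageVersion("bfpca")),
                                      error = function(e) "dev"),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   seed = seed,
                   config = if (!is.null(config)) unclass(config),
                   input_digests = digests)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
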
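#' Quadrature grid on the unit interval
#'
#' Builds a set of `M` sampling points in `[0, 1]` together with quadrature
#' weights for approximating integrals `\int_0^1 f(t) dt` by
#' `sum_m w(t_m) f(t_m)`. The Gauss-Legendre rule is the default observation
#' design used by the built-in simulation scenarios; the trapezoid rule covers
#' equally spaced designs.
#'
#' @param M number of grid points (at least 4).
#' @param scheme `"gauss-legendre"` or `"trapezoid"`.
#' @return An object of class `bfpca_grid`: a list with `points` (strictly
#'   increasing in `[0, 1]`), `weights` (positive, summing to 1), and `scheme`.
#' @examples
#' g <- make_grid(50)
#' sum(g$weights)            # 1, the length of [0, 1]
#' sum(g$weights * g$points) # 0.5, exact for polynomials
#' @export
make_grid <- function(M, scheme = c("gauss-legendre", "trapezoid")) {
  if (!is.numeric(M) || length(M) != 1L || M < 2 || M != round(M)) {
    stop("`M` must be a single integer >= 2", call. = FALSE)
  }
  scheme <- match.arg(scheme)
  if (scheme == "gauss-legendre") {
    gl <- gauss_legendre_rule(M)
    points <- gl$points
    weights <- gl$weights
  } else {
    points <- seq(0, 1, length.out = M)
    h <- 1 / (M - 1)
    weights <- c(h / 2, rep(h, M - 2), h / 2)
  }
  structure(list(points = as.numeric(points), weights = as.numeric(weights),
                 scheme = scheme),
            class = "bfpca_grid")
}

#' @export
print.bfpca_grid <- function(x, ...) {
  cat(sprintf("<bfpca_grid> %d %s points on [%.4g, %.4g], weights sum %.6f\n",
              length(x$points), x$scheme, min(x$points), max(x$points),
              sum(x$weights)))
  invisible(x)
}

# Affine rescaling of arbitrary time stamps onto [0,1]; the map is stored so
# results can be reported on the original axis. Time stamps already inside
# [0,1] (e.g. quadrature nodes) are kept as they are.
rescale_times <- function(times) {
  a <- min(times)
  b <- max(times)
  if (b <= a) stop("time stamps must span a positive range", call. = FALSE)
  if (a >= 0 && b <= 1) return(list(points = times, offset = 0, scale = 1))
  list(points = (times - a) / (b - a), offset = a, scale = b - a)
}
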
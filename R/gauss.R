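# Gauss-Legendre quadrature on [0, 1] by vectorized Newton iteration on the
# Legendre recurrence (Golub-Welsch initial guesses). Rules are cached per
# session because fine rules (1e3-1e4 nodes) are requested repeatedly by the
# basis builder and the scenario validators.

.gl_cache <- new.env(parent = emptyenv())

gauss_legendre_rule <- function(n) {
  key <- as.character(n)
  hit <- get0(key, envir = .gl_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  i <- seq_len(n)
  x <- cos(pi * (i - 0.25) / (n + 0.5))
  pp <- numeric(n)
  for (iter in 1:100) {
    p1 <- rep(1, n); p2 <- rep(0, n)
    for (j in seq_len(n)) {
      p3 <- p2; p2 <- p1
      p1 <- ((2 * j - 1) * x * p2 - (j - 1) * p3) / j
    }
    pp <- n * (x * p1 - p2) / (x^2 - 1)
    dx <- p1 / pp
    x <- x - dx
    if (max(abs(dx)) < 1e-15) break
  }
  w <- 2 / ((1 - x^2) * pp^2)
  ord <- order(x)
  out <- list(points = (x[ord] + 1) / 2, weights = w[ord] / 2)
  assign(key, out, envir = .gl_cache)
  out
}
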
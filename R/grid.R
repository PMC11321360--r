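#' Arcsine-spaced allele-frequency grid
#'
#' Discretizes the unit interval into `K` allele-frequency bins placed at the
#' quantiles of a Beta(1/2, 1/2) distribution evaluated at `K` evenly spaced
#' points, i.e. \eqn{x_k = \sin^2(\pi w_k / 2)} with \eqn{w_k = (k-1)/(K-1)}.
#' The spacing is denser near 0 and 1, where per-generation drift variance
#' \eqn{x(1-x)/N} is smallest, so that small frequency fluctuations near the
#' boundaries are still resolved.
#'
#' @param K integer number of frequency bins (at least 2). Bins 1 and `K` sit
#'   exactly at frequencies 0 and 1 and are absorbing states of the chain.
#' @return an object of class `"freq_grid"`: a list with elements `K`, `w`
#'   (the uniform abscissae), `x` (the bin frequencies, strictly increasing
#'   from 0 to 1) and `mid` (the `K - 1` midpoints between adjacent bins used
#'   to integrate Gaussian transition mass).
#' @examples
#' g <- freq_grid(5)
#' g$x  # 0, 0.1464, 0.5, 0.8536, 1
#' @export
freq_grid <- function(K) {
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 2L)
    stop("'K' must be a single integer >= 2", call. = FALSE)
  w <- seq(0, 1, length.out = K)
  x <- sin(pi * w / 2)^2
  x <- (x + rev(1 - x)) / 2   # enforce the analytic symmetry exactly
  x[1] <- 0
  x[K] <- 1
  structure(list(K = K, w = w, x = x, mid = (x[-K] + x[-1]) / 2),
            class = "freq_grid")
}

#' @export
print.freq_grid <- function(x, ...) {
  cat(sprintf("Allele-frequency grid: %d bins, arcsine (Beta(1/2,1/2) quantile) spacing\n",
              x$K))
  invisible(x)
}

#' Closest frequency bin
#'
#' Index of the grid frequency closest to `f`; ties break toward the lower
#' index. Used to pin the present-day column of the forward matrix to the
#' observed modern derived allele frequency.
#'
#' @param grid a [freq_grid()].
#' @param f frequency in \[0, 1\].
#' @return integer bin index in `1:K`.
#' @export
nearest_bin <- function(grid, f) {
  stopifnot(inherits(grid, "freq_grid"))
  if (length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stop("'f' must be a single frequency in [0, 1]", call. = FALSE)
  which.min(abs(grid$x - f))
}
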
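#' Expected allele frequency one generation back in time
#'
#' Under additive selection with genotype fitnesses 1, 1+s/2 and 1+s, a
#' derived allele at frequency x today was, in expectation, at
#' \deqn{x + \frac{s\,x\,(x-1)}{2 s x + 2}}
#' one generation earlier. For s > 0 this decreases at interior frequencies
#' (the allele was rarer in the past); frequencies 0 and 1 are fixed points.
#'
#' @param x frequency in \[0, 1\] (vectorized).
#' @param s per-generation selection coefficient, |s| <= 0.1.
#' @return expected frequency one generation before the present one.
#' @export
backward_mean <- function(x, s) {
  if (any(x < 0 | x > 1)) stop("'x' must lie in [0, 1]", call. = FALSE)
  if (any(abs(s) > 0.1 + 1e-12)) stop("|s| must be <= 0.1", call. = FALSE)
  x + s * x * (x - 1) / (2 * s * x + 2)
}

#' Epoch-wise selection schedule
#'
#' A piecewise-constant map from time (generations before present) to a
#' selection coefficient: `s[i]` applies on \[`breaks[i-1]`, `breaks[i]`)
#' with `breaks[0] = 0` and the final epoch open-ended.
#'
#' @param s numeric vector of per-epoch coefficients (each |s| <= 0.1).
#' @param breaks strictly increasing breakpoints in generations before
#'   present; `length(breaks) == length(s) - 1`. Empty for a single constant
#'   coefficient.
#' @return object of class `"selection_schedule"`.
#' @export
selection_schedule <- function(s, breaks = numeric(0)) {
  s <- as.numeric(s)
  breaks <- as.numeric(breaks)
  if (length(s) < 1L) stop("need at least one selection coefficient", call. = FALSE)
  if (length(breaks) != length(s) - 1L)
    stop("length(breaks) must be length(s) - 1", call. = FALSE)
  if (any(abs(s) > 0.1 + 1e-12)) stop("|s| must be <= 0.1", call. = FALSE)
  if (length(breaks) && (any(diff(breaks) <= 0) || any(breaks <= 0)))
    stop("breakpoints must be positive and strictly increasing", call. = FALSE)
  structure(list(s = s, breaks = breaks), class = "selection_schedule")
}

#' @rdname selection_schedule
#' @param schedule a `selection_schedule`.
#' @param t time(s) in generations before present.
#' @return `s_at`: the coefficient in force at each `t`.
#' @export
s_at <- function(schedule, t) {
  schedule$s[findInterval(t, schedule$breaks) + 1L]
}

#' Piecewise-constant haploid population-size history
#'
#' @param starts epoch start times in generations before present; the first
#'   must be 0 and starts must be strictly increasing.
#' @param N haploid effective sizes (numbers of sequences), each >= 2.
#' @return object of class `"pop_size_history"`.
#' @export
pop_size_history <- function(starts, N) {
  starts <- as.numeric(starts); N <- as.numeric(N)
  if (length(starts) != length(N) || !length(N))
    stop("'starts' and 'N' must be equal-length, non-empty", call. = FALSE)
  if (starts[1] != 0) stop("first epoch must start at generation 0", call. = FALSE)
  if (any(diff(starts) <= 0)) stop("'starts' must be strictly increasing", call. = FALSE)
  if (any(N < 2)) stop("haploid size must be >= 2 everywhere", call. = FALSE)
  structure(list(starts = starts, N = N), class = "pop_size_history")
}

#' @rdname pop_size_history
#' @param history a `pop_size_history`.
#' @param t time(s) in generations before present.
#' @export
N_at <- function(history, t) {
  history$N[findInterval(t, history$starts)]
}

#' Read a population-size history file
#'
#' Two whitespace-delimited columns, `start_generation N_haploid`, with
#' ascending starts beginning at 0. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return a [pop_size_history()].
#' @export
read_pop_size <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("start", "N"))
  pop_size_history(tab$start, tab$N)
}

#' Per-generation frequency-transition model
#'
#' Row `k` of the transition matrix distributes the Gaussian
#' N([backward_mean()]`(x_k, s)`, `x_k (1 - x_k) / N`) over the frequency
#' bins: interior mass is the CDF difference across adjacent bin midpoints,
#' with the two tails assigned to bins 1 and `K`. Rows 1 and `K` have zero
#' variance and are exact point masses (absorbing boundaries).
#'
#' With `banded = TRUE` only entries whose bin frequency lies within
#' `sd_mult` (default 3.3) standard deviations of the row mean are computed
#' and each row is rescaled to sum to 1 (band approximation A1); at least
#' 99.9% of the Gaussian mass falls inside a 3.3-SD band. The row band limits
#' (`lo`, `hi`) and derived per-column limits (`a`, `b`) support the banded
#' forward/backward sums (approximation A2). `banded = FALSE` gives the exact
#' dense construction used as an oracle in tests.
#'
#' @param grid a [freq_grid()].
#' @param s selection coefficient, |s| <= 0.1.
#' @param N haploid effective population size, >= 2.
#' @param banded logical; compute only the 3.3-SD band and renormalize rows.
#' @param sd_mult band half-width in standard deviations.
#' @return object of class `"transition_model"`: list with the K x K matrix
#'   `P` (zeros outside the band when banded), integer vectors `lo`, `hi`
#'   (row bands), `a`, `b` (column bands), and the generating `s`, `N`.
#' @export
transition_model <- function(grid, s, N, banded = TRUE, sd_mult = 3.3) {
  stopifnot(inherits(grid, "freq_grid"))
  if (length(N) != 1L || is.na(N) || N < 2) stop("'N' must be >= 2", call. = FALSE)
  if (abs(s) > 0.1 + 1e-12) stop("|s| must be <= 0.1", call. = FALSE)
  K <- grid$K
  x <- grid$x
  mid <- grid$mid
  P <- matrix(0, K, K)
  lo <- hi <- integer(K)
  lo[1] <- hi[1] <- 1L; lo[K] <- hi[K] <- K
  P[1, 1] <- 1; P[K, K] <- 1
  if (K > 2) {
    ks <- 2:(K - 1)
    mu <- backward_mean(x[ks], s)
    sdv <- sqrt(x[ks] * (1 - x[ks]) / N)
    if (banded) {
      lo_k <- findInterval(mu - sd_mult * sdv, x, left.open = TRUE) + 1L
      hi_k <- findInterval(mu + sd_mult * sdv, x)
      # never an empty band: fall back to the bin nearest the mean
      empty <- lo_k > hi_k
      if (any(empty)) {
        nb <- vapply(mu[empty], function(m) which.min(abs(x - m)), integer(1))
        lo_k[empty] <- hi_k[empty] <- nb
      }
    } else {
      lo_k <- rep(1L, length(ks)); hi_k <- rep(K, length(ks))
    }
    lo[ks] <- lo_k; hi[ks] <- hi_k
    len <- hi_k - lo_k + 1L
    rows <- rep(ks, len)
    cols <- sequence(len) - 1L + rep(lo_k, len)
    mu_r <- rep(mu, len)
    sd_r <- rep(sdv, len)
    # upper integration edge for column l is mid[l] (Inf for l = K),
    # lower edge is mid[l - 1] (-Inf for l = 1)
    up <- ifelse(cols == K, Inf, mid[pmin(cols, K - 1L)])
    lw <- ifelse(cols == 1L, -Inf, mid[pmax(cols - 1L, 1L)])
    vals <- stats::pnorm(up, mu_r, sd_r) - stats::pnorm(lw, mu_r, sd_r)
    if (banded) {
      rs <- vapply(split(vals, rows), sum, numeric(1))
      vals <- vals / rs[match(rows, ks)]
      bad <- !is.finite(vals)
      if (any(bad)) vals[bad] <- 0
    }
    P[cbind(rows, cols)] <- vals
  }
  nz <- P > 0
  a <- apply(nz, 2, function(cl) if (any(cl)) which(cl)[1] else 0L)
  b <- apply(nz, 2, function(cl) if (any(cl)) max(which(cl)) else -1L)
  structure(list(P = P, lo = lo, hi = hi, a = as.integer(a), b = as.integer(b),
                 s = s, N = N, banded = banded),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("Transition model: K = %d, s = %g, N = %g, %s\n",
              nrow(x$P), x$s, x$N,
              if (x$banded) "banded (3.3-SD, rows renormalized)" else "dense"))
  invisible(x)
}
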
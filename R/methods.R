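#' @export
print.selhmm <- function(x, digits = 5, ...) {
  cat("Epoch-wise selection coefficient fit (allele-frequency HMM)\n\n")
  ep <- x$epochs
  ep$s_mle <- signif(ep$s_mle, digits)
  print(ep, row.names = FALSE)
  cat(sprintf("\nlnLR = %.4f  df = %d  -log10(P) = %.2f  AIC = %.2f\n",
              x$lnlr, x$df, x$minus_log10_p, x$aic))
  if (x$M > 1)
    cat(sprintf("importance samples M = %d, effective sample size = %.1f\n",
                x$M, x$ess))
  if (isTRUE(x$boundary))
    cat("note: MLE at the optimization boundary (|s| = 0.1)\n")
  if (any(x$wide_uncertainty))
    cat(sprintf("note: flat likelihood along epoch(s) %s (little or no data)\n",
                paste(which(x$wide_uncertainty), collapse = ", ")))
  invisible(x)
}

#' @export
summary.selhmm <- function(object, ...) {
  structure(list(fit = object), class = "summary.selhmm")
}

#' @export
print.summary.selhmm <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("\ngrid bins K = %d, horizon T = %d generations, modern frequency %.4g\n",
              f$K, f$t_cutoff, f$pop_freq))
  cat(sprintf("likelihood evaluations: %d\n", nrow(f$trace)))
  invisible(x)
}

#' @export
coef.selhmm <- function(object, ...) {
  stats::setNames(object$s_mle,
                  sprintf("s[%g,%g)", object$epochs$epoch_start,
                          object$epochs$epoch_end))
}

#' @export
logLik.selhmm <- function(object, ...) {
  structure(object$lnlr, df = object$df, class = "logLik")
}

#' Plot the log-likelihood-ratio profile of a fit
#'
#' For a single-epoch fit, plots the recorded `(s, lnLR)` evaluations; for
#' multi-epoch fits, plots lnLR against each coordinate of the trace.
#'
#' @param x a [selhmm()] fit.
#' @param ... passed to [plot()].
#' @export
plot.selhmm <- function(x, ...) {
  tr <- x$trace
  d <- x$df
  op <- graphics::par(mfrow = c(1, d))
  on.exit(graphics::par(op))
  for (i in seq_len(d)) {
    o <- order(tr[, i])
    graphics::plot(tr[o, i], tr[o, ncol(tr)], xlab = sprintf("s (epoch %d)", i),
                   ylab = "lnLR", pch = 16, cex = 0.6, ...)
    graphics::abline(v = x$s_mle[i], col = "red3", lty = 2)
  }
  invisible(x)
}
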
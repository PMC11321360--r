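#' Fit a Gaussian surface to the likelihood-ratio trace
#'
#' Approximates the (unnormalized) likelihood ratio surface around the MLE
#' by a scaled Gaussian density: finds the covariance `Sigma` and free
#' scale minimizing the sum of squared differences between
#' `exp(lnLR_j - lnLR_max)` and the scaled Gaussian at the evaluated points
#' `s_j`. Motivated by the Bernstein-von-Mises limit, this is the proposal
#' from which selection coefficients are drawn when integrating the
#' posterior trajectory over the uncertainty in `s`. Trace points more than
#' 30 log units below the maximum carry essentially no likelihood and are
#' excluded for numerical stability.
#'
#' @param trace matrix from [objective_trace()] (columns `s1..sd`, `lnlr`).
#' @param s_hat the MLE vector (the fitted Gaussian mean).
#' @return object of class `"gaussian_surface"`: list with `mean`, `Sigma`
#'   (d x d, symmetric positive definite), and `scale`.
#' @export
fit_gaussian_surface <- function(trace, s_hat) {
  d <- length(s_hat)
  stopifnot(ncol(trace) == d + 1L)
  lnlr <- trace[, d + 1L]
  keep <- is.finite(lnlr) & lnlr > max(lnlr) - 30
  S <- trace[keep, seq_len(d), drop = FALSE]
  y <- exp(lnlr[keep] - max(lnlr[keep]))
  if (nrow(unique(S)) < d * (d + 1) / 2 + 1)
    stop("degenerate trace: too few distinct points; widen the optimizer trace",
         call. = FALSE)
  if (stats::sd(lnlr[keep]) < 1e-12)
    stop("flat trace values: cannot fit a likelihood surface", call. = FALSE)
  dev <- sweep(S, 2, s_hat)
  # initial curvature from a quadratic fit of lnlr on the deviations
  q0 <- vapply(seq_len(d), function(i) {
    z <- dev[, i]
    if (stats::sd(z) < 1e-12) return(1e-4)
    cf <- stats::coef(stats::lm(lnlr[keep] ~ z + I(z^2)))[3]
    if (!is.finite(cf) || cf >= -1e-8) 1e-4 else sqrt(-1 / (2 * cf))
  }, numeric(1))
  # parameterize the inverse covariance by the log-diagonal Cholesky factor
  ltri <- which(lower.tri(diag(d), diag = FALSE))
  make_L <- function(par) {
    L <- diag(exp(par[seq_len(d)]), d)
    if (length(ltri)) L[ltri] <- par[d + seq_along(ltri)]
    L
  }
  sse <- function(par) {
    L <- make_L(par)
    q <- rowSums((dev %*% L)^2)
    c_hat <- exp(par[length(par)])
    sum((y - c_hat * exp(-0.5 * q))^2)
  }
  par0 <- c(-log(q0), rep(0, length(ltri)), 0)
  opt <- stats::optim(par0, sse, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  L <- make_L(opt$par)
  Sigma <- solve(tcrossprod(L))
  Sigma <- (Sigma + t(Sigma)) / 2
  if (any(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("fitted covariance is not positive definite", call. = FALSE)
  structure(list(mean = as.numeric(s_hat), Sigma = Sigma,
                 scale = exp(opt$par[length(opt$par)])),
            class = "gaussian_surface")
}

#' Sample selection coefficients from a fitted surface
#'
#' Draws from Normal(`mean`, `Sigma`) truncated to the optimization box
#' \[-0.1, 0.1\]^d by rejection.
#'
#' @param surface a [fit_gaussian_surface()].
#' @param n number of draws.
#' @param seed optional integer seed for reproducibility.
#' @return `n x d` matrix of coefficient vectors.
#' @export
sample_posterior_coefficients <- function(surface, n, seed = NULL) {
  stopifnot(inherits(surface, "gaussian_surface"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- length(surface$mean)
  R <- chol(surface$Sigma)
  out <- matrix(NA_real_, 0, d)
  drawn <- 0
  while (nrow(out) < n) {
    m <- max(100L, 2L * (n - nrow(out)))
    z <- matrix(stats::rnorm(m * d), m, d) %*% R
    z <- sweep(z, 2, surface$mean, `+`)
    ok <- rowSums(abs(z) > 0.1) == 0
    out <- rbind(out, z[ok, , drop = FALSE])
    drawn <- drawn + m
    if (drawn >= max(10000, 100 * n) && nrow(out) / drawn < 0.01)
      stop("acceptance rate below 1%: the likelihood surface appears mis-fit",
           call. = FALSE)
  }
  out[seq_len(n), , drop = FALSE]
}

# Marginal posterior over frequency bins at a fixed s for one prepared
# dataset; with several importance-sampled trees the per-sample posteriors
# are averaged with normalized importance weights.
.marginals_at_s <- function(info, svec) {
  models <- lapply(seq_along(info$epoch_of_regime), function(r)
    transition_model(info$grid, svec[info$epoch_of_regime[r]],
                     info$N_of_regime[r]))
  em_list <- if (is.null(info$tree_parts)) {
    list(list(logE = info$shared$logE, one_derived = info$shared$one_derived))
  } else {
    lapply(info$tree_parts, function(tp) {
      le <- tp$logE
      if (!is.null(info$shared)) le <- le + info$shared$logE
      list(logE = le, one_derived = tp$one_derived)
    })
  }
  Tn <- ncol(em_list[[1]]$logE)
  K <- info$grid$K
  pis <- vector("list", length(em_list))
  ll <- numeric(length(em_list))
  for (m in seq_along(em_list)) {
    fw <- run_forward(models, info$step_model, em_list[[m]]$logE, info$init_bin,
                      info$grid, one_derived = em_list[[m]]$one_derived,
                      approx_b = info$approx_b, keep_matrix = TRUE)
    if (!fw$ok) stop("data impossible under this s: -Inf likelihood", call. = FALSE)
    bw <- run_backward(models, info$step_model, em_list[[m]]$logE, info$grid)
    pi_m <- fw$F * bw$B
    cs <- colSums(pi_m)
    bad <- cs <= 0          # beam-pruned forward support can miss B's mass
    if (any(bad)) {
      pi_m[, bad] <- fw$F[, bad]
      cs[bad] <- colSums(fw$F[, bad, drop = FALSE])
    }
    pis[[m]] <- sweep(pi_m, 2, cs, `/`)
    ll[m] <- fw$loglik
  }
  if (length(pis) == 1L) return(t(pis[[1]]))
  w <- exp(ll - logsumexp(ll))
  acc <- matrix(0, K, Tn)
  for (m in seq_along(pis)) acc <- acc + w[m] * pis[[m]]
  t(acc)
}

#' Marginal posterior frequency distributions at a fixed coefficient
#'
#' Per-generation marginal posterior over the frequency bins,
#' \eqn{\pi_t(k) \propto F_{k,t} B_{t,k}}, from a forward-backward pass at
#' the given selection coefficient(s).
#'
#' @param fit a [selhmm()] fit.
#' @param s coefficient vector (defaults to the MLE).
#' @return `T x K` matrix; row `t` is the posterior at `t - 1` generations
#'   before present and sums to 1.
#' @export
marginal_posteriors <- function(fit, s = fit$s_mle) {
  stopifnot(inherits(fit, "selhmm"))
  .marginals_at_s(attr(fit$objective, "info"), as.numeric(s))
}

#' Posterior allele-frequency trajectory
#'
#' Reconstructs the per-generation marginal posterior of the derived allele
#' frequency, integrating over the uncertainty in the selection
#' coefficients: a Gaussian surface is fitted to the likelihood evaluations
#' recorded during optimization, `n_samples` coefficient vectors are drawn
#' from it, and the forward-backward posteriors at the sampled coefficients
#' are averaged. Reported quantiles are 2.5%, 50% and 97.5% of the averaged
#' per-generation mass over the bin frequencies.
#'
#' @param fit a [selhmm()] fit.
#' @param n_samples number of coefficient draws (default `10^d` where `d`
#'   is the number of epochs).
#' @param seed optional integer seed.
#' @return object of class `"selhmm_traj"`: list with `pi` (`T x K`
#'   averaged posterior, rows sum to 1), `quantiles` (data frame
#'   `generation, q2.5, q50, q97.5`), `s_samples`, `surface`.
#' @export
posterior_trajectory <- function(fit, n_samples = NULL, seed = NULL) {
  stopifnot(inherits(fit, "selhmm"))
  d <- fit$df
  if (is.null(n_samples)) n_samples <- 10^d
  surface <- fit_gaussian_surface(fit$trace, fit$s_mle)
  sm <- sample_posterior_coefficients(surface, n_samples, seed = seed)
  info <- attr(fit$objective, "info")
  pi_bar <- 0
  for (i in seq_len(nrow(sm)))
    pi_bar <- pi_bar + .marginals_at_s(info, sm[i, ])
  pi_bar <- pi_bar / nrow(sm)
  structure(list(pi = pi_bar,
                 quantiles = .traj_quantiles(pi_bar, info$grid$x),
                 s_samples = sm, surface = surface,
                 x = info$grid$x),
            class = "selhmm_traj")
}

.traj_quantiles <- function(pi_mat, x) {
  qs <- t(apply(pi_mat, 1, function(p) {
    cs <- cumsum(p)
    c(x[which(cs >= 0.025)[1]], x[which(cs >= 0.5)[1]], x[which(cs >= 0.975)[1]])
  }))
  data.frame(generation = seq_len(nrow(pi_mat)) - 1L,
             q2.5 = qs[, 1], q50 = qs[, 2], q97.5 = qs[, 3])
}

#' @export
print.selhmm_traj <- function(x, ...) {
  cat(sprintf("Posterior allele-frequency trajectory: %d generations, %d coefficient draws\n",
              nrow(x$pi), nrow(x$s_samples)))
  cat("head of quantiles:\n")
  print(utils::head(x$quantiles, 5), row.names = FALSE)
  invisible(x)
}

#' @export
plot.selhmm_traj <- function(x, ...) {
  q <- x$quantiles
  graphics::plot(q$generation, q$q50, type = "n", ylim = c(0, 1),
                 xlab = "generations before present",
                 ylab = "derived allele frequency", ...)
  graphics::polygon(c(q$generation, rev(q$generation)),
                    c(q$q2.5, rev(q$q97.5)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(q$generation, q$q50, col = "steelblue4", lwd = 2)
  invisible(x)
}
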
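logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# Internal: assemble grid, epoch/regime bookkeeping and compiled emissions
# for one dataset. Transition from column t-1 to column t crosses the
# generation t-2 -> t-1 boundary and is assigned the selection epoch and
# population size in force at generation t-2 (the younger end).
.prepare_data <- function(pop_freq, t_cutoff, K, N, N_history,
                          genotypes, haplotypes, trees, time_bins, approx_b) {
  if (is.null(N_history)) {
    if (is.null(N)) stop("supply 'N' or 'N_history'", call. = FALSE)
    N_history <- pop_size_history(0, N)
  } else if (!is.null(N)) stop("'N' and 'N_history' are mutually exclusive", call. = FALSE)
  if (length(pop_freq) != 1 || pop_freq <= 0 || pop_freq > 1)
    stop("'pop_freq' must be in (0, 1]", call. = FALSE)
  T <- as.integer(t_cutoff)
  if (T < 2) stop("'t_cutoff' must be >= 2", call. = FALSE)
  time_bins <- as.numeric(time_bins)
  if (length(time_bins) && (any(diff(time_bins) <= 0) || any(time_bins <= 0)))
    stop("'time_bins' must be positive and strictly increasing", call. = FALSE)
  if (any(time_bins >= T))
    stop("selection breakpoints must be younger than the horizon", call. = FALSE)
  grid <- freq_grid(K)
  init_bin <- nearest_bin(grid, pop_freq)
  gen <- 0:(T - 1)                      # generation crossed by step t = gen + 2
  epoch <- findInterval(gen, time_bins) + 1L
  Nvec <- N_at(N_history, gen)
  regime_key <- paste(epoch, Nvec)
  regimes <- !duplicated(regime_key)
  regime_id <- match(regime_key, regime_key[regimes])
  if (!is.null(trees) && inherits(trees, "tree_events")) trees <- list(trees)
  shared <- NULL
  if (!is.null(genotypes) || !is.null(haplotypes))
    shared <- compile_emissions(grid, T, genotypes = genotypes,
                                haplotypes = haplotypes)
  tree_parts <- NULL
  if (!is.null(trees))
    tree_parts <- lapply(trees, function(ev)
      compile_emissions(grid, T, events = ev, N_history = N_history))
  if (is.null(shared) && is.null(tree_parts))
    stop("at least one of 'genotypes', 'haplotypes', 'trees' is required",
         call. = FALSE)
  list(grid = grid, init_bin = init_bin, T = T, time_bins = time_bins,
       d = length(time_bins) + 1L, N_history = N_history,
       epoch_of_regime = epoch[regimes], N_of_regime = Nvec[regimes],
       step_model = regime_id, shared = shared, tree_parts = tree_parts,
       approx_b = approx_b,
       M = if (is.null(tree_parts)) 1L else length(tree_parts))
}

#' Importance-sampled log-likelihood-ratio objective
#'
#' Builds the function \eqn{s \mapsto \ln[P(D|s)/P(D|s=0)]} for a dataset.
#' With gene trees, the Monte Carlo estimator over the `M` sampled trees
#' \deqn{\frac{P(D|s)}{P(D|s=0)} \approx \frac{1}{M}\sum_m
#'   \frac{P(G_m|s)}{P(G_m|s=0)}}
#' is used; the trees are sampled once under neutrality and reweighted, so
#' the `s = 0` denominators are computed a single time and cached. With
#' genotype/haplotype data only, the ratio is the plain difference of
#' forward log-likelihoods. Transition models are cached per distinct
#' (selection epoch value, population size) pair. All evaluations are
#' recorded; retrieve them with [objective_trace()].
#'
#' @param pop_freq modern derived allele frequency in (0, 1\].
#' @param t_cutoff horizon `T` in generations (the chain spans ages 0 to
#'   `T - 1`).
#' @param K number of frequency bins (default 600).
#' @param N constant haploid population size (alternative to `N_history`).
#' @param N_history a [pop_size_history()].
#' @param genotypes,haplotypes,trees data sources ([genotype_obs()],
#'   [haplotype_obs()], a [tree_events()] or list of them — one per
#'   importance sample).
#' @param time_bins selection-epoch breakpoints (generations before
#'   present); `d = length(time_bins) + 1` coefficients are fit.
#' @param approx_b use the beam window approximation in the forward pass.
#' @return a function `f(s)` (length-`d` vector, each |s| <= 0.1 and finite;
#'   outside the box it returns `-Inf`) with attribute `"info"` holding the
#'   prepared dataset; `f(0) = 0` exactly.
#' @export
selhmm_objective <- function(pop_freq, t_cutoff, K = 600, N = NULL,
                             N_history = NULL, genotypes = NULL,
                             haplotypes = NULL, trees = NULL,
                             time_bins = numeric(0), approx_b = TRUE) {
  info <- .prepare_data(pop_freq, t_cutoff, K, N, N_history,
                        genotypes, haplotypes, trees, time_bins, approx_b)
  model_cache <- new.env(parent = emptyenv())
  get_models <- function(svec) {
    lapply(seq_along(info$epoch_of_regime), function(r) {
      se <- svec[info$epoch_of_regime[r]]
      Nr <- info$N_of_regime[r]
      key <- paste(format(se, digits = 17), Nr)
      m <- model_cache[[key]]
      if (is.null(m)) {
        m <- transition_model(info$grid, se, Nr)
        model_cache[[key]] <- m
      }
      m
    })
  }
  per_sample_loglik <- function(svec) {
    models <- get_models(svec)
    logE_list <- if (is.null(info$tree_parts)) {
      list(list(logE = info$shared$logE, one_derived = info$shared$one_derived))
    } else {
      lapply(info$tree_parts, function(tp) {
        le <- tp$logE
        if (!is.null(info$shared)) le <- le + info$shared$logE
        list(logE = le, one_derived = tp$one_derived)
      })
    }
    vapply(logE_list, function(em)
      run_forward(models, info$step_model, em$logE, info$init_bin, info$grid,
                  one_derived = em$one_derived, approx_b = info$approx_b,
                  keep_matrix = FALSE)$loglik,
      numeric(1))
  }
  null_loglik <- NULL
  trace <- list()
  f <- function(svec) {
    svec <- as.numeric(svec)
    if (length(svec) != info$d)
      stop(sprintf("expected %d selection coefficient(s)", info$d), call. = FALSE)
    if (any(!is.finite(svec)) || any(abs(svec) > 0.1)) return(-Inf)
    if (is.null(null_loglik)) null_loglik <<- per_sample_loglik(numeric(info$d))
    val <- if (all(svec == 0)) 0 else {
      ll <- per_sample_loglik(svec)
      logsumexp(ll - null_loglik) - log(info$M)
    }
    trace[[length(trace) + 1L]] <<- c(svec, val)
    val
  }
  attr(f, "info") <- info
  attr(f, "per_sample_loglr") <- function(svec)
    per_sample_loglik(svec) - {
      if (is.null(null_loglik)) null_loglik <<- per_sample_loglik(numeric(info$d))
      null_loglik
    }
  attr(f, "get_trace") <- function() {
    tr <- do.call(rbind, trace)
    colnames(tr) <- c(paste0("s", seq_len(info$d)), "lnlr")
    tr
  }
  class(f) <- c("selhmm_objective", "function")
  f
}

#' Evaluation trace of an objective
#'
#' Matrix of all `(s, lnLR)` pairs evaluated so far (non-finite values
#' excluded); used to fit the Gaussian likelihood surface for the posterior
#' trajectory.
#'
#' @param objective a [selhmm_objective()].
#' @export
objective_trace <- function(objective) {
  tr <- attr(objective, "get_trace")()
  tr[is.finite(tr[, ncol(tr)]), , drop = FALSE]
}

#' Brent maximization of a one-coefficient objective
#'
#' Maximizes `lnLR(s)` over \[-0.1, 0.1\] by Brent's method to an absolute
#' parameter tolerance of 1e-5. A maximizer within 1e-4 of a boundary is
#' snapped to it and flagged.
#'
#' @param objective function of a single coefficient (e.g.
#'   [selhmm_objective()] with no `time_bins`).
#' @return list with `s` (the MLE), `lnlr`, and `boundary` flag.
#' @export
maximize_single_epoch <- function(objective) {
  v0 <- objective(0)
  if (!is.finite(v0)) stop("objective not finite at s = 0", call. = FALSE)
  opt <- stats::optimize(function(s) objective(s), c(-0.1, 0.1),
                         maximum = TRUE, tol = 1e-5)
  s <- opt$maximum; val <- opt$objective
  boundary <- FALSE
  if (0.1 - abs(s) < 1e-4) {
    sb <- sign(s) * 0.1
    vb <- objective(sb)
    if (vb >= val) { s <- sb; val <- vb }
    boundary <- TRUE
  }
  if (val < v0) { s <- 0; val <- v0 }
  list(s = s, lnlr = val, boundary = boundary)
}

# Standard Nelder-Mead (reflection 1, expansion 2, contraction 0.5, shrink
# 0.5) maximizing f from a caller-supplied initial simplex; stops when the
# simplex diameter drops below `tol` or after `maxeval` evaluations.
.nelder_mead <- function(f, simplex, tol = 1e-5, maxeval = NULL) {
  d <- ncol(simplex)
  if (is.null(maxeval)) maxeval <- 500L * d
  n <- nrow(simplex)
  stopifnot(n == d + 1L)
  vals <- apply(simplex, 1, f)
  nev <- n
  repeat {
    ord <- order(vals, decreasing = TRUE)
    simplex <- simplex[ord, , drop = FALSE]
    vals <- vals[ord]
    diam <- max(dist(simplex))
    if (diam < tol || nev >= maxeval) break
    centroid <- colMeans(simplex[-n, , drop = FALSE])
    xr <- centroid + (centroid - simplex[n, ])
    fr <- f(xr); nev <- nev + 1L
    if (fr > vals[1]) {
      xe <- centroid + 2 * (centroid - simplex[n, ])
      fe <- f(xe); nev <- nev + 1L
      if (fe > fr) { simplex[n, ] <- xe; vals[n] <- fe }
      else { simplex[n, ] <- xr; vals[n] <- fr }
    } else if (fr > vals[n - 1]) {
      simplex[n, ] <- xr; vals[n] <- fr
    } else {
      xc <- if (fr > vals[n]) centroid + 0.5 * (xr - centroid)
            else centroid + 0.5 * (simplex[n, ] - centroid)
      fc <- f(xc); nev <- nev + 1L
      if (fc > max(fr, vals[n])) {
        simplex[n, ] <- xc; vals[n] <- fc
      } else {  # shrink toward the best vertex
        for (i in 2:n) {
          simplex[i, ] <- simplex[1, ] + 0.5 * (simplex[i, ] - simplex[1, ])
          vals[i] <- f(simplex[i, ]); nev <- nev + 1L
        }
      }
    }
  }
  list(par = simplex[1, ], value = vals[1], evals = nev)
}

#' Nelder-Mead maximization of a multi-epoch objective
#'
#' Starts from the simplex of the `d` points with `s = 0.01` in one epoch
#' and 0 elsewhere, plus the all-zero point, and maximizes `lnLR(s)` inside
#' the box \[-0.1, 0.1\]^d (enforced by a `-Inf` penalty in the objective).
#' Convergence at simplex diameter < 1e-5 or 500 d evaluations. After
#' convergence each coordinate is probed by +/- 1e-3; epochs along which
#' the objective is flat (no data in the epoch) are flagged
#' `wide_uncertainty`.
#'
#' @param objective a [selhmm_objective()] over `d >= 2` epochs.
#' @param d number of epochs.
#' @return list with `s`, `lnlr`, `evals`, `boundary`, `wide_uncertainty`
#'   (logical per epoch).
#' @export
maximize_multi_epoch <- function(objective, d) {
  stopifnot(d >= 2)
  simplex <- rbind(diag(0.01, d), rep(0, d))
  res <- .nelder_mead(objective, simplex, tol = 1e-5, maxeval = 500L * d)
  s <- res$par
  wide <- logical(d)
  for (i in seq_len(d)) {
    delta <- 1e-3
    up <- s; up[i] <- min(0.1, s[i] + delta)
    dn <- s; dn[i] <- max(-0.1, s[i] - delta)
    wide[i] <- max(abs(objective(up) - res$value),
                   abs(objective(dn) - res$value)) < 1e-7
  }
  list(s = s, lnlr = res$value, evals = res$evals,
       boundary = any(abs(s) > 0.1 - 1e-4), wide_uncertainty = wide)
}

#' Likelihood-ratio P-value and AIC
#'
#' By Wilks' theorem, `2 lnLR` under the null of neutrality follows a
#' chi-squared distribution with degrees of freedom equal to the number of
#' estimated selection coefficients. `-log10(P)` is computed in log space
#' and stays accurate far beyond double-precision underflow of P itself.
#' `model_aic()` returns `2 df - 2 lnLR`, so a model with one extra epoch is
#' preferred only when it raises the log-likelihood ratio by at least 1.
#'
#' @param lnlr natural-log likelihood ratio (clamped below at 0).
#' @param df number of estimated selection coefficients, >= 1.
#' @return `chi2_pvalue`: list with `p` and `minus_log10_p`.
#' @export
chi2_pvalue <- function(lnlr, df) {
  stopifnot(df >= 1)
  lnlr <- max(0, lnlr)
  lp <- stats::pchisq(2 * lnlr, df, lower.tail = FALSE, log.p = TRUE)
  list(p = exp(lp), minus_log10_p = -lp / log(10))
}

#' @rdname chi2_pvalue
#' @export
model_aic <- function(lnlr, df) {
  stopifnot(df >= 1)
  2 * df - 2 * max(0, lnlr)
}

#' Fit selection coefficients to allele-frequency data
#'
#' The main fitting function. Models the historic frequency of a derived
#' allele as a hidden Markov chain on an arcsine-spaced grid with Gaussian
#' drift-plus-selection transitions, computes the likelihood of ancient
#' genotypes/haplotypes, structured-coalescent gene-tree events, and
#' ancient tree leaves by the forward algorithm (integrating over sampled
#' trees by importance sampling when several are supplied), and maximizes
#' the log-likelihood ratio against neutrality over one selection
#' coefficient per epoch. Reports the Wilks chi-squared P-value and AIC.
#'
#' @inheritParams selhmm_objective
#' @return an object of class `"selhmm"` with components `epochs` (table of
#'   epoch bounds and MLEs), `s_mle`, `lnlr`, `df`, `p_value`,
#'   `minus_log10_p`, `aic`, `M` (importance samples), `ess` (effective
#'   sample size of the importance weights), `trace`, and flags. Methods:
#'   `print`, `summary`, `coef`, `logLik`, `plot`.
#' @examples
#' \donttest{
#' set.seed(1)
#' traj <- simulate_trajectory_backward(0.6, selection_schedule(0.02),
#'                                      pop_size_history(0, 20000), 200)
#' obs <- sample_ancient_genotypes(traj, sampling_schedule(seq(0, 199, 5), 4))
#' fit <- selhmm(pop_freq = 0.6, N = 20000, t_cutoff = 200,
#'               genotypes = obs, K = 150)
#' fit
#' }
#' @export
selhmm <- function(pop_freq, t_cutoff, K = 600, N = NULL, N_history = NULL,
                   genotypes = NULL, haplotypes = NULL, trees = NULL,
                   time_bins = numeric(0), approx_b = TRUE) {
  cl <- match.call()
  objective <- selhmm_objective(pop_freq, t_cutoff, K = K, N = N,
                                N_history = N_history, genotypes = genotypes,
                                haplotypes = haplotypes, trees = trees,
                                time_bins = time_bins, approx_b = approx_b)
  info <- attr(objective, "info")
  d <- info$d
  if (d == 1L) {
    opt <- maximize_single_epoch(objective)
    s <- opt$s; lnlr <- opt$lnlr
    boundary <- opt$boundary; wide <- FALSE
  } else {
    opt <- maximize_multi_epoch(objective, d)
    s <- opt$s; lnlr <- opt$lnlr
    boundary <- opt$boundary; wide <- opt$wide_uncertainty
  }
  lnlr <- max(0, lnlr)
  pv <- chi2_pvalue(lnlr, d)
  lw <- attr(objective, "per_sample_loglr")(s)
  wbar <- exp(lw - logsumexp(lw))
  ess <- 1 / sum(wbar^2)
  if (info$M > 1 && ess < info$M / 10)
    warning(sprintf(
      "importance-weight degeneracy: effective sample size %.1f of M = %d",
      ess, info$M), call. = FALSE)
  starts <- c(0, info$time_bins)
  ends <- c(info$time_bins, info$T)
  structure(list(
    epochs = data.frame(epoch_start = starts, epoch_end = ends, s_mle = s),
    s_mle = s, lnlr = lnlr, df = d, p_value = pv$p,
    minus_log10_p = pv$minus_log10_p, aic = model_aic(lnlr, d),
    M = info$M, ess = ess, boundary = boundary, wide_uncertainty = wide,
    trace = objective_trace(objective), objective = objective,
    K = info$grid$K, t_cutoff = info$T, pop_freq = pop_freq, call = cl),
    class = "selhmm")
}
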
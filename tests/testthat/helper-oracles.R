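# Brute-force dense forward/backward oracles, written independently of the
# package's banded C++ implementation: plain R matrix recursions over the
# full K x K transition matrix with per-column max rescaling.

dense_forward_oracle <- function(P, logE, init_bin) {
  K <- nrow(logE); Tn <- ncol(logE)
  Fm <- matrix(0, K, Tn)
  Fm[init_bin, 1] <- 1
  ls <- numeric(Tn)
  for (t in 2:Tn) {
    v <- as.numeric(crossprod(P, Fm[, t - 1])) * exp(logE[, t])
    m <- max(v)
    if (m <= 0) return(list(loglik = -Inf, F = Fm, logscale = ls))
    Fm[, t] <- v / m
    ls[t] <- ls[t - 1] + log(m)
  }
  list(loglik = log(sum(Fm[, Tn])) + ls[Tn], F = Fm, logscale = ls)
}

dense_backward_oracle <- function(P, logE) {
  K <- nrow(logE); Tn <- ncol(logE)
  B <- matrix(0, K, Tn)
  B[, Tn] <- 1
  ls <- numeric(Tn)
  for (t in (Tn - 1):1) {
    v <- as.numeric(P %*% (exp(logE[, t + 1]) * B[, t + 1]))
    m <- max(v)
    B[, t] <- v / m
    ls[t] <- ls[t + 1] + log(m)
  }
  list(B = B, logscale = ls)
}

# random genotype + tree fixture on a small grid, for oracle-equivalence
# checks; all quantities drawn from realistic ranges for ancient-DNA data
rand_fixture <- function(seed) {
  set.seed(seed)
  K <- sample(40:60, 1)
  Tn <- sample(20:50, 1)
  # the arcsine grid spacing is ~ pi sqrt(x(1-x)) / (K-1) while the drift
  # standard deviation is sqrt(x(1-x)/N), so the resolution ratio
  # sd/spacing = (K-1)/(pi sqrt(N)) is constant across the grid. Small-K
  # fixtures keep the same relative resolution (~0.4) the method's
  # recommended K = 600 has at realistic N, via N = ((K-1)/(pi r))^2.
  r <- runif(1, 0.38, 0.42)
  N <- round(((K - 1) / (pi * r))^2)
  s <- runif(1, -0.05, 0.05)
  f <- runif(1, 0.3, 0.7)
  g <- freq_grid(K)
  nh <- pop_size_history(0, N)
  traj <- simulate_trajectory_backward(f, selection_schedule(s), nh, Tn)
  gt <- sample_ancient_genotypes(
    traj, sampling_schedule(sample(0:(Tn - 2), 6), sample(1:3, 6, replace = TRUE)))
  trees <- NULL
  if (seed %% 2 == 0) {
    sim <- suppressMessages(simulate_structured_coalescent(
      traj, n_modern_derived = 3, n_modern_ancestral = 2,
      ancient_derived = sample(1:(Tn - 3), 1),
      ancient_ancestral = sample(1:(Tn - 3), 1),
      N_history = nh, horizon = Tn - 1))
    trees <- sim$events
  }
  list(grid = g, K = K, Tn = Tn, N = N, s = s, f = f, genotypes = gt,
       trees = trees, N_history = nh)
}

# log-likelihood of a fixture via the dense oracle (exact transitions, no
# banding), averaging over tree samples in linear space when present
fixture_dense_loglik <- function(fx, s) {
  P <- transition_model(fx$grid, s, fx$N, banded = FALSE)$P
  em <- compile_emissions(fx$grid, fx$Tn, genotypes = fx$genotypes,
                          events = fx$trees, N_history = fx$N_history)
  dense_forward_oracle(P, em$logE, nearest_bin(fx$grid, fx$f))$loglik
}

fixture_banded_loglik <- function(fx, s, approx_b) {
  m <- transition_model(fx$grid, s, fx$N)
  em <- compile_emissions(fx$grid, fx$Tn, genotypes = fx$genotypes,
                          events = fx$trees, N_history = fx$N_history)
  run_forward(list(m), rep(1L, fx$Tn), em$logE, nearest_bin(fx$grid, fx$f),
              fx$grid, one_derived = em$one_derived,
              approx_b = approx_b)$loglik
}
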
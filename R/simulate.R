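#' Sampling schedule for ancient individuals or leaves
#'
#' @param times sampling times in generations before present (>= 0).
#' @param n numbers sampled at each time (recycled).
#' @return data frame of class `"sampling_schedule"`.
#' @export
sampling_schedule <- function(times, n) {
  d <- data.frame(t = as.numeric(times), n = as.integer(n))
  if (any(d$t < 0) || any(d$n < 0)) stop("times and counts must be >= 0", call. = FALSE)
  class(d) <- c("sampling_schedule", "data.frame")
  d
}

#' Simulate an allele-frequency trajectory backward in time
#'
#' Model-matched generator: starting from the modern frequency `f`, each
#' step back in time draws from the transition density of the inference
#' HMM itself, Normal([backward_mean()]`(x, s_t)`, `x(1-x)/N(t)`), clipped
#' to \[0, 1\] with exact absorption at the boundaries. Because the
#' generator and the likelihood share one transition law, estimator
#' consistency is exactly testable on its output.
#'
#' @param f modern derived allele frequency.
#' @param schedule a [selection_schedule()].
#' @param N_history a [pop_size_history()].
#' @param T number of generations to simulate back.
#' @param seed optional integer seed.
#' @return numeric vector of length `T + 1`; element `i` is the frequency
#'   `i - 1` generations before present.
#' @export
simulate_trajectory_backward <- function(f, schedule, N_history, T, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(schedule, "selection_schedule"),
            inherits(N_history, "pop_size_history"), T >= 1)
  x <- numeric(T + 1)
  x[1] <- f
  for (a in 0:(T - 1)) {
    cur <- x[a + 1]
    if (cur <= 0 || cur >= 1) { x[a + 2] <- round(cur); next }
    mu <- backward_mean(cur, s_at(schedule, a))
    nxt <- stats::rnorm(1, mu, sqrt(cur * (1 - cur) / N_at(N_history, a)))
    x[a + 2] <- min(1, max(0, nxt))
  }
  x
}

#' Simulate a Wright-Fisher trajectory forward in time
#'
#' Binomial Wright-Fisher reproduction with additive selection (fitnesses
#' 1, 1+s/2, 1+s): the deterministic selection response is
#' \eqn{x' = x(2 + s + sx)/(2 + 2sx)} and the next generation counts are
#' Binomial(`N`, x'). Used to probe robustness of the Gaussian-transition
#' model to the exact reproduction law.
#'
#' @param x0 starting frequency.
#' @param s selection coefficient.
#' @param N haploid population size.
#' @param T generations to simulate forward.
#' @param seed optional integer seed.
#' @return numeric vector of length `T + 1` (forward time, element 1 = start).
#' @export
simulate_wright_fisher_forward <- function(x0, s, N, T, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(x0 >= 0, x0 <= 1, N >= 2)
  x <- numeric(T + 1)
  x[1] <- x0
  for (t in seq_len(T)) {
    cur <- x[t]
    if (cur <= 0 || cur >= 1) { x[t + 1] <- cur; next }
    xp <- cur * (2 + s + s * cur) / (2 + 2 * s * cur)
    x[t + 1] <- stats::rbinom(1, N, xp) / N
  }
  x
}

#' Sample ancient genotypes along a trajectory
#'
#' Each sampled diploid's derived-allele count is Binomial(2, x_t) at the
#' trajectory frequency of its sampling time; hard calls by default. With
#' `error_blend` in (0, 1\], each record's likelihood triple is mixed
#' toward flat likelihoods, emulating low-coverage genotype uncertainty.
#'
#' @param traj trajectory from [simulate_trajectory_backward()] (element
#'   `i` = frequency at `i - 1` generations before present).
#' @param schedule a [sampling_schedule()] of diploid individuals.
#' @param seed optional integer seed.
#' @param error_blend proportion of flat likelihood mixed into each record.
#' @return a [genotype_obs()].
#' @export
sample_ancient_genotypes <- function(traj, schedule, seed = NULL, error_blend = 0) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(schedule, "sampling_schedule"))
  if (any(schedule$t > length(traj) - 1))
    stop("sampling time beyond the simulated trajectory", call. = FALSE)
  idx <- rep(seq_len(nrow(schedule)), schedule$n)
  if (!length(idx))
    return(genotype_obs(numeric(0), numeric(0), numeric(0), numeric(0)))
  tt <- schedule$t[idx]
  xx <- traj[floor(tt) + 1]
  cnt <- stats::rbinom(length(tt), 2, xx)
  L <- matrix(0, length(tt), 3)
  L[cbind(seq_along(tt), cnt + 1L)] <- 1
  if (error_blend > 0) L <- (1 - error_blend) * L + error_blend
  genotype_obs(tt, L[, 1], L[, 2], L[, 3])
}

# One lineage bookkeeping record for the structured-coalescent simulator.
.new_lineage <- function(label, age, cls, mixed = FALSE)
  list(nwk = label, head_age = age, cls = cls, mixed = mixed)

#' Simulate a gene tree under the structured coalescent
#'
#' Backward-in-time simulation conditional on an allele-frequency
#' trajectory: within each generation, derived pairs coalesce at rate
#' \eqn{\binom{n_D}{2}/(x_t N)} and ancestral pairs at
#' \eqn{\binom{n_A}{2}/((1-x_t) N)} (rates frozen within the generation);
#' ancient leaves activate at their ages. When the trajectory is absorbed
#' at 0 the last derived lineage (the mixed lineage, on which the mutation
#' arose) transfers to the ancestral class; its eventual coalescence is the
#' mixed coalescence. If the frequency reaches 0 while two or more derived
#' lineages remain, the remaining derived pairs are merged immediately at
#' that step (reported via a message), never an error. The trajectory is
#' extended at its oldest value if the grand MRCA is older than its end.
#'
#' @param traj frequency by age as in [sample_ancient_genotypes()].
#' @param n_modern_derived,n_modern_ancestral modern sample configuration.
#' @param ancient_derived,ancient_ancestral ages of ancient derived /
#'   ancestral leaves.
#' @param N_history a [pop_size_history()].
#' @param seed optional integer seed.
#' @param horizon stop the simulation at this age (generations); lineages
#'   still active then are left open (events beyond a horizon never enter
#'   the likelihood anyway). Default `Inf` runs to the grand MRCA.
#' @return list with `events` (a [tree_events()]), `newick` (the simulated
#'   labelled tree, or `NA` if truncated; derived leaves named `D1..`,
#'   ancestral `A1..`), `labels` (named 0/1 vector) and `complete`.
#' @export
simulate_structured_coalescent <- function(traj, n_modern_derived,
                                           n_modern_ancestral,
                                           ancient_derived = numeric(0),
                                           ancient_ancestral = numeric(0),
                                           N_history, seed = NULL,
                                           horizon = Inf) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_modern_derived + length(ancient_derived) >= 1)
  lineages <- list()
  for (i in seq_len(n_modern_derived))
    lineages[[length(lineages) + 1L]] <- .new_lineage(paste0("D", i), 0, "D")
  for (i in seq_len(n_modern_ancestral))
    lineages[[length(lineages) + 1L]] <- .new_lineage(paste0("A", i), 0, "A")
  pend_D <- sort(ancient_derived)
  pend_A <- sort(ancient_ancestral)
  nmd <- n_modern_derived; nma <- n_modern_ancestral
  der_coal <- anc_coal <- numeric(0)
  mixed_age <- NA_real_
  forced <- 0L

  merge_pair <- function(i, j, age) {
    if (i > j) { k <- i; i <- j; j <- k }
    la <- lineages[[i]]; lb <- lineages[[j]]
    nwk <- sprintf("(%s:%.10g,%s:%.10g)", la$nwk, age - la$head_age,
                   lb$nwk, age - lb$head_age)
    cls <- if (la$cls == "D" && lb$cls == "D") "D" else "A"
    was_mixed <- la$mixed || lb$mixed
    lineages[[i]] <<- list(nwk = nwk, head_age = age, cls = cls, mixed = FALSE)
    lineages[[j]] <<- NULL
    was_mixed
  }
  classes <- function(cl) which(vapply(lineages, function(l) l$cls == cl, logical(1)))

  a <- 0
  xlen <- length(traj)
  while (a < horizon &&
         (length(lineages) > 1L || length(pend_D) || length(pend_A))) {
    x <- traj[min(a + 2, xlen)]   # frequency at the interval's older end
    N <- N_at(N_history, a)
    # absorbed at 0: >= 2 derived lineages cannot persist; then the single
    # remaining derived lineage is the mixed lineage and turns ancestral
    di <- classes("D")
    while (x <= 0 && length(di) >= 2) {
      pr <- sample(di, 2L)
      merge_pair(pr[1], pr[2], a)
      der_coal <- c(der_coal, a)
      forced <- forced + 1L
      di <- classes("D")
    }
    if (x <= 0 && length(di) == 1L) {
      lineages[[di]]$cls <- "A"
      lineages[[di]]$mixed <- TRUE
    }
    if (x >= 1) {                 # symmetric absorption for the ancestral class
      ai <- classes("A")
      while (length(ai) >= 2) {
        pr <- sample(ai, 2L)
        merge_pair(pr[1], pr[2], a)
        anc_coal <- c(anc_coal, a)
        forced <- forced + 1L
        ai <- classes("A")
      }
    }
    # exponential race across the unit interval [a, a+1); rates frozen at
    # this generation's counts-at-entry are refreshed after each event
    # (memoryless), with leaf activations at their exact ages
    acts <- sort(c(pend_D[pend_D >= a & pend_D < a + 1],
                   pend_A[pend_A >= a & pend_A < a + 1]))
    u <- 0
    repeat {
      di <- classes("D"); ai <- classes("A")
      rD <- if (length(di) >= 2 && x > 0) choose(length(di), 2) / (x * N) else 0
      rA <- if (length(ai) >= 2 && x < 1) choose(length(ai), 2) / ((1 - x) * N) else 0
      wD <- if (rD > 0) stats::rexp(1, rD) else Inf
      wA <- if (rA > 0) stats::rexp(1, rA) else Inf
      w <- min(wD, wA)
      nxt_act <- if (length(acts)) acts[1] - a else Inf
      if (nxt_act <= w && nxt_act < 1) {     # a leaf activates first
        age <- acts[1]
        id <- which(abs(pend_D - age) < 1e-12)
        if (length(id)) {
          nmd <- nmd + 1L
          lineages[[length(lineages) + 1L]] <- .new_lineage(paste0("D", nmd), age, "D")
          pend_D <- pend_D[-id[1]]
        } else {
          ia <- which(abs(pend_A - age) < 1e-12)
          nma <- nma + 1L
          lineages[[length(lineages) + 1L]] <- .new_lineage(paste0("A", nma), age, "A")
          pend_A <- pend_A[-ia[1]]
        }
        acts <- acts[-1]
        u <- age - a
        next
      }
      if (u + w >= 1) break                  # interval ends without an event
      u <- u + w
      age <- a + u
      if (wD < wA) {
        pr <- sample(di, 2L)
        merge_pair(pr[1], pr[2], age)
        der_coal <- c(der_coal, age)
      } else {
        pr <- sample(ai, 2L)
        was_mixed <- merge_pair(pr[1], pr[2], age)
        anc_coal <- c(anc_coal, age)
        if (was_mixed) mixed_age <- age
      }
    }
    a <- a + 1
  }
  if (forced > 0)
    message(sprintf("%d forced coalescence(s) at a frequency-0 step", forced))
  complete <- length(lineages) == 1L && !length(pend_D) && !length(pend_A)
  newick <- if (complete) paste0(lineages[[1]]$nwk, ";") else NA_character_
  leaf_names <- c(if (nmd) paste0("D", seq_len(nmd)),
                  if (nma) paste0("A", seq_len(nma)))
  labels <- stats::setNames(c(rep(1L, nmd), rep(0L, nma)), leaf_names)
  ev <- tree_events(der_coal = der_coal, anc_coal = anc_coal,
                    mixed_age = mixed_age,
                    der_leaves = ancient_derived, anc_leaves = ancient_ancestral,
                    n_der_modern = n_modern_derived,
                    n_anc_modern = n_modern_ancestral)
  list(events = ev, newick = newick, labels = labels, complete = complete)
}

#' Sample frequency paths from the HMM posterior
#'
#' Forward-filtering backward-sampling: runs the forward pass at the given
#' coefficient and draws joint frequency paths from the exact conditional
#' distribution given the data. Combined with
#' [simulate_structured_coalescent()] this provides a posterior sampler of
#' gene trees given genotype data under neutrality, emulating tree sampling
#' from an inferred genealogy.
#'
#' @param objective a [selhmm_objective()] built on the dataset.
#' @param s coefficient vector at which to condition (default all 0).
#' @param n_paths number of paths.
#' @param seed optional integer seed.
#' @return `n_paths x T` matrix of frequencies; column `t` is `t - 1`
#'   generations before present.
#' @export
sample_posterior_paths <- function(objective, s = NULL, n_paths = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  info <- attr(objective, "info")
  if (is.null(s)) s <- numeric(info$d)
  models <- lapply(seq_along(info$epoch_of_regime), function(r)
    transition_model(info$grid, s[info$epoch_of_regime[r]], info$N_of_regime[r]))
  em <- if (is.null(info$tree_parts)) info$shared else
    stop("path sampling is supported for genotype/haplotype data", call. = FALSE)
  fw <- run_forward(models, info$step_model, em$logE, info$init_bin, info$grid,
                    one_derived = em$one_derived, approx_b = FALSE,
                    keep_matrix = TRUE)
  if (!fw$ok) stop("cannot sample paths: data impossible", call. = FALSE)
  Tn <- info$T; K <- info$grid$K
  out <- matrix(NA_real_, n_paths, Tn)
  for (p in seq_len(n_paths)) {
    k <- sample.int(K, 1, prob = fw$F[, Tn])
    out[p, Tn] <- info$grid$x[k]
    for (t in (Tn - 1):1) {
      P <- models[[info$step_model[t + 1]]]$P
      wgt <- fw$F[, t] * P[, k]
      k <- sample.int(K, 1, prob = wgt)
      out[p, t] <- info$grid$x[k]
    }
  }
  out
}

#' Rejection-sampling posterior oracle
#'
#' Exact posterior sampling for a fixed set of hard-called genotype
#' observations under a uniform prior on a single selection coefficient:
#' repeatedly draws `s` uniformly from \[-0.1, 0.1\], simulates a backward
#' trajectory, samples genotype counts at the observation times, and
#' retains the trajectory only when the simulated genotype counts match
#' the observed ones exactly at every time. The accepted trajectories and
#' coefficients are an exact joint posterior sample, used to validate the
#' Monte Carlo trajectory integration.
#'
#' @param observations a [genotype_obs()] with hard calls.
#' @param f modern frequency.
#' @param N constant haploid population size.
#' @param T horizon in generations.
#' @param n_accept accepted trajectories required (1,000 in the validation
#'   design).
#' @param seed optional integer seed.
#' @param max_draws error if this many proposals fail to produce
#'   `n_accept` acceptances (acceptance too low for the oracle).
#' @return list with `s` (accepted coefficients), `traj`
#'   (`n_accept x (T+1)` trajectories) and `quantiles` (per-generation
#'   2.5/50/97.5% of the accepted trajectories).
#' @export
rejection_posterior_oracle <- function(observations, f, N, T, n_accept = 1000,
                                       seed = NULL, max_draws = 5e6) {
  if (!is.null(seed)) set.seed(seed)
  L <- as.matrix(observations[c("L_AA", "L_AD", "L_DD")])
  hard <- max.col(L)
  if (any(abs(rowSums(L) - apply(L, 1, max)) > 1e-12))
    stop("the oracle requires hard-called genotypes", call. = FALSE)
  ot <- floor(observations$t)
  obs_counts <- table(factor(ot, levels = sort(unique(ot))),
                      factor(hard, levels = 1:3))
  times <- as.integer(rownames(obs_counts))
  if (any(times > T)) stop("observation beyond the horizon", call. = FALSE)
  acc_s <- numeric(0)
  acc_traj <- NULL
  drawn <- 0
  batch <- 20000L
  while (length(acc_s) < n_accept) {
    if (drawn >= max_draws)
      stop("acceptance rate too low for the rejection oracle; use a smaller dataset",
           call. = FALSE)
    B <- batch
    s <- stats::runif(B, -0.1, 0.1)
    X <- matrix(0, B, T + 1)
    X[, 1] <- f
    for (g in 1:T) {
      cur <- X[, g]
      mu <- cur + s * cur * (cur - 1) / (2 * s * cur + 2)
      nxt <- stats::rnorm(B, mu, sqrt(pmax(cur * (1 - cur), 0) / N))
      nxt[cur <= 0] <- 0; nxt[cur >= 1] <- 1
      X[, g + 1] <- pmin(1, pmax(0, nxt))
    }
    ok <- rep(TRUE, B)
    for (i in seq_along(times)) {
      xg <- X[, times[i] + 1]
      n_i <- sum(obs_counts[i, ])
      p2 <- xg^2; p1 <- 2 * xg * (1 - xg)
      nDD <- stats::rbinom(B, n_i, p2)
      pr <- ifelse(p2 >= 1, 0, pmin(1, pmax(0, p1 / (1 - p2))))
      nAD <- stats::rbinom(B, n_i - nDD, pr)
      ok <- ok & nDD == obs_counts[i, 3] & nAD == obs_counts[i, 2]
    }
    drawn <- drawn + B
    if (any(ok)) {
      acc_s <- c(acc_s, s[ok])
      acc_traj <- rbind(acc_traj, X[ok, , drop = FALSE])
    }
  }
  acceptance <- length(acc_s) / drawn
  acc_s <- acc_s[seq_len(n_accept)]
  acc_traj <- acc_traj[seq_len(n_accept), , drop = FALSE]
  qs <- apply(acc_traj, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  list(s = acc_s, traj = acc_traj, acceptance = acceptance,
       quantiles = data.frame(generation = 0:T, q2.5 = qs[1, ],
                              q50 = qs[2, ], q97.5 = qs[3, ]))
}

#' Simulation scenario presets
#'
#' Canned study designs used throughout validation:
#' \describe{
#' \item{`"three_epoch"`}{Ancient genotypes under epoch-wise selection
#'   s = 0.01 on \[0, 200), 0 on \[200, 600), -0.005 on \[600, 800);
#'   N = 70,000 haploid, 8 diploids sampled every generation, modern
#'   frequency 0.75.}
#' \item{`"single_epoch"`}{Ancient genotypes under one coefficient
#'   (default 0.01), N = 50,000, 2 diploids per generation, T = 400,
#'   modern frequency 0.75.}
#' }
#'
#' @param name scenario name.
#' @param seed optional integer seed for the replicate.
#' @param s override of the generating coefficient(s).
#' @return list with `genotypes`, `truth` (generating parameters) and the
#'   `trajectory` used.
#' @export
sim_scenario <- function(name = c("three_epoch", "single_epoch"), seed = NULL,
                         s = NULL) {
  name <- match.arg(name)
  if (!is.null(seed)) set.seed(seed)
  if (name == "three_epoch") {
    truth <- list(s = if (is.null(s)) c(0.01, 0, -0.005) else s,
                  time_bins = c(200, 600), N = 70000, T = 800, f = 0.75,
                  diploids_per_gen = 8)
  } else {
    truth <- list(s = if (is.null(s)) 0.01 else s, time_bins = numeric(0),
                  N = 50000, T = 400, f = 0.75, diploids_per_gen = 2)
  }
  sched <- selection_schedule(truth$s, truth$time_bins)
  nh <- pop_size_history(0, truth$N)
  traj <- simulate_trajectory_backward(truth$f, sched, nh, truth$T)
  gt <- sample_ancient_genotypes(
    traj, sampling_schedule(0:(truth$T - 2), truth$diploids_per_gen))
  list(genotypes = gt, truth = truth, trajectory = traj)
}
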
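#' Ancient genotype, haplotype, and tree-event observation containers
#'
#' `genotype_obs()` holds ancient diploid genotype records: a sampling time
#' `t` in generations before present and the three genotype likelihoods
#' P(reads | genotype) on the linear scale (any common scaling of a record's
#' three likelihoods cancels in likelihood ratios). `haplotype_obs()` is the
#' haploid analogue with two likelihoods. Hard calls are encoded as
#' likelihood 1 for the called genotype and 0 elsewhere.
#'
#' @param t sampling times (generations before present, >= 0).
#' @param L_AA,L_AD,L_DD genotype likelihoods (ancestral homozygote,
#'   heterozygote, derived homozygote), each >= 0, at least one positive
#'   per record.
#' @return a data frame of class `"genotype_obs"` / `"haplotype_obs"`.
#' @export
genotype_obs <- function(t, L_AA, L_AD, L_DD) {
  d <- data.frame(t = as.numeric(t), L_AA = as.numeric(L_AA),
                  L_AD = as.numeric(L_AD), L_DD = as.numeric(L_DD))
  .check_obs(d, c("L_AA", "L_AD", "L_DD"))
  class(d) <- c("genotype_obs", "data.frame")
  d
}

#' @rdname genotype_obs
#' @param L_A,L_D haplotype likelihoods for the ancestral / derived allele.
#' @export
haplotype_obs <- function(t, L_A, L_D) {
  d <- data.frame(t = as.numeric(t), L_A = as.numeric(L_A), L_D = as.numeric(L_D))
  .check_obs(d, c("L_A", "L_D"))
  class(d) <- c("haplotype_obs", "data.frame")
  d
}

.check_obs <- function(d, cols) {
  if (any(d$t < 0)) stop("observation times must be >= 0", call. = FALSE)
  L <- as.matrix(d[cols])
  if (any(L < 0) || any(!is.finite(L)))
    stop("likelihoods must be finite and >= 0", call. = FALSE)
  zero <- rowSums(L) == 0
  if (any(zero))
    stop(sprintf("all-zero likelihoods in record(s) %s",
                 paste(which(zero), collapse = ", ")), call. = FALSE)
  invisible(d)
}

#' Tree-derived event list
#'
#' Coalescence and leaf-sampling events extracted from one labelled gene
#' tree, in generations before present. The list of ancestral coalescences
#' includes the mixed coalescence (the parent node of the oldest derived
#' coalescence, where the lineage on which the mutation arose joins the
#' ancestral class); its age is also recorded separately in `mixed_age`
#' because it decrements the derived rather than the ancestral lineage
#' count and can only be emitted at frequency 0.
#'
#' @param der_coal,anc_coal derived / ancestral coalescence node ages.
#' @param mixed_age age of the mixed coalescence node (must appear in
#'   `anc_coal`), or `NA` when the mutation arose above the tree root (all
#'   leaves derived).
#' @param der_leaves,anc_leaves ages of ancient (> 0) derived / ancestral
#'   leaves.
#' @param n_der_modern,n_anc_modern numbers of modern (age-0) derived and
#'   ancestral leaves.
#' @return object of class `"tree_events"`.
#' @export
tree_events <- function(der_coal = numeric(0), anc_coal = numeric(0),
                        mixed_age = NA_real_, der_leaves = numeric(0),
                        anc_leaves = numeric(0), n_der_modern, n_anc_modern) {
  ev <- list(der_coal = sort(as.numeric(der_coal)),
             anc_coal = sort(as.numeric(anc_coal)),
             mixed_age = as.numeric(mixed_age),
             der_leaves = sort(as.numeric(der_leaves)),
             anc_leaves = sort(as.numeric(anc_leaves)),
             n_der_modern = as.integer(n_der_modern),
             n_anc_modern = as.integer(n_anc_modern))
  if (ev$n_der_modern + length(ev$der_leaves) < 1L)
    stop("at least one derived leaf is required", call. = FALSE)
  if (any(unlist(ev[1:5]) < 0, na.rm = TRUE))
    stop("event ages must be >= 0", call. = FALSE)
  if (!is.na(ev$mixed_age) && !any(abs(ev$anc_coal - ev$mixed_age) < 1e-9))
    stop("'mixed_age' must be one of the ancestral coalescence ages", call. = FALSE)
  ndl <- ev$n_der_modern + length(ev$der_leaves)
  # complete trees satisfy equality; horizon-truncated event lists may keep
  # more open derived lineages than one
  if (ndl - length(ev$der_coal) < 1L)
    stop("(#derived leaves) - (#derived coalescences) must be at least 1 (the mixed lineage)",
         call. = FALSE)
  structure(ev, class = "tree_events")
}

#' Hardy-Weinberg genotype emission vector
#'
#' Probability of the genotype records observed at one timestep for each
#' frequency bin:
#' \deqn{e(k) = \prod_g [x_k^2 L_{DD} + 2 x_k (1-x_k) L_{AD} + (1-x_k)^2 L_{AA}]}
#' i.e. two binomial draws per diploid from the bin frequency. Flat
#' likelihoods give exactly 1 (the Hardy-Weinberg weights sum to 1).
#'
#' @param grid a [freq_grid()].
#' @param obs a [genotype_obs()] (any times; all records are used).
#' @return numeric length-`K` emission vector.
#' @export
genotype_emission <- function(grid, obs) {
  exp(.geno_logemission(grid$x, obs))
}

.geno_logemission <- function(x, obs) {
  le <- numeric(length(x))
  for (i in seq_len(nrow(obs)))
    le <- le + log(x^2 * obs$L_DD[i] + 2 * x * (1 - x) * obs$L_AD[i] +
                     (1 - x)^2 * obs$L_AA[i])
  le
}

#' @rdname genotype_emission
#' @details `haplotype_emission()` uses
#'   \eqn{e(k) = \prod [x_k L_D + (1-x_k) L_A]}.
#' @export
haplotype_emission <- function(grid, obs) {
  exp(.haplo_logemission(grid$x, obs))
}

.haplo_logemission <- function(x, obs) {
  le <- numeric(length(x))
  for (i in seq_len(nrow(obs)))
    le <- le + log(x * obs$L_D[i] + (1 - x) * obs$L_A[i])
  le
}

# log of the exponential waiting-time emission for one lineage class over a
# unit interval: events at sorted offsets `off` in [0, 1), starting lineage
# count m0, rate pairs(m)/scale per bin with scale = class_freq * N.
# Returns list(const, n_events, pair_time) so that
# log e(k) = const - n_events * log(scale_k) - pair_time / scale_k.
.exp_waiting_terms <- function(m0, off) {
  d <- length(off)
  counts <- m0 - seq_len(d) + 1L
  pairsv <- counts * (counts - 1) / 2
  if (d > 0 && any(pairsv <= 0)) return(NULL)  # impossible events
  dt <- diff(c(0, off))
  mend <- m0 - d
  pair_time <- sum(pairsv * dt) + mend * (mend - 1) / 2 * (1 - if (d) off[d] else 0)
  list(const = sum(log(pairsv)), n_events = d, pair_time = pair_time)
}

# Vectorized log coalescent emission over all bins for one unit interval.
# x: grid frequencies; n_d includes the mixed lineage; anc offsets include
# the mixed coalescence when it falls in this interval (mixed = TRUE).
.coal_logemission <- function(x, N, n_d, n_a, der = numeric(0),
                              anc = numeric(0)) {
  K <- length(x)
  le <- numeric(K)
  if (length(der) && n_d < 2)
    stop("malformed schedule: derived coalescence with fewer than 2 derived lineages",
         call. = FALSE)
  interior <- if (K > 2) 2:(K - 1) else integer(0)
  if (n_d == 0) {
    # mutation no longer segregating: the chain must sit at frequency 0
    le[] <- -Inf
    if (n_a > 1) {
      at <- .exp_waiting_terms(n_a, anc)
      le[1] <- if (is.null(at)) -Inf else
        at$const - at$n_events * log(N) - at$pair_time / N
    } else {
      le[1] <- if (length(anc)) -Inf else 0
    }
    return(le)
  }
  # derived class, interior bins and bin K (x = 1)
  dt <- .exp_waiting_terms(n_d, der)
  if (is.null(dt)) { le[] <- -Inf; return(le) }
  sc <- x * N
  idx <- c(interior, K)
  le[idx] <- le[idx] + dt$const - dt$n_events * log(sc[idx]) - dt$pair_time / sc[idx]
  # ancestral class, interior bins
  if (n_a >= 1) {
    at0 <- .exp_waiting_terms(n_a, anc)
    if (n_d == 1 && n_a == 1) {
      # mixed lineage alone with the last ancestral lineage: nothing can be
      # observed away from frequency 0
      le[interior] <- 0
      le[K] <- 0
    } else {
      if (is.null(at0)) {
        le[interior] <- -Inf
      } else if (n_a > 1) {
        sca <- (1 - x) * N
        le[interior] <- le[interior] + at0$const -
          at0$n_events * log(sca[interior]) - at0$pair_time / sca[interior]
      }
      # x = 1: infinite ancestral coalescence rate when >= 2 ancestral lineages
      le[K] <- if (n_a >= 2) -Inf else le[K]
    }
  }
  # bin 1 (frequency 0): >= 2 derived lineages impossible; exactly one
  # derived (the mixed) lineage behaves as ancestral with n_a + 1 lineages
  if (n_d >= 2) {
    le[1] <- -Inf
  } else {  # n_d == 1
    at1 <- .exp_waiting_terms(n_a + 1L, c(der, anc))
    le[1] <- if (is.null(at1)) -Inf else
      at1$const - at1$n_events * log(N) - at1$pair_time / N
  }
  le
}

#' Structured-coalescent emission for one unit time interval
#'
#' Probability, for one frequency bin, of the derived and ancestral
#' coalescences observed in a unit interval, given the lineage counts
#' entering it. Within a class with `m` lineages and class frequency `p`,
#' pairs coalesce at exponential rate \eqn{\binom{m}{2}/(pN)}; the emission
#' is the product of the waiting-time densities at the observed offsets and
#' the survival probability to the end of the interval. At frequency 0 the
#' single remaining derived (mixed) lineage is treated as ancestral; two or
#' more derived lineages at frequency 0, or two or more ancestral lineages
#' at frequency 1, are impossible (emission 0).
#'
#' @param grid a [freq_grid()].
#' @param k frequency bin index.
#' @param N haploid population size over the interval.
#' @param n_d derived lineage count entering the interval (includes the
#'   mixed lineage).
#' @param n_a ancestral lineage count entering the interval.
#' @param derived,ancestral ascending event offsets in \[0, 1); `ancestral`
#'   includes the mixed coalescence if it falls in this interval.
#' @return emission probability (linear scale).
#' @export
interval_coalescent_emission <- function(grid, k, N, n_d, n_a,
                                         derived = numeric(0),
                                         ancestral = numeric(0)) {
  stopifnot(inherits(grid, "freq_grid"), k >= 1, k <= grid$K, n_a >= 0, n_d >= 0)
  le <- .coal_logemission(grid$x, N, n_d, n_a, sort(derived), sort(ancestral))
  exp(le[k])
}

#' Ancient-leaf emission multiplier
#'
#' Sampling `m_D` derived and `m_A` ancestral leaves in an interval
#' multiplies the emission by \eqn{x_k^{m_D} (1-x_k)^{m_A}}; the lineage
#' counts increase accordingly from the next interval on.
#'
#' @param x frequency (vectorized).
#' @param m_D,m_A numbers of derived / ancestral leaves sampled.
#' @export
leaf_emission_multiplier <- function(x, m_D, m_A) {
  x^m_D * (1 - x)^m_A
}

# Map an observation age (generations before present) to the recursion step
# that carries the chain across it: ages in [t-1, t) are emitted at step
# t + 1, i.e. step floor(age) + 2.
.age_to_step <- function(age) floor(age) + 2L

#' Compile an emission schedule
#'
#' Combines genotype, haplotype, and tree-event emissions into the
#' `K x T` natural-log emission matrix consumed by [run_forward()] /
#' [run_backward()]: per-step emissions from independent sources multiply
#' (add in log). Steps without observations emit all ones (log 0).
#' Observations too old to have a carrying step inside the horizon
#' (age >= `T - 1`) are dropped with a warning. For tree data, the per-step
#' flag of exactly one remaining derived lineage is exposed for the beam
#' approximation.
#'
#' @param grid a [freq_grid()].
#' @param T horizon: number of forward-matrix columns (column `t` is `t - 1`
#'   generations before present), >= 2.
#' @param genotypes optional [genotype_obs()].
#' @param haplotypes optional [haplotype_obs()].
#' @param events optional [tree_events()].
#' @param N_history a [pop_size_history()] (needed for coalescent rates).
#' @return list with `logE` (`K x T`), `one_derived` (length `T`), and
#'   `n_sources`.
#' @export
compile_emissions <- function(grid, T, genotypes = NULL, haplotypes = NULL,
                              events = NULL, N_history = NULL) {
  T <- as.integer(T)
  if (T < 2L) stop("'T' must be >= 2", call. = FALSE)
  n_sources <- sum(!is.null(genotypes), !is.null(haplotypes), !is.null(events))
  if (n_sources == 0L) stop("at least one data source is required", call. = FALSE)
  K <- grid$K
  x <- grid$x
  logE <- matrix(0, K, T)
  one_derived <- logical(T)

  add_obs <- function(obs, logfun) {
    step <- .age_to_step(obs$t)
    drop <- step > T
    if (any(drop)) {
      warning(sprintf("%d observation(s) older than the horizon dropped", sum(drop)),
              call. = FALSE)
      obs <- obs[!drop, , drop = FALSE]
      step <- step[!drop]
    }
    for (s in unique(step))
      logE[, s] <<- logE[, s] + logfun(x, obs[step == s, , drop = FALSE])
  }
  if (!is.null(genotypes)) add_obs(genotypes, .geno_logemission)
  if (!is.null(haplotypes)) add_obs(haplotypes, .haplo_logemission)

  if (!is.null(events)) {
    if (is.null(N_history)) stop("'N_history' is required with tree events", call. = FALSE)
    stopifnot(inherits(events, "tree_events"))
    horizon <- T - 1
    clip <- function(v) {
      if (any(v >= horizon))
        warning(sprintf("%d tree event(s) at or beyond the horizon dropped",
                        sum(v >= horizon)), call. = FALSE)
      v[v < horizon]
    }
    der_coal <- clip(events$der_coal)
    anc_coal <- clip(events$anc_coal)
    der_leaves <- clip(events$der_leaves)
    anc_leaves <- clip(events$anc_leaves)
    mixed_age <- events$mixed_age
    n_d <- events$n_der_modern
    n_a <- events$n_anc_modern
    for (t in 2:T) {
      lo <- t - 2
      in_iv <- function(v) v[v >= lo & v < lo + 1] - lo
      dc <- in_iv(der_coal)
      ac <- in_iv(anc_coal)
      # force the beam window down to bin 1 once at most one derived lineage
      # remains: the mixed coalescence (and everything after it) can only be
      # emitted at frequency 0 and must never be pruned away
      one_derived[t] <- n_d <= 1L
      logE[, t] <- logE[, t] +
        .coal_logemission(x, N_at(N_history, lo), n_d, n_a, dc, ac)
      m_D <- sum(der_leaves >= lo & der_leaves < lo + 1)
      m_A <- sum(anc_leaves >= lo & anc_leaves < lo + 1)
      if (m_D) logE[, t] <- logE[, t] + m_D * log(x)
      if (m_A) logE[, t] <- logE[, t] + m_A * log(1 - x)
      # update lineage counts for the next (older) interval
      n_d <- n_d - length(dc)
      mixed_here <- !is.na(mixed_age) && mixed_age >= lo && mixed_age < lo + 1
      if (mixed_here) {
        n_d <- n_d - 1L       # the mixed lineage joins the ancestral class
        n_a <- n_a - (length(ac) - 1L)
      } else {
        n_a <- n_a - length(ac)
      }
      if (n_d < 0L || n_a < 0L)
        stop("malformed schedule: lineage count fell below 0", call. = FALSE)
      n_d <- n_d + m_D
      n_a <- n_a + m_A
    }
  }
  list(logE = logE, one_derived = one_derived, n_sources = n_sources)
}

#' Read ancient genotype / haplotype likelihood files
#'
#' Whitespace-delimited text with a header line `#time logL_AA logL_AD
#' logL_DD` (genotypes) or `#time logL_A logL_D` (haplotypes); times in
#' generations before present, likelihoods in natural log (hard calls:
#' 0 for the called genotype, -1e9 elsewhere).
#'
#' @param path file path.
#' @return a [genotype_obs()] / [haplotype_obs()].
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) != 4) stop("genotype file must have 4 columns", call. = FALSE)
  genotype_obs(tab[[1]], exp(tab[[2]]), exp(tab[[3]]), exp(tab[[4]]))
}

#' @rdname read_genotypes
#' @export
read_haplotypes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) != 3) stop("haplotype file must have 3 columns", call. = FALSE)
  haplotype_obs(tab[[1]], exp(tab[[2]]), exp(tab[[3]]))
}

#' @rdname read_genotypes
#' @param obs observations to write.
#' @export
write_genotypes <- function(obs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#time logL_AA logL_AD logL_DD", con)
  utils::write.table(data.frame(obs$t, log(obs$L_AA), log(obs$L_AD), log(obs$L_DD)),
                     con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
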
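---
title: "Modelling selection on allele-frequency trajectories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling selection on allele-frequency trajectories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selhmm)
```

# The model

`selhmm` estimates per-generation selection coefficients acting on a derived
allele from three kinds of evidence: time-stamped ancient genotypes (or
haplotypes) with per-genotype likelihoods, gene trees at the focal site with
derived/ancestral leaf labels, and gene trees that additionally contain
ancient leaves. The latent variable is the historic trajectory of the derived
allele frequency, treated as the hidden state of an HMM that runs backward in
time from the present.

**States.** The unit interval is discretized into `K` bins at the quantiles
of a Beta(1/2, 1/2) distribution, $x_k = \sin^2(\pi w_k / 2)$ for equally
spaced $w_k$. The spacing is proportional to $\sqrt{x(1-x)}$, which is also
how the drift standard deviation scales, so the grid's resolution relative to
one generation of drift is constant across frequencies (this identity is used
repeatedly below). Bins 1 and `K` sit exactly at 0 and 1 and are absorbing.

**Transitions.** Under additive selection (fitnesses $1$, $1+s/2$, $1+s$),
the expected frequency one generation back is
$x + s\,x(x-1)/(2sx+2)$, and the transition from bin $k$ spreads a Gaussian
with that mean and variance $x_k(1-x_k)/N$ over the bin cells, where $N$ is
the *haploid* effective population size. A piecewise-constant $N(t)$ and
epoch-wise coefficients $s_t$ (breakpoints supplied by the user, never
estimated) are supported; transition matrices are cached per distinct
$(s_t, N(t))$ pair.

**Emissions.** Ancient diploid genotypes emit Hardy–Weinberg mixtures of
their genotype likelihoods; haplotypes emit the one-draw analogue. A labelled
gene tree emits, per unit interval, exponential waiting-time densities for
the coalescences observed in that interval — within the derived class at rate
$\binom{n_D}{2}/(x_kN)$, within the ancestral class at
$\binom{n_A}{2}/((1-x_k)N)$ — times the survival probability to the interval
end. The lineage on which the mutation arose (the *mixed lineage*, the parent
branch of the oldest derived coalescence) is counted in $n_D$ but treated
specially at frequency 0: there it behaves as an extra ancestral lineage, so
its eventual coalescence — the mixed coalescence — can only be emitted at
$x=0$. States with $\ge 2$ derived lineages at $x=0$, or $\ge 2$ ancestral
lineages at $x=1$, have emission 0 (their coalescence rate diverges). Once no
derived lineage remains, the chain is pinned at frequency 0. Ancient leaves
multiply the emission by $x_k^{m_D}(1-x_k)^{m_A}$ and increment the lineage
counts from the following interval on.

**Likelihood and inference.** The forward algorithm starts from a point mass
at the bin nearest the modern frequency and returns
$P(D|s)=\sum_k F_{k,T}$ under uniform exit probabilities. The log-likelihood
*ratio* against $s=0$ is maximized — by Brent's method on $[-0.1, 0.1]$ for a
single coefficient (parameter tolerance $10^{-5}$), by Nelder–Mead for $d$
epochs starting from the simplex of the $d$ points with $s=0.01$ in one epoch
and 0 elsewhere plus the origin, constrained to the box by a $-\infty$
penalty, stopping at simplex diameter $10^{-5}$ or $500d$ evaluations (both
tolerances are our choices; the optimizer and simplex are part of the
method). $2\ln LR$ is referred to a $\chi^2_d$ distribution, $-\log_{10}P$ is
computed in log space so it remains exact past floating-point underflow, and
AIC $=2d-2\ln LR$ ranks epoch models.

**Importance sampling over trees.** When `M` sampled marginal trees are
supplied (sampled once, under neutrality, by an external tool), the
likelihood ratio is estimated as
$\frac{1}{M}\sum_m P(G_m|s)/P(G_m|0)$; the neutral denominators are computed
once and cached. The effective sample size of the weights, $1/\sum \bar
w_m^2$, is reported and a warning is raised below $M/10$ (weight degeneracy).
With a single estimated coefficient and few samples this estimator is biased
toward 0 — the prior under which the trees were sampled — and the bias
disappears as `M` grows; the test suite reproduces both properties.

# Time alignment conventions

Column $t$ of the forward matrix is $t-1$ generations before present. An
observation with age $a \in [t-1, t)$ is emitted at recursion step $t+1$, the
step that carries the chain across that interval; coalescence offsets within
an interval are measured from its young end, and rates use the lineage counts
entering the interval, with sampled leaves taking effect from the next
interval. Events with age $\ge T-1$ have no carrying step inside the horizon
and are dropped with a warning at schedule compilation. Ancient leaves
sampled exactly at an interval boundary belong to the younger interval. These
conventions are applied uniformly; they shift each observation's effective
binding by at most one generation, which is far below the drift and sampling
noise at realistic parameter values.

# Computational approximations

Three approximations make the forward–backward passes fast, and all are
optional (`banded = FALSE`, `approx_b = FALSE` give exact modes used as
oracles in the tests):

* **A1 (banded transitions).** Each row keeps only bins whose frequency lies
  within 3.3 standard deviations of the row mean (99.9% of the Gaussian
  mass) and is then rescaled to sum to 1.
* **A2 (banded sums).** The forward sum for bin $k$ runs only over the
  nonzero rows of column $k$; the backward pass analogously uses row bands.
  Given A1 this adds no further error.
* **B (beam window, forward only).** Each new column is computed only inside
  a window derived from the previous column: the smallest central window
  obtained by trimming at most 0.05% of mass from each tail, expanded to
  $(x_\alpha - 2(x_\beta - x_\alpha) - 0.1,\; x_\beta + 2(x_\beta-x_\alpha) +
  0.1)$. Entries outside are exactly 0. Whenever at most one derived lineage
  remains the window is forced down to bin 1, so the mixed coalescence at
  frequency 0 is never pruned away. (We extend the forcing from "exactly
  one" to "at most one" remaining derived lineage: after the mixed
  coalescence every emission is concentrated on bin 1, and a window that
  excluded it would zero the whole column.)

**When A1 is accurate.** Because spacing and drift share the
$\sqrt{x(1-x)}$ profile, a single ratio $\rho = (K-1)/(\pi\sqrt{N})$ — drift
standard deviation per bin spacing — governs the band everywhere on the
grid. The outermost band cell's boundary sits at roughly
$(\lfloor 3.3\rho \rfloor + 1/2)/\rho$ standard deviations, so the truncated
(and re-scaled) mass per step oscillates with $\rho$: near $\rho \approx
0.4$ the boundary is ~3.75 SD out and the per-step distortion is about
$2\times10^{-4}$, while unfavourable $\rho$ (band cut just inside a cell
boundary, or $\rho$ so small the row freezes onto its own bin) can distort
the absolute log-likelihood by 0.1 or more over tens of steps. At the
default `K = 600` and realistic $N$ the ratio lands in the benign range, and
likelihood-*ratio* quantities cancel most of the residual row-rescaling
inflation. The oracle-equivalence tests therefore draw their small-`K`
fixtures with $N = ((K-1)/(\pi\rho))^2$, $\rho \sim U(0.38, 0.42)$ — the
same relative resolution the recommended settings have — and verify
agreement with the exact dense forward to 0.01 (A1+A2) and 0.1 (adding B).
Outside that regime the band approximation genuinely degrades; if in doubt,
rerun with `approx_b = FALSE` and a larger `K`.

`K` defaults to 600 (configurable); the number of bins used in published
analyses of this kind. All likelihood math is in natural-log space with
per-column rescaling, so horizons of ~1000 generations with thousands of
emissions do not underflow.

# Posterior trajectories

The marginal posterior of the frequency at time $t$ is $\pi_t(k) \propto
F_{k,t}B_{t,k}$. Rather than conditioning on $\hat s$ alone (which
understates uncertainty), the likelihood-ratio surface evaluated during
optimization is approximated by a scaled Gaussian density centred at
$\hat s$: the covariance and a free scale are fitted by least squares to
$\exp(\ln LR_j - \ln LR_{\max})$ (points more than 30 log units below the
maximum are dropped — they carry no likelihood and destabilize the fit).
`n_samples` coefficients (default $10^d$; we read the ambiguous "10d" as
$10^d$ since $10\cdot d$ draws would be far too few for stable averaging)
are drawn from that Gaussian truncated to the optimization box, and the
fixed-$s$ posteriors are averaged. Quantiles (2.5/50/97.5%) are read off the
averaged per-generation mass. With several importance-sampled trees the
per-sample posteriors are combined with normalized importance weights at
each sampled $s$.

A rejection sampler provides an exact validation oracle on small datasets:
draw $s$ uniformly from $[-0.1, 0.1]$, simulate a backward trajectory,
sample genotype counts at the observation times, and keep only exact
matches of the observed counts. The retained $(s, X)$ pairs are an exact
posterior sample; the test suite requires the Monte Carlo bands to overlap
the oracle's bands at $\ge 90\%$ of time points.

# Synthetic data generators

The primary generator is *model-matched*: it draws each backward step from
the HMM's own Gaussian transition law (clipped to $[0,1]$, exact absorption
at the boundaries), so estimator consistency is exactly testable on its
output. A forward binomial Wright–Fisher generator (same fitness scheme) is
provided to probe robustness to the exact reproduction law. Genotypes are
two binomial draws per diploid from the trajectory frequency at the sampling
time; a blending option mixes the hard-call likelihoods toward flat triples
to emulate low coverage. The structured-coalescent simulator runs the same
frozen per-generation exponential races the emission model assumes, so the
two sides of tree-likelihood tests share one definition of the process; it
returns both the event list and a labelled Newick tree (the infinite-sites
clade property holds by construction). If the frequency hits 0 while two or
more derived lineages remain, the remaining derived pairs are merged
immediately at that step and a message is issued.

The three-epoch validation study uses the generating conditions stated with
the method's multi-epoch design: coefficients 0.01 / 0 / −0.005 with
breakpoints at 200 and 600 generations, $N = 70{,}000$ haploid, eight
diploids sampled per generation. The horizon (800 generations) and modern
frequency (0.75) are the preset's defaults. Twenty replicates at `K = 600`
keep the full study inside a few minutes on one core; per-epoch means across
replicates are required to land within three empirical standard errors of
the generating coefficients.

What passing these tests shows — and does not. The generators emulate
drift, selection, HWE sampling and the structured coalescent, but not
relatedness among sampled individuals, genotype-caller biases beyond a flat
blend, ARG-inference miscalibration, background selection, or population
structure. Tests passing on this synthetic data validate the implementation
and the statistical machinery, not those field effects.

# Degenerate inputs and numerical edges

* Rows at $x=0,1$ are exact point masses, not Gaussian limits.
* An all-zero forward column (impossible data, e.g. a derived coalescence
  while the chain is confined to frequency 0) returns $-\infty$ with a flag,
  never an exception.
* $\ln LR$ is clamped below at 0 before the $\chi^2$ test (optimizer noise
  can leave it at $-10^{-9}$).
* A maximizer within $10^{-4}$ of $\pm0.1$ is snapped to the boundary and
  flagged. Epochs along which the objective is flat (no data) are flagged
  `wide_uncertainty` via post-fit probes of $\pm10^{-3}$.
* Minimum-flip relabelling enumerates every node's leaf set (single leaves
  included, the empty set excluded — a segregating allele needs a derived
  leaf) and breaks ties to the first minimizing clade in a preorder
  traversal of the Newick string; the reference tool's exact tie-break rule
  is unpublished, so ties may resolve differently there.
* Importance-sample files carry `Modern:` and `Mixed:` lines beyond the
  coalescence/leaf lists because the emission bookkeeping needs the modern
  leaf counts and must know which ancestral-list event retires the mixed
  lineage.

# Known limitations

Breakpoint positions are taken as given (a grid search over breakpoints with
extra degrees of freedom is the user's job); no dominance parameter; no
recurrent mutation; trees are consumed as externally sampled event lists —
no ARG inference is performed. The rejection oracle requires datasets small
enough for exact matching to be feasible and refuses otherwise.
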
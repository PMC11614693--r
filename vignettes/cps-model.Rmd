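---
title: "The CPS model: latent disease ordering from quantitative neuropathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CPS model: latent disease ordering from quantitative neuropathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpstraj)
```

## Motivation and model

Immunohistochemistry image analysis yields, per donor, counts of stained
objects per standardised area in each cortical layer: tangle-bearing
neurons, amyloid plaques, microglia, astrocytes, neuronal nuclei, and so
on. Ordinal stagings (Braak, Thal, ADNC) discretise severity coarsely;
donors within the same stage differ widely in local burden. The package's
central object is a latent, continuous pseudoprogression score (CPS)
$t_d \in [0,1]$ per donor, estimated jointly with the dynamics of every
measurement.

Pathological aggregates are well described by exponential growth or decay
in time, so the observation model takes the Poisson rate of measurement
$m$ in layer $l$ to be log-linear in the latent time:

$$X_d^{m,l} \sim \mathrm{Poisson}\!\left(e^{k_m^l\, t_{\pi(d)} + a_m^l}\right),$$

where $k_m^l$ is the exponential rise (or fall) rate and $a_m^l$ the log
initial level. A permutation $\pi$ assigns donors to the slots of a sorted
time vector $t$; sampling $\pi$ explicitly makes the latent-space
exploration a matter of reordering donors rather than moving many
continuous coordinates through each other.

The priors are:

* $\pi$ uniform over permutations;
* sorted times $t$ uniform over increasing sequences in $[0,1]$ — i.e. the
  law of sorted $\mathrm{Uniform}(0,1)$ order statistics. Equivalently the
  gaps $(t_1, t_2 - t_1, \dots, 1 - t_D)$ are uniform on the simplex;
  this is the unique exchangeable flat prior on an increasing sequence,
  and we adopt it as the meaning of a "uniform partition-simplex" prior;
* $a_m, k_m \sim \mathcal N(0,1)$ population-level dynamics, and
  $a_m^l \sim \mathcal N(a_m, 1)$, $k_m^l \sim \mathcal N(k_m, 1)$ at the
  layer level. The unit hierarchical standard deviation lets layers borrow
  strength from their measurement without forcing them to agree.

Masked (unmeasured) cells simply drop out of the likelihood; no imputation
is performed.

### The direction degeneracy

The likelihood is exactly invariant under
$(t, k, a) \mapsto (1 - t \text{ reversed}, -k, a + k)$: a disease that
"runs backwards" with negated rates fits identically. Only the prior on
$(a, k)$ breaks the tie, and negligibly so. `orient_draws()` resolves the
degeneracy after sampling by applying the exact flip to every draw whose
anchor measurement has a negative population slope. The anchor defaults to
the measurement with the largest posterior mean |slope|; in real panels one
would anchor on a variable known to increase with pathology (e.g. the
pTau-bearing-cell count), so that CPS = 1 is maximal burden. Because the
flip is an exact likelihood symmetry, orientation is pure post-processing:
each draw's likelihood is unchanged (verified to 1e-8 in the tests) and
applying the flip twice is the identity.

## Inference

A block Gibbs sampler cycles through three conditional updates per sweep.

**Times.** Given $\pi$ and the dynamics, each sorted time $t_j$ has a full
conditional proportional to the Poisson likelihood of the donor occupying
slot $j$, restricted to $(t_{j-1}, t_{j+1})$ (boundary slots clamp to
$[0,1]$); the order-statistics prior is flat on that bracket. We update
each slot by shrinkage slice sampling, which preserves the target without
tuning parameters and reduces to an exact uniform draw when the likelihood
is flat — so a data-free run provably leaves the prior invariant, a
property the test suite checks against the Beta$(j, D+1-j)$ marginals of
uniform order statistics.

**Permutation.** The conditional over $\pi$ is intractable for all but
tiny $D$. Following the Gumbel-Sinkhorn construction, we form the
$D \times D$ score matrix $S_{dj}$ = log-likelihood of donor $d$'s cells at
slot time $t_j$, perturb it with i.i.d. Gumbel(0,1) noise, balance
$\exp((S+G)/\tau)$ to a doubly stochastic matrix by Sinkhorn iterations in
log space, and round to a hard permutation by maximum-weight bipartite
matching. This is an approximate conditional draw, and the package
documents its bias rather than hiding it: at $D = 2$ the two perturbed
matching totals differ by a sum of two independent logistic variables
(one per matched entry pair), not the single logistic that would reproduce
the exact softmax, so sampled frequencies are pulled toward 1/2 relative
to the exact conditional. The deviation grows with the score gap; at the
moderate gaps exercised in the tests it is 0.02–0.03 in absolute
frequency. Two further structural notes: (i) row/column balancing adds
constants to every perfect matching's total, so the hard rounding is
invariant to the Sinkhorn step and to the temperature — the relaxed matrix
matters for diagnostics, while the sampling distribution is fixed by the
Gumbel perturbation; (ii) with the noise switched off the block reduces
exactly to the maximum-weight assignment, which the tests verify against
exhaustive enumeration.

**Dynamics.** Given $(t, \pi)$, measurements are conditionally
independent. The population parameters are conjugate —
$a_m \mid a_m^{1:L} \sim \mathcal N\!\big(\sum_l a_m^l/(L+1),\ 1/(L+1)\big)$
— and are drawn exactly. Layer parameters are updated one at a time by
random-walk Metropolis on their Poisson-likelihood-plus-prior conditional.
Proposal scales adapt toward a 0.44 acceptance rate (the univariate
optimum) during burn-in only and are frozen afterwards, so retained draws
come from a fixed kernel satisfying detailed balance. Correctness is
checked three ways: prior recovery on an all-masked panel, agreement with
a grid-search maximum on an informative single-measurement panel, and a
Geweke-style successive-conditional simulation that must keep the
parameter marginals at the prior.

**Initialisation and chains.** Times start at equal spacing $j/(D+1)$;
the permutation starts from the donors' total observed counts (an
informative guess at the severity ordering) perturbed by Gumbel jitter so
chains start differently; dynamics start from the prior. Each chain is
seeded deterministically from the master seed, making every run exactly
reproducible. Convergence is reported as split-$\hat R$ on each donor's
CPS; the package deliberately has no automatic stopping rule.

### Defaults that matter

| parameter | default | meaning |
|---|---|---|
| `n_sweeps`, `burn_in` | 500, 100 | Gibbs sweeps per chain; burn-in doubles as the adaptation window |
| `n_chains` | 2 | independently initialised chains, pooled after orientation |
| `sinkhorn_temperature` | 1 | relaxation temperature (diagnostics only — see above) |
| `sinkhorn_iters` | 100 | balancing iterations; row/col sums reach 1 within 1e-6 well before this on well-conditioned scores |
| `dynamics_steps_per_sweep` | 2 | Metropolis scans per sweep; cheap relative to the permutation block |

## The synthetic-data generator

`simulate_dataset()` draws from exactly the generative model above, with
known ground truth (times, permutation, dynamics) returned alongside the
panel. Its defaults define the package's study conditions:

* population slopes $k_m \sim \mathcal N(0, \texttt{slope\_scale}^2)$ and
  intercepts $a_m \sim \mathcal N(0, \texttt{intercept\_scale}^2)$; layer
  deviations with standard deviation `layer_sd` (the model's prior value
  is 1; recovery studies use 0.25 so that layers of one measurement agree
  on direction, as stained-object counts in neighbouring layers do);
* `time_spacing = "equal"` places donors at $d/(D+1)$ — a deterministic
  grid convenient for recovery studies; `"uniform_order_statistics"`
  matches the prior exactly;
* the donor-to-slot permutation is a seeded random shuffle, so input row
  order carries no information and the $\pi$-inference path is exercised;
* missingness is completely at random (`missing_fraction`) — the neutral
  default absent a known mechanism for which sections fail staining or
  quantification; one observed cell per donor and measurement is reinstated if
  masking removes a whole row or column, preserving the dataset
  invariants;
* `n_null_measurements` appends variables with all slopes exactly zero —
  nuisance variables whose counts provably carry no ordering information
  (checked by a permutation-null Spearman bound);
* rates above 1e12 abort the simulation: counts per unit tissue area at
  such magnitudes are physically meaningless and only arise from
  degenerate scale settings.

The generator emulates the statistical structure of layer-resolved
neuropathology panels, not their imaging provenance: no segmentation
noise, staining batch effects, spatial correlation between neighbouring
layers beyond the shared measurement mean, or comorbidity co-occurrence.
Passing recovery tests on these panels demonstrates that the sampler
inverts its own generative model at realistic sizes — it does not
demonstrate robustness to the model misspecification real panels surely
carry.

The reference recovery condition used in tests and in
`scripts/acceptance.R` is a 40-donor, 6-measurement, 5-layer panel with
`slope_scale = 3`, `intercept_scale = 1`, `layer_sd = 0.25`, equal
spacing, panel seed 1. There the posterior-mean CPS reaches Spearman
$|\rho| \ge 0.9$ (typically 0.96–0.99) against the true times with 500
sweeps, 100 burn-in and 2 chains. Panels whose six slope draws all land
near zero are genuinely uninformative — the posterior is then honestly
diffuse (per-donor sd around 0.25) and rank recovery degrades; that is an
information limit, not a sampler failure.

## Trajectory analyses

**Z-scores and smoothing.** Each variable (measurement-layer pair) is
standardised across observed donors (sd with denominator $n-1$);
zero-variance or under-observed variables are excluded with a warning
rather than divided by zero. For heatmap display along the CPS ordering, a
centred moving average of width 5 donors (truncated at the edges, missing
entries ignored per window) smooths each variable; 5 is local relative to
a cohort of ~80 donors while suppressing single-donor noise, and is a
parameter, not a constant.

**Co-correlation clustering.** Variables are clustered by average-linkage
agglomeration on the distance $1 - r$ (Pearson, pairwise-complete donors);
average linkage is the standard choice for correlation-structure heatmaps
and is recorded in the output so it can be swapped. Pairs with fewer than
3 complete observations get the maximal distance 2. The number of clusters
is a parameter defaulting to 8 — a data-dependent choice that suits panels
with roughly eight coherent variable families (plaque burden, tangle
burden, neuronal density, glial markers, ...); anticorrelated families
(e.g. pathology counts versus NeuN immunoreactivity) land in different
clusters by construction, since $r = -1$ maps to the maximal distance.

**Five-bin change tests.** The CPS axis is divided into five equal bins
(left-closed, last bin closed at 1). "Did this variable change in bin $b$
relative to the least-affected donors?" is answered by least squares on
bin indicators with bin 0 as reference — the simplest additive model whose
per-bin coefficients, t-statistics and two-tailed p-values are exactly
what per-bin change heatmaps display. Smoother spline bases would
interpolate between bins and blur the question the bins exist to ask, so
they are deliberately out of scope. Bins with fewer than two observations
are flagged untested; a zero-residual-variance fit reports p = 0 for
nonzero effects with a degenerate-fit flag. Across a batch of
variables × layers × bins, Benjamini–Hochberg controls the FDR at
$\alpha$ (default 0.05), and each variable's first significant bin is
reported. Calibration is verified by simulation: null rejection rates per
bin fall in [0.03, 0.07] at $\alpha = 0.05$, and a late step change is
localised to the correct bins in ≥95% of runs.

**LOESS bootstrap.** Trend curves with uncertainty come from repeating a
degree-1 LOESS fit (tricube weights, span 0.6) on 1,000 random 80%
subsamples (without replacement) and reporting the pointwise mean and
standard deviation across fits as the trend and its s.e. Degree-1 local
regression is exact on linear data, which pins the implementation to
machine precision in tests; grid points outside a subsample's x-range are
extrapolated by the direct-surface evaluator and counted in the output.
The span and kernel are reported with every curve since they are choices,
not data.

## Numerical and interface choices

* $\log(X!)$ via `lgamma(X + 1)` for stability at large counts.
* All Sinkhorn arithmetic in log space; balanced log-probabilities are
  clamped at −1e6 before matching (harmless: dominated entries only).
* Slice updates cap shrinkage at 100 steps and return the current point on
  a degenerate (zero-width) bracket.
* Non-integer values in input tables are rounded half up onto the Poisson
  support, with a count of modified cells reported — the choice of
  area-normalisation that would make real densities integers is upstream
  of this package.
* Tabular artifacts are CSV with a commented metadata header (tool
  version, subcommand, seed, effective config and its hash — no
  timestamps, so equal-seed runs are byte-identical); parameter structures
  are JSON; raw draws are a single uncompressed RDS whose layout is the
  documented `cps_draws` structure.
* The test suite runs the heavier checks at deliberately scaled sizes
  chosen as part of the package's design: the prior-recovery study uses a
  4-donor all-masked panel over 20,000 retained sweeps; the recovery study
  uses the 40-donor reference panel above; bootstrap and calibration
  simulations use hundreds to a thousand replicates.

## Known limitations

* The permutation block is approximate; its bias is quantified at $D = 2$
  but not corrected. A Metropolis acceptance step on top of the
  Gumbel-Sinkhorn proposal would make it exact at extra cost.
* The Poisson observation family is fixed; overdispersed panels would need
  a negative binomial variant, which the interfaces do not currently
  expose.
* CPS is identified only up to the direction flip; orientation requires an
  anchor whose expected direction is known (or trusting the
  largest-|slope| heuristic).
* Covariate adjustment (age, sex, APOE genotype) is out of scope here and
  belongs downstream of CPS estimation.
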
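# cpstraj

Quantitative neuropathology panels measure, for every brain donor, the
density of stained objects (pTau/AT8-bearing neurons, 6E10+ amyloid plaques,
NeuN+ nuclei, GFAP+ astrocytes, ...) in each cortical layer. Categorical
stagings such as Braak, Thal or ADNC compress this information into a few
ordinal levels and hide the wide variation in local burden within each
level. `cpstraj` instead places each donor on a **continuous
pseudoprogression score (CPS)** in [0, 1], inferred directly from the
layer-resolved counts, and provides the descriptive machinery to study how
every variable changes along that axis.

## The model

Counts `X[d, m, l]` for donor `d`, measurement `m` and cortical layer `l`
are modelled as Poisson draws whose log-rate is linear in a latent donor
time, reflecting exponential aggregation dynamics of pathology:

    pi            ~ Uniform(permutations of 1..D)
    t             ~ Uniform order statistics on [0, 1]   (sorted times)
    a_m, k_m      ~ Normal(0, 1)                          (population)
    a_m^l         ~ Normal(a_m, 1)                        (layer level)
    k_m^l         ~ Normal(k_m, 1)
    X[d, m, l]    ~ Poisson(exp(k_m^l * t[pi(d)] + a_m^l))

Donor `d`'s CPS is the posterior mean of `t[pi(d)]`. The hierarchy borrows
strength across layers: layer-level dynamics `(a_m^l, k_m^l)` are shrunk
toward per-measurement population values `(a_m, k_m)`.

Inference is a block Gibbs sampler:

* **times** — slice sampling of each sorted time within its neighbour
  bracket (this leaves the uniform order-statistics prior invariant);
* **permutation** — Gumbel-Sinkhorn: perturb the donor-by-slot
  log-likelihood score matrix with Gumbel noise, balance it to a doubly
  stochastic matrix by Sinkhorn iterations, round to a hard permutation by
  maximum-weight bipartite matching (an approximate conditional draw);
* **dynamics** — exact conjugate draws for the population level and
  adaptive random-walk Metropolis for the layer level.

The likelihood is exactly invariant under the direction flip
`(t, k, a) -> (1 - t reversed, -k, a + k)`; `orient_draws()` resolves this
by constraining an anchor measurement's population slope to be nonnegative,
so the CPS increases with pathology.

Downstream, the package reproduces the standard trajectory analyses:
per-variable z-scores, moving-average smoothing along the CPS ordering,
co-correlation hierarchical clustering of variables, five-bin change tests
(piecewise-constant fits with two-tailed t-statistics and
Benjamini–Hochberg correction) and subsample-bootstrap LOESS trend curves
(mean and pointwise s.e. over repeated fits on 80% subsamples).

## Worked example

```r
library(cpstraj)

sim <- simulate_dataset(simulation_config(n_donors = 30, n_measurements = 4,
                        n_layers = 3, slope_scale = 3, layer_sd = 0.25, seed = 8))
sim$dataset
#> neuropath_dataset: 30 donors x 4 measurements x 3 layers (100.0% observed)

draws <- orient_draws(run_gibbs(sim$dataset,
          gibbs_config(n_sweeps = 300, burn_in = 100, n_chains = 2, seed = 9)))
res <- summarize_cps(draws)
head(res, 4)
#>   donor_id cps_mean cps_sd cps_q05 cps_q95 rank rhat
#> 1 donor_01    0.615  0.023  0.5740    0.65   20  1.8
#> 2 donor_02    0.708  0.016  0.6783    0.73   23  1.6
#> 3 donor_03    0.034  0.032  0.0013    0.10    3  1.3
#> 4 donor_04    0.432  0.037  0.3641    0.48   16  1.8

cor(res$cps_mean, sim$truth$donor_times, method = "spearman")
#> 0.997
```

Each donor gets a posterior mean CPS with spread (`cps_sd`, 90% interval),
a rank, and a split-R̂ convergence diagnostic. On this synthetic panel the
inferred ordering matches the simulated truth almost perfectly
(Spearman 0.997).

Trajectory statistics along the fitted CPS:

```r
vm <- variable_matrix(sim$dataset, donor_order = order(res$cps_mean))
tests <- per_bin_change_batch(vm, res$cps_mean, n_bins = 5)
head(subset(tests$tests, significant), 4)
#>     variable bin n effect     t        p    p_adj significant
#> 7  meas_2@L1   3 6    208  5.34 1.54e-05 1.48e-04        TRUE
#> 8  meas_2@L1   4 5    527 12.77 1.87e-12 2.99e-11        TRUE
#> 23 meas_2@L2   3 6    116  5.15 2.52e-05 2.02e-04        TRUE
#> 24 meas_2@L2   4 5    323 13.54 5.17e-13 1.24e-11        TRUE
```

`meas_2` (the steepest simulated variable) first departs from the
lowest-CPS bin in bin 3, i.e. beyond CPS 0.6 — the late, exponential phase
of its dynamics; flat variables stay nonsignificant after correction.

A command-line wrapper around the same functions supports
`simulate`, `fit`, `preprocess` and `trajectory` subcommands:

```sh
Rscript inst/cli/cps.R simulate --donors 30 --measurements 4 --layers 3 \
    --seed 8 --out data.csv --truth truth.json
Rscript inst/cli/cps.R fit --input data.csv --sweeps 300 --burn-in 100 \
    --chains 2 --seed 9 --out-prefix run1
```

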
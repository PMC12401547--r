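# camtrapISDM

Bayesian integrated species distribution modelling for abundance
estimation of rare species, combining two data streams around one latent
abundance surface:

* **presence-only (PO) sighting records** — opportunistic occurrences with
  no information about surveyed absences, modelled as a thinned
  inhomogeneous Poisson point process with a logit-linear thinning factor
  absorbing observation bias (e.g. distance to road);
* **presence-absence (PA) camera-trap histories** — repeat-visit
  detection/non-detection records, modelled as an occupancy process with
  imperfect detection.

The package is aimed at ecologists running camera-trap programs for
low-density species (the motivating system is an endangered gliding
marsupial surveyed at naive capture rates of a few percent per
camera-night), where neither data stream alone supports a defensible
abundance estimate.

## The model

Over a gridded landscape with covariates $x_k$ and cell areas $A_k$:

$$
\log \lambda_k = \beta_0 + \beta^\top x_k, \qquad
N_k \sim \text{Poisson}(\lambda_k A_k), \qquad
\psi_k = 1 - e^{-\lambda_k A_k}
$$

$$
\ell_{PO} = \sum_i \log\!\big(\lambda_{k(i)} b_{k(i)}\big)
          - \sum_k \lambda_k b_k A_k ,
\qquad b_k = \text{logit}^{-1}(\delta_0 + \delta_1\,\text{bias}_k)
$$

$$
\ell_{PA} = \sum_{\text{surveyed }k} \log\!\Big[\psi_k\,p^{d_k}
            (1-p)^{w_k-d_k} + (1-\psi_k)\,\mathbb{1}(d_k=0)\Big],
\qquad p = \text{logit}^{-1}(\alpha)
$$

with joint log-likelihood $\ell_{PO} + \ell_{PA}$ (the latent occupancy
state is marginalized analytically). Inference is adaptive random-walk
Metropolis-within-Gibbs (compiled inner loop), gated on split
Gelman–Rubin diagnostics; abundance predictions sum the posterior
intensity surface over cells. Grid aggregation (factor $k$ → $k^2$-ha
cells) proxies home-range size; camera subsampling (max / mean / sum)
resolves multiple cameras per aggregated cell. A synthetic-data generator
produces landscapes, latent abundance, biased sighting records, camera
deployments (even or clustered) and nightly detection histories, and a
simulation harness reproduces the survey-design experiments (camera
placement, subsampling, aggregation method, scale dependency). See the
methods vignette (`vignettes/integrated-sdm-methods.Rmd`) for the full
account.

## Worked example

Simulate a standard synthetic survey (100 × 100 one-hectare cells, ~500
biased sighting records, 100 cameras × 40 nights at per-night
detectability 0.3), fit the integrated model at the production MCMC
schedule, and predict total abundance:

```r
library(camtrapISDM)

cfg <- sim_config(rng_seed = 42)
sim <- simulate_survey(cfg, seed = 42)
fit <- run_mcmc(sim$po, sim$histories, sim$grid, mcmc_config(rng_seed = 7))
fit
summary(fit)
detectability_estimate(fit)
predict_abundance(fit, sim$grid, n_draws = 1000, seed = 1)
```

```
<isdm_fit> 4 chains x 5000 retained draws x 7 parameters
  max split R-hat: 1.009 (converged)
      parameter median  lower  upper excludes_zero rhat acceptance
1         beta0 -2.315 -2.658 -1.886          TRUE 1.01      0.425
2     beta_env1  0.777  0.682  0.875          TRUE 1.00      0.480
3     beta_env2 -0.467 -0.558 -0.377          TRUE 1.00      0.482
4 beta_habitat3  0.355  0.168  0.542          TRUE 1.00      0.441
5        delta0 -0.989 -1.584 -0.398          TRUE 1.01      0.423
6        delta1 -1.085 -1.415 -0.836          TRUE 1.00      0.468
7         alpha -0.783 -0.956 -0.613          TRUE 1.00      0.451

median  lower  upper 
  31.4   27.8   35.1

<abundance_prediction> median 1659 (95% interval 1191-2489), 1000 draws, cell area 1 ha
```

Reading the output: every 95% credible interval excludes zero and covers
its generating value (`true_beta = (-2.2, 0.75, -0.5, 0.25)`,
`true_delta = (-1, -1)`, detectability 30%); the posterior detectability
is 31.4% (27.8–35.1%); and the predicted total abundance of 1659
(1191–2489) brackets the generator's expected total of 1778 individuals.

For survey-design questions, the experiment harness runs paired
simulate→fit replicates:

```r
pl <- placement_experiment(sim_config(), replicates = 25, factor = 3)
coverage_summary(pl)   # CI coverage and widths, even vs clustered cameras
```

A thin command-line wrapper is installed at
`system.file("cli/camtrap-isdm", package = "camtrapISDM")` with
`simulate`, `fit` and `predict` subcommands over the CSV/JSON formats
documented in `?write_cell_grid`.

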
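---
title: "Integrated species distribution modelling from camera traps and sighting records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated species distribution modelling from camera traps and sighting records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Abundance estimation for rare, hard-to-detect species rarely has the luxury
of a single clean data source. Camera-trap surveys give structured
repeat-visit detection/non-detection records at known locations, but at the
low detectabilities typical of rare arboreal mammals (a few percent per
night) a stand-alone occupancy model is weakly informed. Opportunistic
sighting records accumulated over decades cover far more of a species'
range, but carry no information about surveyed absences and are biased
toward accessible places (roads, settlements). `camtrapISDM` implements an
integrated species distribution model that combines both sources around one
latent abundance surface, together with the survey-design simulation
machinery needed to understand when the combination can be trusted.

## The model

The study extent is discretized into grid cells $k$ with covariate vectors
$x_k$, cell areas $A_k$ (hectares) and an observation-bias covariate (a
road-proximity-like layer). The model has four linked parts.

**Latent abundance.** An inhomogeneous Poisson process with log-linear
intensity,
$$\log \lambda_k = \beta_0 + \beta^\top x_k, \qquad
  N_k \sim \text{Poisson}(\mu_k), \quad \mu_k = \lambda_k A_k ,$$
so the expected total abundance is $\sum_k \mu_k$ over unmasked cells. The
cell sum is the discretized intensity integral; no finer quadrature is
attempted, so the working aggregation factor sets the integration
resolution.

**Occupancy link.** A cell is occupied when it holds at least one
individual: $Z_k = \mathbb{1}(N_k > 0)$, hence
$$\psi_k = P(Z_k = 1) = 1 - e^{-\mu_k}.$$
This is the only occupancy-abundance link consistent with Poisson latent
counts: it is saturating (near-linear for small $\mu$, approaching 1 for
large $\mu$), which is what makes grid-cell size — a proxy for home range —
bite on the abundance scale.

**Presence-only thinning.** Each individual enters the sighting record
independently with probability
$$b_k = \operatorname{logit}^{-1}(\delta_0 + \delta_1 \cdot
  \text{bias}_k),$$
giving a thinned Poisson process with discretized log-likelihood
$$\ell_{PO} = \sum_i \log(\lambda_{k(i)} b_{k(i)})
  - \sum_k \lambda_k b_k A_k .$$
The full thinned point-process likelihood is used (not a logistic
regression approximation). The logit link for $b$ is a modelling choice;
with an intercept and a single bias covariate any strictly monotone link
would behave similarly after refitting.

**Detection.** For a surveyed cell with $w$ nights and $d$ detections, the
per-night detection probability is $p = \operatorname{logit}^{-1}(\alpha)$,
constant across cameras and nights (no detection covariates were recorded
in the motivating surveys), and the latent state is marginalized
analytically:
$$\ell_{PA} = \sum_{\text{surveyed } k} \log\!\left[ \psi_k\, p^{d_k}
  (1-p)^{w_k - d_k} + (1-\psi_k)\,\mathbb{1}(d_k = 0) \right].$$
Marginalizing $Z$ (rather than sampling it, as a JAGS implementation
would) is exact and removes the latent layer from the sampler. The two
data streams are assumed independent given the parameters, so the joint
log-likelihood is $\ell_{PO} + \ell_{PA}$.

**Priors.** Reference implementations of this model class leave priors
unstated; the package defaults are weakly informative: $\beta_j \sim N(0, 2.5^2)$ on the
log-intensity scale and standard Logistic priors on the logit-scale
parameters $\delta_0, \delta_1, \alpha$ (a Logistic(0,1) prior on a logit
parameter is uniform on the probability scale). `beta_prior_sd` is
exposed for sensitivity checks.

## Inference

Sampling is adaptive Gaussian random-walk Metropolis-within-Gibbs: each
parameter is updated one at a time against the joint log-posterior.
Per-parameter log step sizes drift toward a 0.44 acceptance target during
the adaptation phase (Robbins–Monro, gain $\min(0.25, 2/\sqrt{t})$) and
are frozen afterwards. Chains start from independent prior draws, which
provides the overdispersion the convergence diagnostic needs;
initialization retries up to 100 prior draws if the log-posterior is not
finite at the start. The production schedule is 4 chains, 1000 adaptation
steps, 10,000 burn-in steps and 25,000 sampling steps thinned by 5 —
20,000 retained draws.

Convergence is gated on the split Gelman–Rubin statistic (each chain
halved before the between/within variance comparison, so within-chain
drift registers), with the conventional 1.05 threshold. Constant chains
report $\hat R = 1$ by convention. Summaries use type-7 (linearly
interpolated) quantiles; this matters because 95% credible-interval
endpoints feed the evidence flags and the simulation-experiment coverage
metrics.

The likelihood inner loop is compiled (Rcpp). Proposals reuse the cached
linear predictor $\eta = X\beta$: an intensity-coefficient update costs one
fused pass over the cells, a thinning update one pass for the new $b$, and
a detection update touches only the surveyed cells. The presence-only
point term uses $\log \lambda_k = \eta_k$ directly and $\log b$ only at
cells holding points.

## The synthetic-data generator

Field datasets of this kind (sighting databases, fine-resolution
environmental rasters) are rarely deposited, so the generator is a
first-class module that emulates their statistical structure; every downstream stage is tested against it.

Continuous covariate fields are Gaussian white noise convolved with an
isotropic Gaussian kernel (standard deviation `covariate_smoothness`
cells) and standardized; this is cheap, exactly seedable, and produces the
spatial autocorrelation the tests need, without claiming to be a specific
geostatistical model. Binary habitat covariates threshold a smoothed field
at its 0.6 quantile. The observation-bias layer is built like the
continuous covariates. As the kernel width goes to zero the fields become
iid standard normal — a property the tests exploit.

Defaults define the standard study conditions used throughout:

* 100 × 100 grid of 1-ha pixels;
* `true_beta = c(-2.2, 0.75, -0.5, 0.25)` (intercept, two continuous
  covariates, one binary), giving an expected total around 1800
  individuals and per-1-ha-cell occupancy around 0.15 — a low-density,
  patchily distributed species;
* `true_delta = c(-1, -1)`: thinning probabilities mostly between 0.1 and
  0.5, declining away from the "road", yielding roughly 500 sighting
  records — the same order as a cleaned multi-decade sighting database;
* 100 cameras (even lattice, or 25 clusters of 4 within 3 × 3-cell boxes)
  for 40 nights at a per-night detectability of 0.3 (the value the
  survey-design simulations use; field estimates are far lower).

The cluster box (3 × 3 cells) is a design choice: clustered cameras share
covariate context, which is exactly what degrades their information
content. Presence-only thinning is realized at the individual level
(binomial thinning of $N_k$), which is equal in distribution to thinning
the point process.

What the generator does *not* emulate: animal movement and home-range
geometry (home range enters only through cell area), temporally open
populations, false positives, and detection heterogeneity. Passing tests
therefore demonstrate correctness of the estimator under the model's own
assumptions plus the stated scale mismatch below — not robustness to every
field complication.

## Data preparation semantics

* **Detection incidents**: an image opens a new incident when it is at
  least 30 minutes (inclusive boundary) after the preceding image of that
  species at that camera — measured from the preceding *image*, not the
  preceding incident. The operation is idempotent.
* **Effort**: camera-nights summed per site, respecting per-camera
  operating durations. Naive capture rates are detections per 100
  camera-nights, reported to two decimals.
* **Sighting-record cleaning**: drop incomplete records and records
  before 1990; counts collapse to presences.
* **Standardization**: continuous covariates are z-scored over unmasked
  cells; binary covariates pass through; the scaler is retained so
  prediction grids are transformed identically. A zero-variance continuous
  covariate is an error naming the covariate.
* **Aggregation**: coarse covariates are means of unmasked constituent
  cells (binary covariates therefore become habitat fractions, used
  as-is), areas are sums, a coarse cell is masked only if all constituents
  are; ragged edges are padded with masked cells. Factor $k$ on 1-ha
  pixels gives $k^2$-ha cells, so factors 3–5 span the 9–25 ha home-range
  scenarios.
* **Camera subsampling**: within a coarse cell, `max` keeps the camera
  with the most detections (ties to the lowest camera id, for
  determinism); `sum` pools detections and nights but errors when pooled
  detections exceed the survey duration (the longest single-camera
  deployment in the cell) — pooled counts beyond that violate the
  occupancy model's one-detection-per-night support, the reason the
  survey-design simulations use a detectability of 0.3; `mean` produces
  fractional per-night histories, violates Bernoulli support, and is
  flagged `non_bernoulli` for diagnostic use only (the marginal likelihood
  accepts fractional $d$ as a quasi-likelihood).

## The simulation experiments

All four experiments share a harness: simulate → prepare → fit →
summarize, with per-replicate seeds derived from a master seed, matched
seeds across paired arms, and a convergence gate (a fit with any split
$\hat R \ge 1.05$ is re-run once with a fresh seed, then flagged —
flagged, not dropped, to avoid survivorship bias in coverage). Reports are
tidy data frames (one row per scenario × replicate × metric) that
round-trip through CSV.

Two deliberate design points:

* **Scale mismatch is real, and kept.** The generator places individuals
  in fine cells and cameras detect their own fine cell's occupant. Fitting
  at an aggregation factor $f > 1$ therefore confronts the model with
  detection histories that under-report coarse-cell occupancy — the
  home-range/cell-size mismatch that makes grid-based abundance estimates
  scale-dependent. The scale sweep exhibits the expected
  direction: abundance estimates decline as cells coarsen and occupied
  cells are underestimated at coarse factors.
* **Subsampling is a sample-size question.** The subsampling experiment
  keeps each camera's observations unaltered and retains one camera per
  would-be coarse cell — chosen by camera id, blind to detections — then
  fits at native resolution. Folding the aggregation itself into the
  experiment would confound the sample-size effect with the scale
  mismatch; selecting survivors by detection count (as the max rule does
  in the real pipeline) would add the detectability-inflating selection
  effect on top. The selection effect is real — keeping the
  highest-detection camera inflates apparent detectability and hence
  abundance — but it belongs to the aggregation-method comparison, not to
  the sample-size experiment.

The placement comparison (even lattice vs 25 × 4 clusters) is run at a
working factor of 3: at native resolution both designs retain all 100
cameras and differ negligibly, while under aggregation the clusters
collapse to far fewer effective cameras — the mechanism by which clustered
designs lose precision.

"Occupied cells" is reported as the posterior of $\sum_k \psi_k$ (the
expected number of occupied cells) against the realized $\sum_k
\mathbb{1}(N_k > 0)$ aggregated to the working resolution; the posterior
of total abundance sums expected intensities $\sum_k \lambda_k A_k$
without adding Poisson predictive noise — predictions summarize the
intensity surface, not hypothetical new realizations.

## Problem sizes used by the test and acceptance suites

Chosen as desk-scale study conditions: parameter-recovery runs use the
standard 100 × 100 / 100-camera / 40-night conditions with 10 replicate
simulate-fit cycles and a shortened chain schedule (2 chains, 1000
adaptation, 1000 burn-in, 3000 sampling steps thinned by 3); the
directional experiments use 8 replicates each with 600/600/1800/3 chains,
except the subsampling coverage comparison, which runs its stated 25
replicates with 800/1200/3000/3 chains (a coverage band is only
informative over well-mixed fits). The coverage bands are
binomial-tolerance analogues of the 50-replicate formulation (at least 8
of 10 per parameter). Replicate counts scale the sharpness of the
directional majorities, not their direction.

## Numerical choices

* Zero-detection occupancy contributions are computed as
  $\log(e^{-\mu} + \psi (1-p)^w)$ directly — both terms live in $[0,1]$,
  so no log-sum-exp gymnastics are needed; $\psi = 1 - e^{-\mu}$ uses
  `expm1`.
* Non-finite proposals (intensity overflow) are rejected rather than
  clamped; initialization retries prior draws until the posterior is
  finite.
* Posterior predictions subsample retained draws without replacement under
  a fixed seed; requesting at least as many draws as are retained uses
  them all.
* Quantile convention is type-7 everywhere, including the
  2.5/25/50/75/97.5% abundance quantiles (the reported interval levels are
  configurable; the defaults bracket a central 95% interval).

## Known limitations

* Closed population, no movement: a camera informs only its own cell.
* Constant detectability; night- or site-level detection covariates are
  out of scope.
* No spatial random effects or residual autocorrelation beyond what the
  covariates carry.
* The PO and PA streams are assumed independent; double-counted
  individuals (a sighting at a camera site) would violate this.
* Real-data headline quantities (range-wide abundance medians,
  field-estimated detectabilities) depend on undeposited rasters and
  sighting databases and are out of reach of the synthetic conditions;
  the package reproduces the survey-table arithmetic and the qualitative
  simulation findings instead.
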
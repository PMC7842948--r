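---
title: "Joint multispecies occupancy modelling of wading-bird surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint multispecies occupancy modelling of wading-bird surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waderOccu)
```

## The problem

Aerial detection/nondetection surveys of wetland wading birds -- herons,
egrets, ibises, storks and spoonbills -- record whether each species was
seen in each 2-km grid cell on repeated monthly visits during the breeding
season, stacked across years. Two features of such data frustrate naive
species distribution modelling. First, detection is highly imperfect: a
per-visit detection probability can be as low as 0.04 for a rarely
detected species, so raw presence maps badly understate occurrence.
Second, rare species are detected in too few cells to support
single-species models at all. The joint multispecies occupancy model
addresses both: a latent occupancy state separates presence from
detection, and a community-level prior lets rare species borrow strength
from the rest of the assemblage.

## The model

For site-year $j$ and species $i$, the latent occupancy state is
$z_{ji} \sim \mathrm{Bernoulli}(\psi_{ji})$ with

$$\operatorname{logit}(\psi_{ji}) = \alpha_{\psi,i} + \beta_i^\top x_j,$$

where $x_j$ holds the standardized site covariates: breeding-season water
depth (cm), recession rate (cm/day, positive when water is dropping),
days dry over the previous three years, canopy-cover proportion, and the
easting/northing cell coordinates; the three hydrologic covariates enter
both linearly and quadratically, giving nine predictors plus the
intercept. Visit-level detections are
$X_{jki} \sim \mathrm{Bernoulli}(p_i \, z_{ji})$: detection varies only
among species, not across visits or sites, so
$\operatorname{logit}(p_i) = \alpha_{p,i}$.

The observed-data likelihood used throughout the package marginalizes the
latent state. With $d_{ji}$ detections over $K_{ji}$ observed visits,

$$L_{ji} = \psi_{ji}\, p_i^{d_{ji}} (1-p_i)^{K_{ji}-d_{ji}}
  + (1-\psi_{ji})\,\mathbb{1}[d_{ji} = 0],$$

and missing visits simply drop out of $K_{ji}$. `modelLoglik()` computes
exactly this quantity, and the test suite checks it against brute-force
enumeration of every latent configuration on small problems.

### Two readings of the community prior

The prior on coefficients is a normal with mean 0 and precision 0.001.
That sentence supports two structures, and the package implements both
(`communityPrior()`):

* **literal** -- every species-specific coefficient independently receives
  the vague Normal(0, 1000) prior. Nothing is shared across species.
* **hierarchical** (the default) -- for each parameter family (each
  occupancy predictor, the occupancy intercept, and the detection
  intercept) the species coefficients are draws from a common normal
  whose hypermean carries the vague prior and whose hyper-SD is
  Uniform(0, 10). Only this reading produces the cross-species borrowing
  that makes rarely detected species estimable, which is the stated
  motivation for joint modelling, so it is the default; the literal
  reading remains available and is what the Savage-Dickey prior density
  refers to.

Detection intercepts get the same mode-dependent treatment as occupancy
coefficients.

A third mode, `"logistic"`, is provided for single-species fits: a
standard logistic prior on each intercept, equivalent to Uniform(0, 1) on
the corresponding probability. This matters in the weakly identified
rare-detection regime. A Normal(0, precision 0.001) prior is vague on
the *logit* scale but concentrates its mass at probabilities near 0 and 1;
with a per-visit detection probability near 0.04 the likelihood has a long
ridge toward $\psi \to 1$, the logit-scale prior weights that ridge
heavily, and the exact posterior mean of $p$ (verified by dense 2-d
quadrature, the same oracle the tests use against the sampler) lands well
below the generating value. The Uniform(0, 1)-equivalent prior — the
conventional vague choice in the occupancy literature — removes the
boundary pathology; the package's detection-recovery studies use it for
their intercept-only fits, and the community modes are unchanged.

## The sampler

`fitOccu()` runs an adaptive Metropolis-within-Gibbs sampler written for
this model. Species parameters are updated coordinate-wise by random-walk
Metropolis **against the marginalized likelihood** above. An earlier
data-augmented variant (conditioning the coefficient updates on an imputed
$z$) mixed an order of magnitude worse for rare species -- with $p
\approx 0.04$ most occupied sites have no detections, so the imputed
$z$ is mostly prior noise and the coefficients random-walk through it.
Integrating $z$ out removes that bottleneck entirely; the latent state is
still drawn each iteration from its Bernoulli full conditional
($\Pr(z=1 \mid \text{no detection}) =
\operatorname{plogis}(\operatorname{logit}\psi + K\log(1-p))$) so
augmented-likelihood diagnostics and $z$-recovery checks remain available.
In hierarchical mode the hypermeans have conjugate normal updates and the
hyper-SDs a log-scale random walk under the uniform prior.

Numerical choices:

* Proposal scales adapt in batches of 50 toward 44% acceptance with
  diminishing steps ($\min(0.1, 1/\sqrt{b})$), during burn-in only;
  frozen afterwards so the retained chain is a fixed Markov kernel.
* Initialization: $z = 1$ wherever a detection occurred, coefficients
  from Normal(0, 0.1), detection intercepts at the logit of the naive
  detection rate, jittered per chain; a bounded re-initialization guard
  covers non-finite starts.
* `log1p`/softplus forms are used everywhere a saturated logit could
  overflow.
* Chains run sequentially with seeds derived deterministically from the
  configuration seed, so a fit is byte-reproducible.

The default chain configuration is 3 chains of 20,000 iterations, 10,000
burn-in, thinning 10 (1,000 retained draws per chain). Convergence is
judged by the plain Gelman-Rubin potential scale reduction factor
(`gelmanRhat()`), with the conventional 1.1 threshold; split-chain and
rank-normalized variants are available as options, the plain statistic
being the default reported one to match common occupancy-model practice.
Sampler correctness is tested against a dense-grid quadrature posterior
on the intercept-only model, not just against recovery of simulated
truth.

## The synthetic survey generator

No field data ship with the package; `generateCovariates()` /
`simulateDetections()` emulate the survey that motivated the model: 1,782
grid cells of 2 km, 10 years stacked (17,820 site-years), 5 monthly
visits, 9 species. The generator's defaults are the study conditions and
are not tuned per analysis:

* Covariate marginals are moment-matched to the landscape's observed
  mean/SD/range: truncated normals for depth, recession and the
  coordinates (underlying parameters solved so the *truncated* moments
  hit the targets), a zero-inflated truncated normal for days-dry (30%
  of cells never dry in a three-year window -- a modelling choice for the
  point mass evident at the range minimum), and a rescaled Beta on
  [0, 0.64] for canopy cover. Samples of 10,000 site-years reproduce the
  target moments within a few percent.
* Canopy and coordinates are drawn once per cell and repeated across
  years; hydrologic covariates are drawn independently per site-year.
  Coordinates snap to the 2-km lattice.
* Default per-visit detection probabilities span the studied community's
  range, 0.042 (roseate spoonbill, little blue heron) to 0.511 (great
  egret).
* `exampleCommunityParams()` supplies a realistic community truth:
  coefficient hypermeans whose signs mirror the fitted system (occupancy
  peaking at intermediate depth, favouring receding water, declining
  steeply with days dry, increasing with canopy, trending east and
  south) with between-species SD 0.4.
* Visits can be masked missing-at-random (`pMissing`, default 0) to
  exercise the likelihood's missing-data path; the survey is treated as
  complete otherwise, since the design gives no reason to drop months.

What the generator does **not** emulate: spatial autocorrelation beyond
the linear easting/northing trend, temporal (inter-annual) dynamics,
residual between-species correlation, and observer- or condition-driven
detection heterogeneity. Passing recovery tests on these synthetic data
therefore demonstrates correctness of the estimator under the model's own
assumptions, not robustness to their violation in field data.

## Evidence and model checking

* **Credible-interval importance**: a predictor is "important" for a
  species when its central 95% interval excludes 0
  (`summarizePosterior()`).
* **Savage-Dickey Bayes factors** (`savageDickeyLnBF()`): ln BF$_{10}$ =
  ln prior density at 0 minus ln posterior density at 0, under the vague
  Normal(0, precision 0.001) coefficient prior; ln BF > 4.61 (= ln 100)
  is decisive, ln BF < 0 negligible. The posterior density at 0 is a
  Gaussian KDE with Silverman bandwidth when 0 lies inside the sample
  range of the draws. Outside that range a KDE is meaningless (its tails
  decay at bandwidth scale), so the estimator switches to a normal tail
  approximation from the draws' mean and SD -- exact for Gaussian
  posteriors, and flagged in the result so the two estimators can be
  compared. The point-null formulation is two-sided.
* **Dunn-Smyth residuals** (`dunnSmythResiduals()`): randomized quantile
  residuals for the binary ever-detected outcome, exactly standard normal
  under the generating model; one uniform draw per observation at a fixed
  seed. The fitted value they are plotted against is the *ever-detection*
  probability $\psi(1-(1-p)^K)$ by default -- the probability of the
  observable -- because the calibration property only holds against the
  observable's probability; plain $\psi$ is available by option, and the
  same convention question applies to AUC.
* **AUC** (`aucOccu()`, `aucPosterior()`): Mann-Whitney concordance with
  ties counted one half, scored per retained draw and summarized with a
  95% interval per species; 0.7 is the conventional adequacy bar. Under
  the generator's community spread a particular species' draw can sit
  marginally below 0.7 even when the model is exactly right -- small
  simulated effect sizes bound discrimination -- so the bar describes the
  fitted system, not a guarantee of the method.

## Prediction and scenarios

`responseCurve()` sweeps one covariate across its observed natural-unit
range with all others held at their mean (standardized 0), per retained
draw. `predictOccupancyMap()` produces per-cell, per-species occupancy
probabilities by plugging posterior-mean parameters through the link --
the plug-in convention of the reference workflow -- with the
Jensen-distinct mean-of-$\psi$ alternative available by option. Scenario
covariates are always standardized with the *training* center and scale
stored in the fit, so a changed hydrologic scenario moves the linear
predictor rather than silently redefining the coefficients; values
outside the training range warn but predict. `compareScenarios()` reports
the per-cell percent difference $100(\psi_{alt}-\psi_{base})/\psi_{base}$
with per-species summaries, the decision metric used to rank hydrologic
alternatives. `writeAsciiGrid()` exports plain-text ESRI ASCII rasters.

## Problem sizes used by the tests

The shipped tests run the whole machinery at desk scale, a deliberate
package choice: detection-recovery fits use 2,000 site-years (5,000 for
the rare-species regime, where information per site is scarcest); the
nine-species community fit uses 1,500 site-years with 3 chains of 4,000
iterations (2,000 burn-in, thin 2); the generator's moment checks use
10,000 site-years; oracle equivalences (brute-force likelihood
enumeration, pairwise AUC, quadrature posteriors) use deliberately tiny
instances where exhaustive computation is exact. `scripts/acceptance.R`
re-runs the recovery studies from scratch at these sizes.

## Known limitations

* Detection has no covariates and no temporal structure, matching the
  modelled survey; systems with strong visit-level detection drivers need
  a different detection model.
* Occupancy is single-season ("stacked"): the same cell in different
  years is treated as independent given covariates.
* Residual between-species correlation is not estimated, so the model
  cannot separate co-occurrence from shared environmental response.
* The Savage-Dickey estimate inherits the usual sensitivity to the prior
  scale: with a much tighter prior the same posterior yields a smaller
  Bayes factor.
* Pure-R MCMC: fits at the full 17,820-site scale with default chain
  lengths take on the order of hours on one core; the desk-scale
  configurations above are sized for routine use.
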
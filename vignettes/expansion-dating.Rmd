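---
title: "Expansion dating: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expansion dating: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

tideclock analyses mitochondrial control-region alignments from populations
suspected of recent, environmentally triggered expansion — the motivating
system is a littoral fish sampled along a post-glacially re-flooded coastline
— and turns the inferred onset time of population growth into a
substitution-rate estimate. This vignette explains the models behind each
stage, the choices that were genuinely open, and what the simulation-based
tests do and do not establish.

## Units: everything is scaled by the mutation rate

No stage of the inference knows the substitution rate; that is the point of
the method. Time is therefore measured in expected substitutions per site,
and population sizes are female effective sizes multiplied by the mutation
rate, written fNeμ. Only the final calibration step attaches years: if the
transition from constant size to growth happened `t_trans` substitutions/site
ago and is identified with a dated environmental event `c` years ago, the
rate is `μ = t_trans / c` substitutions/site/year, reported as percent per
million years (×10⁸). The default calibration window, 18–13 ka BP, spans the
post-glacial sea-level rise to the warming of surface waters; widening the
window can only widen the reported envelope.

## The two-epoch demography

Looking backwards from the present, the population has size `N1·exp(-r·t)`
during the recent growth epoch (`t < t_trans`) and constant size `N0` beyond
it. `N0` and `N1` are independent parameters: the trajectory may jump at
`t_trans`, which mirrors how the model is parameterised in the Bayesian
phylogenetics tools this package emulates. The coalescent under this
demography is implemented through the integrated intensity
`Λ(a,b) = ∫ dt/N(t)`, which has a closed form in each epoch (`expm1` is used
for the growth epoch so small `r·Δt` does not lose precision); waiting times
are drawn by inverting `C(k,2)·Λ = Exponential(1)` epoch by epoch, and the
likelihood of a genealogy is the standard product over inter-coalescent
intervals.

## Fixed genealogy: the central approximation

The reference analyses sample genealogies and demographic parameters jointly.
tideclock instead conditions on a single clock-compatible genealogy (UPGMA on
TN93 distances, node heights = cluster distance / 2), which keeps the whole
pipeline self-contained and desk-scale. Two consequences matter:

* posteriors on real data are **narrower** than a joint analysis would give,
  because genealogical uncertainty is ignored;
* at low diversity the UPGMA tree is **biased towards recent coalescence**:
  every set of identical sequences collapses to simultaneous coalescences at
  height zero, which the coalescent likelihood can only explain by a tiny
  present-day size. On data where most sequences are identical this drags
  `N1` and `t_trans` towards their prior floors.

For this reason the package's calibration tests condition on the simulated
(true) genealogy: they establish that the likelihood, the sampler, the HPD
machinery and the rate calibration are correct given a genealogy, which is
the part of the method this package owns. Conclusions drawn from the UPGMA
route on very-low-diversity data should be treated as qualitative.

## Priors and sampling

Population sizes get truncated 1/x priors (scale-free, proper on a bounded
interval); `r` and `t_trans` get uniform priors. Bounds are user-supplied,
ideally guided by a first skyline run — `default_two_epoch_priors()` widens
the skyline HPD threefold, mirroring that practice. The sampler is a
single-site Metropolis–Hastings sweep: multiplicative log-normal proposals
(sd 0.3) on sizes with the Jacobian in the acceptance ratio, reflected
uniform windows (10% of the prior width) on `r` and `t_trans`. Defaults —
20 000 sweeps, thin 10, 25% burn-in, target ESS > 200 — are a desk-scale
version of the reference runs (20 M generations, every 1000th sampled, 25%
burn-in), keeping the same proportions. ESS uses the initial-positive-
sequence estimator; a chain with negative lag-1 autocorrelation counts its
lag-1 term alone, so antithetic traces report ESS > N without a divide-by-
zero.

The Bayesian skyline groups the n−1 coalescent intervals into `m = 10`
contiguous groups of near-equal event counts (the group count is our default,
not a published value), gives the most recent group a truncated 1/x prior and
each later group an exponential prior centred on its predecessor — a
smoothing choice stated here because the reference implementation leaves its
internals unstated.

## Marginal likelihoods and model choice

Path sampling integrates the per-step mean log-likelihood over the
Beta(0.3, 1)-quantile schedule `β_k = (k/K)^(1/0.3)` (steps concentrate near
β = 0 where the power posterior changes fastest); stepping-stone reuses the
same per-step samples with a log-sum-exp bridge. Chains are warm-started from
the previous β with 10% per-step burn-in. Both estimators are validated
against the constant-size model, whose evidence under a truncated 1/x prior
has an incomplete-gamma closed form (`constant_model_evidence()`); the
agreement requirement in the tests is 0.2 nats at K = 32 with 20 000 sweeps
per step. Bayes factors are reported as `2 ln BF` with the conventional
interpretation bands (> 6 strong).

## Statistical-parsimony network

The exact connection-limit computation of the original parsimony-network
software is not reproduced; instead the limit is the largest step count `j`
whose probability of containing no superimposed change,
`(1 − q(j/L))^j` with `q` the Poisson multiple-hit probability given a
Jukes–Cantor-corrected per-site distance, stays at or above the confidence
(0.95 default). The network is then built agglomeratively: haplotype pairs in
order of increasing raw difference, ties preferring high joint frequency then
lexicographic ids (determinism), inserting `difference − 1` inferred
intermediates. Star-likeness is summarised as the maximum node degree divided
by the edge count of its component — 1 for a perfect star, 0.5 for a path of
five nodes.

## Genetic landscape

Locality connectivity is a Delaunay triangulation (Bowyer–Watson; locality
counts are tens, so the quadratic insertion is ample) on longitude/latitude
treated as planar for the topology, while all *distances* are great-circle
kilometres — over a ~3° latitudinal study area the planar distortion of
distances is not negligible, hence the haversine choice. Edge genetic
distances are mean raw differences between the endpoint localities'
individuals; residuals from the OLS regression of genetic on geographic
distance are attached to great-circle midpoints and interpolated by inverse
distance weighting (`α = 1`, grid 0.05°, convex-hull mask). IDW is a convex
combination, so the surface is bounded by the residual extremes; a grid node
that coincides with a midpoint takes its value exactly.

## The synthetic-data generator

`sim_config()` defaults describe the study conditions the package targets:
84 haploid sequences of 352 sites from 10 georeferenced coastal localities,
two-epoch demography with `t_trans = 4.7e-4` substitutions/site (the scale of
the motivating posterior mean), present size `N1 = 1e-2`, growth rate
`r = 5e3` (so `r·t_trans ≈ 2.4`, a ~10-fold expansion) and ancient size
`N0 = 2e-3` (nucleotide diversity of order 4e-3, matching control-region
diversity in the motivating system). The substitution model is HKY+I with
`kappa = 10` and `p_inv = 0.5` — placeholders typical for control-region
data, since the motivating study does not report its fitted values. Sequence
evolution uses the closed-form HKY transition matrix; a Bernoulli(`p_inv`)
site mask never mutates, and variable sites run at rate `1/(1 − p_inv)`, so
branch lengths stay expected substitutions per site averaged over **all**
sites and the expected diversity `E[pi] = 2·fNeμ` is independent of `p_inv`
(asserted in the tests). The `two_deme` mode joins two independent
genealogies by a divergence stem; it is a pragmatic structure generator for
landscape tests, not a structured coalescent.

What the generator does **not** emulate: recombination (none expected in
mtDNA), migration between demes, selection, sequencing error, and ambiguous
bases. Passing tests therefore demonstrate correctness of the machinery under
the stated model, not robustness to these real-data features.

## Numerical choices and degenerate inputs

* Pairwise deletion everywhere: a pair with no jointly resolved site is an
  error naming the pair, not a silent NA.
* TN93 distances refuse saturated pairs (non-positive log argument) and
  advise the uncorrected p-distance; the invariant-sites correction is *not*
  applied to distances (ill-conditioned below ~1% divergence, negligible
  there anyway).
* Fu's Fs runs entirely in log space (log-Stirling-number recurrence +
  log-sum-exp), stable for samples in the hundreds; the identity
  `sum_k |s(n,k)| = n!` is used as a self-check in the tests.
* HPD intervals are the shortest contiguous window of `⌈mass·N⌉` sorted
  draws; zero-width intervals on constant input are returned, not errors.
* All simulations consume a single seeded R stream (Mersenne-Twister, R's
  default) in documented order; pipeline stages derive per-stage seeds by
  hashing the stage name into a 32-bit range, so any stage can be re-run
  alone and reproduce its artefact byte for byte.

## Problem sizes in the shipped checks

The packaged checks use: conjugate-oracle chains of 20 000 sweeps with a
32-step path-sampling schedule; 50 study-size recovery replicates (6 000
sweeps each); 500 null datasets for Tajima's D and 200 + 200 for Fu's Fs;
2 000 TMRCA draws and 1 000 diversity replicates; 20 two-deme landscape
replicates. These sizes were chosen as the smallest at which the Monte-Carlo
error is comfortably below each criterion's tolerance.

## Known limitations

* The fixed-genealogy posterior understates uncertainty; see above.
* The connection limit is an approximation to the original software's; use
  the `limit` argument to impose an externally computed value.
* The landscape mask is the localities' convex hull — no coastline masking.
* The printed rate envelope combines HPD endpoints across the calibration
  window; it is a bracketing interval, not itself a 95% credible interval
  (use `mix_c = TRUE` to integrate the calibration age instead).
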
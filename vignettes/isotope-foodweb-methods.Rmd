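---
title: "Methods: two-baseline trophic positions, trophic guilds and diet mixing models"
author: "isofoodweb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-baseline trophic positions, trophic guilds and diet mixing models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, and the design choices made where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` do not themselves compute.

## The scientific setting

Nitrogen stable-isotope ratios (δ¹⁵N) enrich stepwise with each trophic
transfer, while carbon ratios (δ¹³C) change little but separate basal
carbon sources — in coastal systems, chiefly the benthic and the pelagic
pathway. A consumer's trophic position (TP) can therefore be read off its
δ¹⁵N *relative to a baseline of known trophic level*, and its reliance on
the benthic versus pelagic pathway off its δ¹³C. In shallow fishing
grounds, food subsidies such as fisheries discards are hypothesized to
raise the TP of consumers — especially low-TP benthic invertebrates — above
the global averages reported for their taxa, and diet mixing models can
quantify how much of a consumer's assimilated diet is drawn from guilds
(pelagic fish, demersal fish and cephalopods) it could hardly prey upon
alive.

## Two-baseline trophic-position model

For one consumer taxon with individuals `j`, benthic/pelagic baseline
samples, shared baseline trophic level λ, and class-specific trophic
discrimination factors (TDFs) Δ¹³C and Δ¹⁵N:

$$\delta^{15}N_j \sim \mathrm{N}\!\left(\alpha\mu_{N,b} + (1-\alpha)\mu_{N,p} + \Delta^{15}N\,(TP-\lambda),\ \sigma_N\right)$$
$$\delta^{13}C_j \sim \mathrm{N}\!\left(\alpha\mu_{C,b} + (1-\alpha)\mu_{C,p} + \Delta^{13}C\,(TP-\lambda),\ \sigma_C\right)$$

Both tracers carry the TDF term: carbon also fractionates (weakly) per
trophic step, and omitting its term biases α when consumers sit well above
the baselines. Baseline observations enter the likelihood and inform
μ and σ of each baseline, so baseline uncertainty propagates into the TP
posterior, as does TDF uncertainty through the informative TDF priors.

Priors, with units and rationale:

| parameter | prior | rationale |
|---|---|---|
| TP | Uniform(λ, 10) | wide enough for tertiary consumers, bounded for sampler stability |
| α (benthic fraction) | Beta(1, 1) | no assumption about pathway reliance — the model's point |
| Δ¹³C, Δ¹⁵N | Normal(TDF mean, TDF SD) | literature TDFs with their uncertainty (see registry below) |
| baseline means | Normal(observed mean, 10 ‰) | effectively data-driven; the 10 ‰ scale is vague on the δ scale |
| all SDs | half-Normal(0, 5 ‰) | weakly informative; isotopic SDs above ~2 ‰ are already unusual |

The TDF registry (`tdf_registry()`): Actinopterygii 1 ± 0.5 ‰ C /
3.4 ± 0.5 ‰ N; Chondrichthyes 1 ± 0.5 ‰ C / 2.3 ± 0.5 ‰ N (cartilaginous
fishes assimilate nitrogen differently, hence the lower Δ¹⁵N);
invertebrates 0.5 ± 0.13 ‰ C / 2.3 ± 0.18 ‰ N.

Sampling is Gibbs/slice MCMC via JAGS. Chains are initialised at a
moment-based starting point — the (α, TP) solution of the two mixture
equations at observed means and prior-mean TDFs — jittered per chain.
With vague inits, chains can stall far from the posterior ridge when
variances are small; the moment start removes that failure mode without
touching the posterior, and Gelman-Rubin R̂ on TP (threshold 1.1) still
guards convergence. Non-converged fits are returned flagged rather than
discarded.

### Baseline retro-calculation

When no pelagic primary consumer was sampled, one is retro-calculated
from a strictly zooplanktivorous fish one trophic level above it. Each of
`n_sim = 50` pseudo-baseline values is the mean of `resample_k = 7`
consumer values resampled with replacement minus the mean of 7 TDF draws.
The expectation is consumer mean − TDF mean; the SD,
≈ √(σ_c² + σ_Δ²)/√7 ≈ 0.25–0.3 ‰ for typical inputs, matches the scale of
reported retro-calculated baselines. The literal alternative — one
resampled value minus one TDF draw per pseudo-value — inflates the
pseudo-baseline SD to ~0.7 ‰, far above reported values, and was rejected
for that reason. This choice is parameterized (`n_sim`, `resample_k`) and
seeded.

### Literature comparison

`compare_to_reference()` reports direction and overlap of the 95 %
credible interval with the literature mean ± SE. Where a literature TL is
published without proportions, `reference_tl_from_diet()` resamples
uniform Dirichlet diet weights over the listed items and reports the mean
and SD of `1 + weighted mean prey TL` as (mean, SE).

## Trophic-guild clustering

Taxa differ in sample size (4–9 individuals typically), which biases
within-taxon variance estimates. Each bootstrap replicate therefore
resamples every taxon to a common size `m = 4` (a typical minimum n),
takes the resample mean as the taxon's 2-D coordinate, z-scores the
coordinates *across taxa within the replicate*, and computes Euclidean
distances; `B = 500` replicate matrices are averaged. Design choices made
where the procedure was open:

- **Coordinates are resample means**, not the m raw points: this gives an
  order-invariant, fixed-dimension representation of each taxon.
  (The raw-points alternative would require a distance between point
  sets.)
- **Standardization is per replicate**, not global: each replicate is a
  complete re-realization of the procedure. A coordinate with zero
  variance across taxa contributes zero (instead of 0/0) — relevant only
  for degenerate inputs.
- The averaged matrix is symmetric with a zero diagonal, but averaging
  need not preserve the triangle inequality; it is treated as a
  dissimilarity, which is all UPGMA requires.

UPGMA itself is average-linkage `stats::hclust`, which implements the
unweighted pair-group method exactly and deterministically; a
hand-agglomerated four-taxon oracle in the test suite pins merge order
and heights. `select_clusters(k = "auto")` places the cut at the largest
*relative* jump between successive merge heights and returns the height
profile — a fusion-level aid to, not a replacement for, inspecting the
dendrogram. The case-study emulation uses the published `k = 6`.

## Diet mixing models

Per tracer `t` and consumer individual `j`, with sources `k` at moments
(μ_kt, σ_kt) and the *consumer's* class TDF attached to every source
(discrimination happens in the consumer):

$$y_{jt} \sim \mathrm{N}\!\left(\textstyle\sum_k p_k(\mu_{kt}+\mu_{\Delta,kt}),\
\sqrt{\varepsilon_t \sum_k p_k^2(\sigma_{kt}^2+\sigma_{\Delta,kt}^2)}\right)$$

with **p** ~ Dirichlet(1, …, 1) and a per-tracer residual multiplier
ε_t ~ Uniform(1, 25). The multiplicative residual keeps the total variance
positive, nests the process-only model at ε = 1, and lets unexplained
consumer-level variance inflate — but never deflate — the process
variance. Summaries report the posterior mean, the mode (Gaussian kernel
density, Silverman bandwidth) and the equal-tailed 95 % CI per source;
mean and mode are both emitted because published tables are not always
explicit about which central statistic they print.

Two pooling modes are deliberately distinct:

- `pool_sources()` merges guilds *before* fitting (n-weighted pooled
  moments, which inflate the pooled SD by the between-guild mean spread);
- `combine_posterior()` sums member proportions *within each draw after*
  fitting, preserving the simplex exactly.

They agree only in the zero-variance limit. The case-study emulation
pools the ecologically adjacent SBF and BIF guilds a priori in every
model, but combines the two pelagic guilds (PPC, PSC) draw-wise in the
squid model — fitting them separately and summing reproduces the
published combined contribution, whereas a-priori pooling of two guilds
nearly 4 ‰ apart in δ¹⁵N smears the pooled source and understates the
pelagic share.

DIC = mean deviance + pD with pD = mean deviance − deviance at the
posterior mean, computed from the monitored draws. `polygon_check()`
screens consumers against the closed convex hull of TDF-corrected source
means (boundary counts as inside, tolerance 1e-9; a 1-D interval test
with fewer than three sources); an outside consumer yields a warning and
a flag, not an error, since marginal excursions of a few tenths of a
per-mil are common and the model remains estimable.

## Convergence diagnostics

Gelman-Rubin R̂ uses the classic formula
√(((n−1)/n·W + B/n)/W), floored at 1: by chance the variance ratio can
dip marginally below 1 when chains agree more closely than independent
sampling would, and the floor keeps the statistic interpretable as a
scale *reduction* factor (identical chains give exactly 1). The Geweke
z-score compares the first 10 % with the last 50 % of a chain, with
spectral-density-at-zero standard errors from a Bartlett-windowed
autocovariance sum (lag window √n). A stationarity test in the
Heidelberger–Welch style is intentionally out of scope: at desk scale it
adds little beyond R̂ + Geweke, and leaving it out keeps the diagnostic
surface explicit.

## Synthetic data and what passing tests show

`simulate_community()` inverts the models: TP consumers are drawn from
the two-baseline equations with per-individual TDF draws (mirroring how
TDF variance enters the likelihood) and 0.4 ‰ observation noise; mixture
consumers from the proportion-weighted source model. Defaults emulate a
coastal bentho-demersal community: 31 taxa over seven classes, 4–9
individuals each, TPs in [2.2, 4.5], benthic fractions spanning [0.05,
0.95], baselines ~2.5 ‰ apart in δ¹³C. The generator does *not* emulate
spatial or temporal baseline gradients, body-size effects, tissue
turnover, or non-normal tracer distributions — parameter recovery on
synthetic data therefore demonstrates self-consistency of the inference,
not robustness to those real-data features.

Individuals emulated from *published summary moments* are reconstituted
as seeded normal draws rescaled to the exact printed mean and SD
(`reconstitute_samples(exact = TRUE)`). The printed moments are the only
information available, so matching them exactly keeps the emulation
faithful to its inputs; the residual degrees of freedom stay random. With
plain (non-rescaled) draws, per-taxon means drift by their standard
error, which is enough to destabilize guild memberships of adjacent taxa.

## Problem sizes and numerical choices

The `"fast"` MCMC profile (3 chains, 20,000 iterations, 5,000 burn-in,
thin 10 → 4,500 merged draws) is the package's working default and the
test default; `"full"` (500,000 / 100,000 / thin 100) mirrors long
production runs and changes posterior means by less than Monte-Carlo
noise on these model sizes. Property suites run 20 synthetic TP fits for
coverage and 10 mixing fits for proportion recovery; the bootstrap
enumeration oracle uses 3 taxa × 2 individuals where the resampling
distribution is exhaustively enumerable. Sub-seeds for every stage are
derived deterministically from one master seed, so stage-level reruns
reproduce pipeline runs bit-for-bit.

Degenerate inputs: zero TDF SDs are floored at 1e-6 inside the TP model
(JAGS requires positive precision); an all-zero process variance in the
mixing model is floored at 1e-4 ‰; n = 1 taxa carry SD 0 with a warning;
ties in agglomeration resolve deterministically via `hclust`.

## Known limitations

- Sources in a mixing model must not be collinear in tracer space:
  with two tracers, three or more sources on a line are unidentifiable,
  and the posterior mean then reflects the prior as much as the data.
  The polygon check flags the consumer side; source geometry is the
  user's responsibility.
- One community, one baseline pair: no spatial or temporal baseline
  structure, no one- or three-baseline variants.
- Mixing models are per-consumer-taxon; no hierarchical pooling across
  taxa and no concentration dependence.
- Literature-TL comparisons are indicative, not formal tests: global
  averages carry heterogeneous SEs and geographic mismatch.
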
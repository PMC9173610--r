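# isofoodweb

Bayesian stable-isotope food-web modelling for coastal communities, built
around the question of how much fisheries discards (and other food
subsidies) contribute to the diet and trophic position of marine consumers
in heavily fished grounds.

The package is aimed at trophic ecologists working with per-individual
δ¹³C / δ¹⁵N data from a sampled community. It provides, as a tested,
reusable pipeline:

- **Two-baseline trophic-position estimation.** For a consumer with tracer
  values (δ¹³C, δ¹⁵N), a benthic and a pelagic baseline of shared trophic
  level λ, and class-specific trophic discrimination factors (TDFs)
  Δ¹³C, Δ¹⁵N, the model is

      δ¹⁵N_c ~ Normal(α·μN_b + (1−α)·μN_p + Δ¹⁵N·(TP − λ), σ_N)
      δ¹³C_c ~ Normal(α·μC_b + (1−α)·μC_p + Δ¹³C·(TP − λ), σ_C)

  with TP ~ Uniform(λ, 10), benthic-reliance α ~ Beta(1, 1), informative
  normal TDF priors, and baseline means/SDs informed by the baseline
  observations. TDF, source and consumer variability are all propagated
  into the TP posterior. Sampling is MCMC via JAGS.
- **Baseline retro-calculation.** When no pelagic primary consumer was
  sampled, one is retro-calculated from a strictly zooplanktivorous
  consumer by simulating the subtraction of one TDF step.
- **Trophic-guild clustering.** UPGMA on a bootstrap-averaged Euclidean
  distance matrix over z-scored isotope coordinates (resampling every
  taxon to a common size m removes sample-size bias), with a fusion-level
  heuristic for choosing the number of guilds.
- **Diet mixing models.** Dirichlet(1, …, 1) diet proportions **p** with
  process error weighted by squared proportions and a per-tracer residual
  multiplier ε ≥ 1:

      δ_jt ~ Normal(Σ_k p_k (μ_kt + Δ_kt), sqrt(ε_t Σ_k p_k² (σ_kt² + σ_Δkt²)))

  plus a-priori source pooling, draw-wise posterior combination, DIC model
  comparison and mixing-polygon feasibility screening.
- **MCMC diagnostics** (Gelman-Rubin R̂, Geweke z) and a
  **synthetic-community generator** with known trophic positions, mixing
  fractions and diet proportions for parameter-recovery testing.
- A bundled **case-study emulation** of a Bay of Biscay (Bay of Bourgneuf)
  fishing-ground community: 30 consumer taxa plus a scallop benthic
  baseline, reconstituted at the individual level from published per-taxon
  summaries.

## Worked example

Estimate the trophic position of whiting (*Merlangius merlangus*) in the
Bourgneuf emulation, compare it with the global-average literature value,
and model the diet of the circular crab *Atelecyclus undecimdentatus* from
guild-level sources:

```r
library(isofoodweb)

ds <- bourgneuf_dataset(seed = 1)                     # reconstituted individuals
bl <- bourgneuf_baselines(seed = 1, dataset = ds)     # scallop + retro-calculated PPC

whiting <- ds[ds$taxon_id == "Mmerla", ]
fit <- fit_tp(whiting, bl$pair, tdf_for_class("Actinopterygii"),
              mcmc_profile("fast", seed = 1))
fit
#> Trophic position of Mmerla: 4.23 (95% CI 3.62-5.10), alpha 0.45
compare_to_reference(fit, ref_mean = 4.4, ref_se = 0.2)
#>   taxon_id model_mean   ci_lo    ci_hi ref_mean ref_se direction overlap
#> 1   Mmerla   4.225301 3.61523 5.098708      4.4    0.2     below    TRUE

crab <- ds[ds$taxon_id == "Aund", ]
diet <- fit_mixing(crab, bourgneuf_sources("Decapoda"),
                   mcmc_profile("fast", seed = 1))
diet
#> Diet of Aund (4 sources, DIC 41.2)
#>   SBF-BIF    mean  5.4%  mode  1.5%  95% CI  0.2-17.3%
#>   BPC        mean 85.4%  mode 89.5%  95% CI 65.4-96.1%
#>   PSC        mean  5.8%  mode  1.3%  95% CI  0.1-20.6%
#>   DFC        mean  3.4%  mode  1.0%  95% CI  0.1-11.7%
```

Whiting sits a full two trophic steps above the baselines (a tertiary
consumer), its credible interval overlapping the literature value. The
crab's diet is dominated by benthic primary consumers (the scallop guild),
with only minor contributions from fish-containing guilds — the pattern
expected for a scavenging benthic invertebrate with some access to
discarded material. `run_pipeline(pipeline_config_study(), out_dir)`
executes the full emulation (validation, clustering, 30 TP models, 10
mixing models, diagnostics) and writes every stage's tables.

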
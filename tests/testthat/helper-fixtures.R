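# Shared in-code fixtures; nothing is read from disk except the bundled
# case-study summary table.

toy_dataset <- function() {
  community_dataset(data.frame(
    taxon_id = c("A", "A", "B"),
    taxon_name = c("Taxon A", "Taxon A", "Taxon B"),
    tax_class = c("Decapoda", "Decapoda", "Actinopterygii"),
    d13C = c(-17.5, -16.5, -19.0),
    d15N = c(11.5, 12.5, 14.0),
    pctC = c(45, 44, 40),
    pctN = c(12, 12, 11),
    stringsAsFactors = FALSE))
}

# Two well-separated sources with an invertebrate-magnitude TDF.
two_source_fixture <- function(sd = 0.3) {
  diet_sources(data.frame(
    source_id = c("S1", "S2"),
    mean_dC = c(-20, -14), sd_dC = sd,
    mean_dN = c(9, 15), sd_dN = sd,
    n = 10, stringsAsFactors = FALSE),
    tdf = tdf_spec(0.5, 0.1, 2.3, 0.15))
}

# Synthetic baseline pair: well-separated end-members at lambda = 2.
synthetic_baselines <- function(seed = 1, n = 20) {
  benthic <- reconstitute_samples("B1", -16, 0.3, 10, 0.4, n, seed = seed,
                                  exact = FALSE)
  pelagic <- reconstitute_samples("P1", -21, 0.3, 8, 0.4, n,
                                  seed = seed + 1, exact = FALSE)
  build_baseline_pair(benthic, pelagic, lambda = 2)
}

fast_mcmc <- function(seed = 1) mcmc_profile("fast", seed = seed)

# Shorter chains for unit tests where only coarse posterior location matters.
quick_mcmc <- function(seed = 1) {
  mcmc_settings(chains = 3, adapt = 1000, iterations = 6000, burn_in = 2000,
                thin = 4, seed = seed)
}
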
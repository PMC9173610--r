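#' Per-taxon summary table of the Bay of Bourgneuf community
#'
#' Published per-taxon isotope moments of the bentho-demersal community
#' sampled in the Bay of Bourgneuf fishing ground (30 consumer taxa plus
#' the benthic-baseline scallop), with sample sizes, code labels, the
#' trophic-guild assignment and global-average literature trophic levels
#' (mean +/- SE). The scallop's sample size is not published; 9 (the top
#' of the per-taxon range) is assumed. These summaries are the inputs from
#' which the case-study emulation reconstitutes individuals.
#'
#' @return data.frame with columns `tax_class`, `taxon_name`, `code`,
#'   `cluster`, `n`, `d13C_mean`, `d13C_sd`, `d15N_mean`, `d15N_sd`,
#'   `ref_tl_mean`, `ref_tl_se`.
#' @export
bourgneuf_taxa <- function() {
  path <- system.file("extdata", "bourgneuf_table1.csv",
                      package = "isofoodweb", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Trophic-guild summary moments of the Bourgneuf community
#'
#' Published group-level tracer moments of the six trophic guilds:
#' benthic primary consumers (BPC, the scallop), pelagic primary consumers
#' (PPC, retro-calculated zooplankton), pelagic secondary consumers (PSC),
#' benthic invertebrates and fish (BIF), shrimps and benthic fish (SBF)
#' and demersal fish and cephalopods (DFC). Group sizes are the summed
#' member sample sizes (50 for the simulated PPC).
#'
#' @return data.frame: `group_id`, `mean_dC`, `sd_dC`, `mean_dN`,
#'   `sd_dN`, `n`.
#' @export
bourgneuf_groups <- function() {
  data.frame(
    group_id = c("BPC", "PPC", "PSC", "BIF", "SBF", "DFC"),
    mean_dC = c(-17.9, -20.4, -18.6, -16.9, -15.7, -17.3),
    sd_dC   = c(0.2, 0.2, 0.6, 0.7, 0.9, 0.8),
    mean_dN = c(10.1, 8.6, 12.5, 13.2, 14.6, 15.2),
    sd_dN   = c(0.4, 0.3, 0.8, 0.8, 0.7, 0.9),
    n = c(9L, 50L, 27L, 72L, 21L, 82L),
    stringsAsFactors = FALSE)
}

#' Reconstitute the Bourgneuf community at the individual level
#'
#' Builds a per-individual dataset from the published per-taxon moments
#' via [reconstitute_samples()] (moment-matched by default), one taxon per
#' row of [bourgneuf_taxa()].
#'
#' @param seed integer master seed.
#' @param exact moment-match the reconstituted individuals (default TRUE).
#' @return a [community_dataset()].
#' @export
bourgneuf_dataset <- function(seed = 1, exact = TRUE) {
  t1 <- bourgneuf_taxa()
  rows <- lapply(seq_len(nrow(t1)), function(i) {
    as.data.frame(reconstitute_samples(
      t1$code[i], t1$d13C_mean[i], t1$d13C_sd[i],
      t1$d15N_mean[i], t1$d15N_sd[i], t1$n[i],
      seed = derive_seed(seed, paste0("taxon-", t1$code[i])),
      taxon_name = t1$taxon_name[i], tax_class = t1$tax_class[i],
      exact = exact))
  })
  community_dataset(do.call(rbind, rows))
}

#' Baseline pair of the Bourgneuf case study
#'
#' Benthic end-member: the scallop *Pecten maximus* (trophic level 2),
#' reconstituted from its published moments. Pelagic end-member: a pelagic
#' primary consumer retro-calculated from the strictly zooplanktivorous
#' sprat (*Sprattus sprattus*) by subtracting one Actinopterygii TDF step
#' ([retrocalculate_baseline()], 50 simulated values, resampling of 7).
#'
#' @param seed integer master seed.
#' @param dataset optionally, an existing community dataset holding `Pmax`
#'   and `Sspr` rows; reconstituted from the published moments when NULL.
#' @return list with `pair` (a [build_baseline_pair()] at lambda = 2) and
#'   `ppc_summary` (the retro-calculated baseline's mean/SD table).
#' @export
bourgneuf_baselines <- function(seed = 1, dataset = NULL) {
  if (is.null(dataset)) dataset <- bourgneuf_dataset(seed)
  benthic <- dataset[dataset$taxon_id == "Pmax", ]
  sprat <- dataset[dataset$taxon_id == "Sspr", ]
  retro <- retrocalculate_baseline(sprat, tdf_registry()$actinopterygii,
                                   n_sim = 50, resample_k = 7,
                                   seed = derive_seed(seed, "ppc"))
  list(pair = build_baseline_pair(benthic, retro$samples, lambda = 2),
       ppc_summary = retro$summary)
}

#' Guild-level diet sources for a Bourgneuf consumer
#'
#' Assembles the published guild moments into a [diet_sources()] table for
#' one consumer, carrying that consumer's class TDF on every source. The
#' SBF and BIF guilds are pooled a priori in all case-study models
#' (n-weighted pooled moments); the squid *Alloteuthis* model additionally
#' keeps PPC in place of BPC, its pelagic diet making the benthic primary
#' consumer implausible.
#'
#' @param consumer_class taxonomic class of the consumer (selects the TDF).
#' @param group_ids guilds to include (default BPC, SBF, BIF, DFC, PSC).
#' @param pool named list of a-priori pools applied after selection
#'   (default merges SBF and BIF).
#' @return a [diet_sources()].
#' @export
bourgneuf_sources <- function(consumer_class,
                              group_ids = c("BPC", "SBF", "BIF", "DFC", "PSC"),
                              pool = list(`SBF-BIF` = c("SBF", "BIF"))) {
  g <- bourgneuf_groups()
  g <- g[g$group_id %in% group_ids, ]
  names(g)[names(g) == "group_id"] <- "source_id"
  src <- diet_sources(g, tdf = tdf_for_class(consumer_class))
  if (length(pool) > 0) src <- pool_sources(src, pool)
  src
}
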
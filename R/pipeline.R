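#' Demo pipeline configuration
#'
#' A small synthetic five-taxon community with two well-separated diet
#' sources, used for smoke tests and as a template for user configs. The
#' same structure, serialized as YAML, is accepted by [run_pipeline()].
#'
#' @param mcmc_profile `"fast"` or `"full"`.
#' @return a pipeline configuration list.
#' @export
pipeline_config_demo <- function(mcmc_profile = "fast") {
  cfg <- default_community_config(n_taxa = 5)
  list(
    data = list(source = "synthetic", synthetic = cfg),
    baselines = list(benthic_taxon = cfg$benthic$taxon_id,
                     pelagic_taxon = cfg$pelagic$taxon_id, lambda = cfg$lambda),
    clustering = list(m = 4, B = 100, k = "auto"),
    tp = list(taxa = vapply(cfg$taxa, `[[`, character(1), "taxon_id")),
    mixing = list(),
    mcmc_profile = mcmc_profile)
}

#' Case-study pipeline configuration
#'
#' Reproduces the Bay of Bourgneuf analysis end-to-end from the published
#' per-taxon moments: individual reconstitution, baseline construction
#' (scallop + retro-calculated pelagic primary consumer), bootstrap-UPGMA
#' guild clustering at k = 6, a trophic-position model per consumer with
#' literature comparison, and guild-source mixing models for the ten taxa
#' with prior evidence of discard ingestion (SBF and BIF pooled a priori
#' in all models; PPC and PSC fitted separately and combined draw-wise for
#' the squid *Alloteuthis*).
#'
#' @param mcmc_profile `"fast"` or `"full"`.
#' @return a pipeline configuration list.
#' @export
pipeline_config_study <- function(mcmc_profile = "fast") {
  t1 <- bourgneuf_taxa()
  consumers <- t1$code[t1$cluster != "BPC"]
  mix_taxa <- c("Rund", "Scani", "Soff", "Aund", "Cpag", "Npub", "Mbra",
                "Aacu", "Bund")
  mixing <- lapply(mix_taxa, function(code) {
    list(consumer = code, groups = c("BPC", "SBF", "BIF", "DFC", "PSC"),
         pool = list(`SBF-BIF` = c("SBF", "BIF")), combine = NULL)
  })
  mixing <- c(mixing, list(list(
    consumer = "Allo", groups = c("SBF", "BIF", "DFC", "PSC", "PPC"),
    pool = list(`SBF-BIF` = c("SBF", "BIF")),
    combine = list(`PPC-PSC` = c("PPC", "PSC"), `SBF-BIF` = "SBF-BIF",
                   DFC = "DFC"))))
  list(
    data = list(source = "bourgneuf"),
    baselines = list(benthic_taxon = "Pmax", pelagic_taxon = "Sspr",
                     lambda = 2, retro = TRUE),
    clustering = list(m = 4, B = 500, k = 6),
    tp = list(taxa = consumers),
    mixing = mixing,
    mcmc_profile = mcmc_profile)
}

pipeline_load_data <- function(config, seed) {
  src <- config$data$source
  if (src == "csv") {
    list(dataset = read_samples(config$data$path), truth = NULL, baselines = NULL)
  } else if (src == "bourgneuf") {
    list(dataset = bourgneuf_dataset(seed), truth = NULL, baselines = NULL)
  } else if (src == "synthetic") {
    simulate_community(config$data$synthetic, seed = seed)
  } else {
    stop("pipeline stage 'load': unknown data source '", src, "'", call. = FALSE)
  }
}

pipeline_baselines <- function(config, dataset, seed) {
  bc <- config$baselines
  benthic <- dataset[dataset$taxon_id == bc$benthic_taxon, ]
  if (isTRUE(bc$retro)) {
    consumer <- dataset[dataset$taxon_id == bc$pelagic_taxon, ]
    tdf <- tdf_for_class(consumer$tax_class[1])
    retro <- retrocalculate_baseline(consumer, tdf, n_sim = 50, resample_k = 7,
                                     seed = derive_seed(seed, "ppc"))
    pelagic <- retro$samples
  } else {
    pelagic <- dataset[dataset$taxon_id == bc$pelagic_taxon, ]
  }
  build_baseline_pair(benthic, pelagic, lambda = bc$lambda)
}

#' Run the full analysis pipeline
#'
#' Executes validate, summarize, baseline construction, guild clustering,
#' per-taxon trophic-position models (with literature comparison when
#' reference levels are available), polygon-screened diet mixing models
#' and convergence diagnostics, writing every stage's output as CSV plus
#' a JSON run manifest to `out_dir`. All randomness flows from `seed`
#' through per-stage derived sub-seeds, so the run is reproducible and
#' stage-level reruns match pipeline runs.
#'
#' @param config configuration list (see [pipeline_config_demo()],
#'   [pipeline_config_study()]) or path to an equivalent YAML file.
#' @param out_dir output directory, created if absent.
#' @param seed integer master seed.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory stage results:
#'   `dataset`, `flags`, `taxa_summary`, `baselines`, `partition`,
#'   `tp_summary`, `tp_fits`, `mixing_summary`, `mixing_fits`,
#'   `diagnostics`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, seed = 1, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  say("load", "reading data (source = ", config$data$source, ")")
  loaded <- stage("load", pipeline_load_data(config, seed))
  dataset <- loaded$dataset
  write_samples(dataset, file.path(out_dir, "dataset.csv"))
  if (!is.null(loaded$truth)) {
    utils::write.csv(loaded$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  }

  flags <- stage("validate", validate_samples(dataset))
  utils::write.csv(flags, file.path(out_dir, "validation_flags.csv"), row.names = FALSE)
  say("validate", nrow(flags), " flag(s)")

  taxa_summary <- stage("summarize", summarize_taxa(dataset))
  utils::write.csv(taxa_summary, file.path(out_dir, "taxa_summary.csv"), row.names = FALSE)

  baselines <- stage("baseline", pipeline_baselines(config, dataset, seed))
  utils::write.csv(summarize_taxa(community_dataset(rbind(
    as.data.frame(baselines$benthic), as.data.frame(baselines$pelagic)))),
    file.path(out_dir, "baselines.csv"), row.names = FALSE)
  say("baseline", "lambda = ", baselines$lambda)

  cl <- config$clustering
  ens <- stage("cluster", bootstrap_distances(dataset, m = cl$m, B = cl$B,
                                              seed = derive_seed(seed, "cluster")))
  tree <- upgma(ens)
  partition <- select_clusters(tree, k = cl$k)
  utils::write.csv(as.data.frame(ens$avg_matrix),
                   file.path(out_dir, "avg_distance_matrix.csv"))
  writeLines(tree_newick(tree), file.path(out_dir, "dendrogram.nwk"))
  utils::write.csv(data.frame(taxon_id = names(partition$assignments),
                              guild = unname(partition$assignments)),
                   file.path(out_dir, "guilds.csv"), row.names = FALSE)
  say("cluster", partition$k, " guilds from B = ", ens$B, " replicates")

  prof <- config$mcmc_profile %||% "fast"
  t1 <- if (config$data$source == "bourgneuf") bourgneuf_taxa() else NULL
  tp_fits <- list()
  tp_rows <- list()
  for (code in config$tp$taxa) {
    consumer <- dataset[dataset$taxon_id == code, ]
    fit <- stage(paste0("tp:", code), fit_tp(
      consumer, baselines, tdf_for_class(consumer$tax_class[1]),
      mcmc = mcmc_profile(prof, seed = derive_seed(seed, paste0("tp-", code)))))
    tp_fits[[code]] <- fit
    row <- data.frame(taxon_id = code, n = nrow(consumer),
                      mean_tp = fit$mean_tp,
                      ci_lo = unname(fit$ci95["lo"]), ci_hi = unname(fit$ci95["hi"]),
                      rhat = fit$rhat, converged = fit$converged,
                      ref_mean = NA_real_, ref_se = NA_real_, overlap = NA,
                      stringsAsFactors = FALSE)
    if (!is.null(t1) && code %in% t1$code && !is.na(t1$ref_tl_mean[t1$code == code])) {
      cmp <- compare_to_reference(fit, t1$ref_tl_mean[t1$code == code],
                                  t1$ref_tl_se[t1$code == code])
      row$ref_mean <- cmp$ref_mean; row$ref_se <- cmp$ref_se
      row$overlap <- cmp$overlap
    }
    tp_rows[[code]] <- row
    say("tp", code, sprintf(": TP %.2f (%.2f-%.2f)", fit$mean_tp,
                            fit$ci95["lo"], fit$ci95["hi"]))
  }
  tp_summary <- if (length(tp_rows) > 0) do.call(rbind, tp_rows) else NULL
  if (!is.null(tp_summary)) {
    rownames(tp_summary) <- NULL
    utils::write.csv(tp_summary, file.path(out_dir, "tp_summary.csv"), row.names = FALSE)
  }

  mixing_fits <- list()
  mix_rows <- list()
  for (mx in config$mixing) {
    code <- mx$consumer
    consumer <- dataset[dataset$taxon_id == code, ]
    src <- stage(paste0("mix:", code), if (config$data$source == "bourgneuf") {
      bourgneuf_sources(consumer$tax_class[1], group_ids = mx$groups,
                        pool = mx$pool %||% list())
    } else {
      mx$sources
    })
    fit <- stage(paste0("mix:", code), fit_mixing(
      consumer, src,
      mcmc = mcmc_profile(prof, seed = derive_seed(seed, paste0("mix-", code)))))
    if (!is.null(mx$combine)) fit <- combine_posterior(fit, mx$combine)
    mixing_fits[[code]] <- fit
    s <- fit$summary
    s <- cbind(data.frame(consumer = code, stringsAsFactors = FALSE), s,
               data.frame(dic = fit$dic, polygon_ok = isTRUE(fit$polygon_ok)))
    mix_rows[[code]] <- s
    say("mix", code, ": top source ", s$source_id[which.max(s$mean)],
        sprintf(" (%.0f%%)", 100 * max(s$mean)))
  }
  mixing_summary <- if (length(mix_rows) > 0) do.call(rbind, mix_rows) else NULL
  if (!is.null(mixing_summary)) {
    rownames(mixing_summary) <- NULL
    utils::write.csv(mixing_summary, file.path(out_dir, "mixing_summary.csv"),
                     row.names = FALSE)
  }

  diag_sets <- lapply(tp_fits, function(f) f$tp_by_chain)
  names(diag_sets) <- if (length(tp_fits)) paste0("TP_", names(tp_fits)) else character()
  diagnostics <- if (length(diag_sets) > 0) diagnose_chains(diag_sets) else NULL
  if (!is.null(diagnostics)) {
    utils::write.csv(diagnostics, file.path(out_dir, "diagnostics.csv"),
                     row.names = FALSE)
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(seed = seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   package_version = as.character(utils::packageVersion("isofoodweb")),
                   r_version = R.version.string,
                   n_taxa = length(unique(dataset$taxon_id)),
                   n_individuals = nrow(dataset))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done", "outputs in ", out_dir)
  invisible(list(dataset = dataset, flags = flags, taxa_summary = taxa_summary,
                 baselines = baselines, partition = partition,
                 tp_summary = tp_summary, tp_fits = tp_fits,
                 mixing_summary = mixing_summary, mixing_fits = mixing_fits,
                 diagnostics = diagnostics, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
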
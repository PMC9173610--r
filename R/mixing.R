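#' Diet source table
#'
#' Sources are trophic guilds (or taxa) characterized by their tracer
#' moments and sample size, each carrying the TDF of the *consumer* whose
#' diet is being modeled -- trophic discrimination happens in the consumer,
#' so one consumer-class TDF applies to every source in its model.
#'
#' @param df data.frame with columns `source_id`, `mean_dC`, `sd_dC`,
#'   `mean_dN`, `sd_dN`, `n`.
#' @param tdf a [tdf_spec()] applied to all sources, or NULL if `df`
#'   already carries `tdf_mean_dC`, `tdf_sd_dC`, `tdf_mean_dN`,
#'   `tdf_sd_dN` columns.
#' @return object of class `diet_sources`.
#' @export
diet_sources <- function(df, tdf = NULL) {
  stopifnot(is.data.frame(df))
  need <- c("source_id", "mean_dC", "sd_dC", "mean_dN", "sd_dN", "n")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("diet_sources: missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) < 2) stop("at least 2 sources required", call. = FALSE)
  if (anyDuplicated(df$source_id)) stop("source ids must be unique", call. = FALSE)
  stopifnot(all(df$sd_dC >= 0), all(df$sd_dN >= 0))
  if (!is.null(tdf)) {
    stopifnot(inherits(tdf, "tdf_spec"))
    df$tdf_mean_dC <- tdf$mean_dC
    df$tdf_sd_dC <- tdf$sd_dC
    df$tdf_mean_dN <- tdf$mean_dN
    df$tdf_sd_dN <- tdf$sd_dN
  }
  tcols <- c("tdf_mean_dC", "tdf_sd_dC", "tdf_mean_dN", "tdf_sd_dN")
  if (length(setdiff(tcols, names(df))) > 0) {
    stop("sources need a TDF: pass `tdf` or include tdf_* columns", call. = FALSE)
  }
  rownames(df) <- NULL
  structure(list(sources = df), class = "diet_sources")
}

MIX_MODEL_STRING <- "
model {
  p ~ ddirch(aD)
  for (t in 1:nt) {
    eps[t] ~ dunif(eps_lo, eps_hi)
    mu[t] <- inprod(p, smu[, t] + tmu[, t])
    v[t] <- eps[t] * inprod(p * p, pow(ssd[, t], 2) + pow(tsd[, t], 2))
    for (j in 1:nc) {
      y[j, t] ~ dnorm(mu[t], 1 / v[t])
    }
  }
}"

# Mixture mean and variance per tracer for given proportions/multipliers.
mix_moments <- function(p, eps, src, tracers) {
  cols <- list(d13C = c("mean_dC", "sd_dC", "tdf_mean_dC", "tdf_sd_dC"),
               d15N = c("mean_dN", "sd_dN", "tdf_mean_dN", "tdf_sd_dN"))
  out <- lapply(seq_along(tracers), function(t) {
    cc <- cols[[tracers[t]]]
    m <- sum(p * (src[[cc[1]]] + src[[cc[3]]]))
    v <- eps[t] * sum(p^2 * (src[[cc[2]]]^2 + src[[cc[4]]]^2))
    c(m, v)
  })
  list(mu = vapply(out, `[`, numeric(1), 1),
       v = vapply(out, `[`, numeric(1), 2))
}

# -2 log-likelihood of consumer data y (n x nt) at (p, eps).
mix_deviance <- function(p, eps, src, y, tracers) {
  mm <- mix_moments(p, eps, src, tracers)
  v <- pmax(mm$v, 1e-12)
  ll <- 0
  for (t in seq_along(tracers)) {
    ll <- ll + sum(stats::dnorm(y[, t], mm$mu[t], sqrt(v[t]), log = TRUE))
  }
  -2 * ll
}

summarize_p_draws <- function(p_draws) {
  data.frame(
    source_id = colnames(p_draws),
    mean = colMeans(p_draws),
    mode = apply(p_draws, 2, posterior_mode),
    ci_lo = apply(p_draws, 2, function(x) ci_equal_tailed(x)["lo"]),
    ci_hi = apply(p_draws, 2, function(x) ci_equal_tailed(x)["hi"]),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit a Bayesian diet-proportion mixing model
#'
#' The consumer's tracer values are modeled as a proportion-weighted
#' mixture of TDF-shifted sources with process and residual error: per
#' tracer `t` and individual `j`, `y_jt ~ Normal(sum_k p_k (mu_kt +
#' tdf_mu_kt), sqrt(eps_t sum_k p_k^2 (sd_kt^2 + tdf_sd_kt^2)))`. The
#' proportion vector has an uninformative Dirichlet(1, ..., 1) prior; the
#' per-tracer residual multiplier `eps_t >= 1` inflates the process
#' variance (Uniform(1, 25) prior), nesting the process-only model at
#' `eps = 1`. Feasibility of the source polygon is checked up front with
#' [polygon_check()]; an outside consumer yields a warning, not an error.
#' DIC (mean deviance + pD) is computed from the draws for model
#' comparison.
#'
#' @param consumer a [community_dataset()] with >= 2 rows of one taxon.
#' @param sources a [diet_sources()].
#' @param mcmc an [mcmc_settings()].
#' @param tracers tracers to use (default both `d13C` and `d15N`).
#' @param resid_prior bounds of the uniform prior on the residual variance
#'   multiplier (default `c(1, 25)`).
#' @return object of class `diet_posterior`: `p_draws` (draws x sources,
#'   rows on the simplex), `eps_draws`, `summary` (mean, mode via kernel
#'   density, equal-tailed 95% CI per source), `dic`, `pd`, `rhat`,
#'   `converged`, `polygon_ok`.
#' @export
fit_mixing <- function(consumer, sources, mcmc = mcmc_profile("fast"),
                       tracers = c("d13C", "d15N"), resid_prior = c(1, 25)) {
  stopifnot(inherits(sources, "diet_sources"), inherits(mcmc, "mcmc_settings"))
  if (nrow(consumer) < 2) stop("consumer needs n >= 2", call. = FALSE)
  tracers <- match.arg(tracers, c("d13C", "d15N"), several.ok = TRUE)
  src <- sources$sources
  K <- nrow(src)
  y <- as.matrix(as.data.frame(consumer)[, tracers, drop = FALSE])
  cols <- list(d13C = c("mean_dC", "sd_dC", "tdf_mean_dC", "tdf_sd_dC"),
               d15N = c("mean_dN", "sd_dN", "tdf_mean_dN", "tdf_sd_dN"))
  smu <- vapply(tracers, function(tr) src[[cols[[tr]][1]]], numeric(K))
  ssd <- vapply(tracers, function(tr) src[[cols[[tr]][2]]], numeric(K))
  tmu <- vapply(tracers, function(tr) src[[cols[[tr]][3]]], numeric(K))
  tsd <- vapply(tracers, function(tr) src[[cols[[tr]][4]]], numeric(K))
  dim(smu) <- dim(ssd) <- dim(tmu) <- dim(tsd) <- c(K, length(tracers))
  # keep the sampler defined when a tracer's process variance is zero
  ssd[ssd == 0 & rep(colSums(ssd + tsd) == 0, each = K)] <- 1e-4
  polygon_ok <- if (length(tracers) == 2 && K >= 3) {
    polygon_check(c(mean(y[, 1]), mean(y[, 2])), sources, tracers = tracers)
  } else NA
  if (isFALSE(polygon_ok)) {
    warning("consumer mean lies outside the mixing polygon of the sources",
            call. = FALSE)
  }
  dat <- list(y = y, nc = nrow(y), nt = length(tracers), aD = rep(1, K),
              smu = smu, ssd = ssd, tmu = tmu, tsd = tsd,
              eps_lo = resid_prior[1], eps_hi = resid_prior[2])
  model <- jags_model_quietly(textConnection(MIX_MODEL_STRING), data = dat,
                             inits = jags_inits(mcmc$chains, mcmc$seed),
                             n.chains = mcmc$chains, n.adapt = mcmc$adapt,
                             quiet = TRUE)
  stats::update(model, mcmc$burn_in, progress.bar = "none")
  samp <- rjags::coda.samples(model, c("p", "eps"),
                              n.iter = mcmc$iterations - mcmc$burn_in,
                              thin = mcmc$thin, progress.bar = "none")
  all_cols <- colnames(as.matrix(samp[[1]]))
  p_cols <- paste0("p[", seq_len(K), "]")
  eps_cols <- if (length(tracers) == 1 && "eps" %in% all_cols) "eps" else
    paste0("eps[", seq_along(tracers), "]")
  p_by_chain <- lapply(samp, function(ch) as.matrix(ch)[, p_cols, drop = FALSE])
  p_draws <- do.call(rbind, p_by_chain)
  colnames(p_draws) <- src$source_id
  eps_draws <- do.call(rbind, lapply(samp, function(ch)
    as.matrix(ch)[, eps_cols, drop = FALSE]))
  colnames(eps_draws) <- tracers
  # renormalize away ddirch round-off so simplex holds to machine accuracy
  p_draws <- p_draws / rowSums(p_draws)
  dev_draws <- vapply(seq_len(nrow(p_draws)), function(i) {
    mix_deviance(p_draws[i, ], eps_draws[i, ], src, y, tracers)
  }, numeric(1))
  dbar <- mean(dev_draws)
  p_bar <- colMeans(p_draws); p_bar <- p_bar / sum(p_bar)
  d_at_mean <- mix_deviance(p_bar, colMeans(eps_draws), src, y, tracers)
  pd <- dbar - d_at_mean
  rhat <- max(vapply(seq_len(K), function(k) {
    gelman_rubin(lapply(p_by_chain, function(m) m[, k]))
  }, numeric(1)))
  structure(list(
    taxon_id = consumer$taxon_id[1],
    p_draws = p_draws, eps_draws = eps_draws, dev_draws = dev_draws,
    summary = summarize_p_draws(p_draws),
    dic = dbar + pd, pd = pd, mean_deviance = dbar,
    rhat = rhat, converged = is.finite(rhat) && rhat <= 1.1,
    polygon_ok = polygon_ok, sources = sources, tracers = tracers,
    settings = mcmc), class = "diet_posterior")
}

#' @export
print.diet_posterior <- function(x, ...) {
  cat(sprintf("Diet of %s (%d sources, DIC %.1f%s)\n", x$taxon_id,
              ncol(x$p_draws), x$dic,
              if (x$converged) "" else ", NOT CONVERGED"))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-10s mean %4.1f%%  mode %4.1f%%  95%% CI %4.1f-%4.1f%%\n",
                s$source_id[i], 100 * s$mean[i], 100 * s$mode[i],
                100 * s$ci_lo[i], 100 * s$ci_hi[i]))
  }
  invisible(x)
}

#' Pool sources a priori
#'
#' Merges guilds before fitting, reducing the source count: merged moments
#' are the n-weighted pooled moments of the members ([pool_moments()]),
#' and the merged TDF is the n-weighted pooled combination of the member
#' TDFs. Sources not named in `merge_spec` pass through unchanged.
#'
#' @param sources a [diet_sources()].
#' @param merge_spec named list: new source_id -> character vector of
#'   member source_ids; each source may appear in at most one group.
#' @return a [diet_sources()] with merged rows (merged groups first, in
#'   `merge_spec` order, then untouched sources).
#' @export
pool_sources <- function(sources, merge_spec) {
  stopifnot(inherits(sources, "diet_sources"), is.list(merge_spec))
  src <- sources$sources
  members <- unlist(merge_spec, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("overlapping merge groups in merge_spec", call. = FALSE)
  }
  unknown <- setdiff(members, src$source_id)
  if (length(unknown) > 0) {
    stop("unknown source(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  merged <- do.call(rbind, lapply(names(merge_spec), function(id) {
    rows <- src[src$source_id %in% merge_spec[[id]], ]
    mC <- pool_moments(rows$mean_dC, rows$sd_dC, rows$n)
    mN <- pool_moments(rows$mean_dN, rows$sd_dN, rows$n)
    tC <- pool_moments(rows$tdf_mean_dC, rows$tdf_sd_dC, rows$n)
    tN <- pool_moments(rows$tdf_mean_dN, rows$tdf_sd_dN, rows$n)
    data.frame(source_id = id, mean_dC = mC["mean"], sd_dC = mC["sd"],
               mean_dN = mN["mean"], sd_dN = mN["sd"], n = mC["n"],
               tdf_mean_dC = tC["mean"], tdf_sd_dC = tC["sd"],
               tdf_mean_dN = tN["mean"], tdf_sd_dN = tN["sd"],
               stringsAsFactors = FALSE)
  }))
  rest <- src[!src$source_id %in% members, ]
  out <- rbind(merged, rest)
  rownames(out) <- NULL
  diet_sources(out)
}

#' Combine posterior proportions draw-wise
#'
#' Pools sources *after* fitting by summing member proportions within each
#' draw, then re-summarizing; the simplex is preserved exactly. This is
#' distinct from a-priori pooling ([pool_sources()]) except in the
#' zero-variance limit.
#'
#' @param post a `diet_posterior`.
#' @param groups named list partitioning the source ids: new label ->
#'   members. Every source must appear exactly once.
#' @return a `diet_posterior` over the combined sources (DIC and deviance
#'   carried over from the fitted model; they are unchanged by relabeling).
#' @export
combine_posterior <- function(post, groups) {
  stopifnot(inherits(post, "diet_posterior"), is.list(groups))
  members <- unlist(groups, use.names = FALSE)
  ids <- colnames(post$p_draws)
  if (length(members) != length(ids) || !setequal(members, ids) ||
      anyDuplicated(members)) {
    stop("groups must partition the source list exactly", call. = FALSE)
  }
  combined <- vapply(groups, function(g) {
    rowSums(post$p_draws[, g, drop = FALSE])
  }, numeric(nrow(post$p_draws)))
  colnames(combined) <- names(groups)
  out <- post
  out$p_draws <- combined
  out$summary <- summarize_p_draws(combined)
  out
}

#' Deviance information criterion of a fitted mixing model
#'
#' `DIC = mean deviance + pD`, with the effective parameter count
#' `pD = mean deviance - deviance at the posterior mean parameters`.
#' Smaller is better; differences of a few units are noise.
#'
#' @param post a `diet_posterior`.
#' @return the DIC (numeric scalar).
#' @export
dic <- function(post) {
  stopifnot(inherits(post, "diet_posterior"))
  post$dic
}

#' Mixing-polygon feasibility check
#'
#' A consumer can only be explained by a source set if its TDF-corrected
#' mean lies inside the convex hull of the source means in tracer space.
#' The consumer mean minus the (consumer-class) TDF means is tested against
#' the closed hull (boundary counts as inside, tolerance 1e-9). With fewer
#' than 3 sources the hull is degenerate and a 1-D interval test per
#' tracer is used.
#'
#' @param consumer_mean numeric length-2 vector of the consumer's mean
#'   tracer values, in `tracers` order.
#' @param sources a [diet_sources()].
#' @param tracers tracer order of `consumer_mean` (default d13C, d15N).
#' @return TRUE if the corrected consumer mean is inside the polygon.
#' @export
polygon_check <- function(consumer_mean, sources,
                          tracers = c("d13C", "d15N")) {
  stopifnot(inherits(sources, "diet_sources"), length(consumer_mean) == 2)
  src <- sources$sources
  mu <- cbind(
    if ("d13C" %in% tracers) src$mean_dC + src$tdf_mean_dC else NULL,
    if ("d15N" %in% tracers) src$mean_dN + src$tdf_mean_dN else NULL)
  mu <- mu[, order(match(c("d13C", "d15N")[c("d13C", "d15N") %in% tracers],
                         tracers)), drop = FALSE]
  pt <- as.numeric(consumer_mean)
  tol <- 1e-9
  if (nrow(src) < 3) {
    return(all(pt >= apply(mu, 2, min) - tol & pt <= apply(mu, 2, max) + tol))
  }
  hull <- grDevices::chull(mu)
  hx <- mu[hull, 1]; hy <- mu[hull, 2]
  nh <- length(hull)
  # chull returns clockwise order; inside iff every edge cross-product has
  # the same (non-positive) sign, with |cross| <= tol counting as on-edge.
  cr <- vapply(seq_len(nh), function(i) {
    j <- if (i == nh) 1L else i + 1L
    (hx[j] - hx[i]) * (pt[2] - hy[i]) - (hy[j] - hy[i]) * (pt[1] - hx[i])
  }, numeric(1))
  all(cr <= tol) || all(cr >= -tol)
}
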
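#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) R-hat: with `m` chains of length `n`, within-chain
#' variance `W` (mean of chain variances) and between-chain variance
#' `B = n * var(chain means)`,
#' `Rhat = sqrt(((n - 1)/n * W + B/n) / W)`, floored at 1 (by chance the
#' variance ratio can dip marginally below 1 when chains agree more closely
#' than independent sampling would; the floor keeps the statistic
#' interpretable as a scale *reduction* factor). Values near 1 indicate the
#' chains sample the same distribution; > 1.1 is the conventional
#' non-convergence flag.
#'
#' @param chains list of >= 2 equal-length numeric vectors (one per
#'   chain), or a matrix with one column per chain.
#' @return R-hat (numeric scalar; 1 exactly when the chain means agree).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (length(chains) < 2) stop("at least 2 chains required", call. = FALSE)
  lens <- lengths(chains)
  stopifnot(all(lens == lens[1]), lens[1] >= 10)
  n <- lens[1]
  means <- vapply(chains, mean, numeric(1))
  W <- mean(vapply(chains, stats::var, numeric(1)))
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  max(1, sqrt(((n - 1) / n * W + B / n) / W))
}

# Spectral density at frequency zero via a Bartlett-windowed autocovariance
# sum; lag window = floor(sqrt(length)).
spectral_density_zero <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(0)
  W <- floor(sqrt(n))
  ac <- stats::acf(x, lag.max = W, type = "covariance", plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  g0 <- ac[1]
  if (W >= 1) {
    w <- 1 - seq_len(W) / (W + 1)
    g0 <- g0 + 2 * sum(w * ac[-1])
  }
  max(g0, 0)
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first `frac_a` of a chain with the mean of the
#' last `frac_b`, standardized by spectral-density-at-zero standard errors
#' (Bartlett-windowed autocovariance estimate), so autocorrelation does not
#' deflate the standard errors. Under stationarity z is asymptotically
#' standard normal; |z| > 2 flags a drifting chain.
#'
#' @param chain numeric vector, length >= 100.
#' @param frac_a fraction used for the early window (default 0.1).
#' @param frac_b fraction used for the late window (default 0.5).
#' @return z-score (0 for a constant chain).
#' @export
geweke <- function(chain, frac_a = 0.1, frac_b = 0.5) {
  n <- length(chain)
  if (n < 100) stop("chain too short for Geweke diagnostic (need >= 100)",
                    call. = FALSE)
  stopifnot(frac_a > 0, frac_b > 0, frac_a + frac_b <= 1)
  a <- chain[seq_len(floor(frac_a * n))]
  b <- chain[seq.int(n - floor(frac_b * n) + 1, n)]
  se2 <- spectral_density_zero(a) / length(a) +
    spectral_density_zero(b) / length(b)
  if (se2 == 0) return(0)
  (mean(a) - mean(b)) / sqrt(se2)
}

#' Convergence report for a set of monitored parameters
#'
#' @param chain_sets named list; each element is a list of per-chain
#'   numeric vectors for one parameter.
#' @param rhat_max,geweke_max verdict thresholds (defaults 1.1 and 2).
#' @return data.frame: `parameter`, `rhat`, `geweke_z` (worst chain),
#'   `verdict` ("ok" or "check").
#' @export
diagnose_chains <- function(chain_sets, rhat_max = 1.1, geweke_max = 2) {
  stopifnot(is.list(chain_sets), length(chain_sets) > 0)
  out <- do.call(rbind, lapply(names(chain_sets), function(par) {
    cs <- chain_sets[[par]]
    rh <- gelman_rubin(cs)
    gz <- max(abs(vapply(cs, geweke, numeric(1))))
    data.frame(parameter = par, rhat = rh, geweke_z = gz,
               verdict = if (rh <= rhat_max && gz <= geweke_max) "ok" else "check",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
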
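# Deterministic sub-seed derivation: one master seed drives every stage,
# so stage-level reruns reproduce pipeline runs. Kept within 32-bit range.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Equal-tailed credible interval from draws.
ci_equal_tailed <- function(draws, level = 0.95) {
  a <- (1 - level) / 2
  q <- stats::quantile(draws, c(a, 1 - a), names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

# Posterior mode via Gaussian kernel density (Silverman bandwidth).
posterior_mode <- function(draws) {
  if (diff(range(draws)) < 1e-12) return(mean(draws))
  d <- stats::density(draws, bw = "nrd0")
  d$x[which.max(d$y)]
}

# jags.model reports "Adaptation incomplete" on small conjugate models
# whose samplers need no tuning; muffle just that warning (convergence is
# still guarded by the diagnostics).
jags_model_quietly <- function(...) {
  withCallingHandlers(
    rjags::jags.model(...),
    warning = function(w) {
      if (grepl("Adaptation incomplete", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

# Per-chain JAGS RNG initialisation for reproducible sampling.
jags_inits <- function(chains, seed) {
  lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(seed, paste0("chain", ch)))
  })
}
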
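test_that("a pure-diet consumer is attributed to its source", {
  src <- two_source_fixture(sd = 0.05)
  src$sources$tdf_sd_dC <- 0.02; src$sources$tdf_sd_dN <- 0.02
  consumer <- reconstitute_samples("pure", -20 + 0.5, 0.05, 9 + 2.3, 0.05,
                                   n = 8, seed = 1, tax_class = "Decapoda")
  fit <- fit_mixing(consumer, src, quick_mcmc(1))
  expect_gt(fit$summary$mean[fit$summary$source_id == "S1"], 0.95)
  expect_true(fit$converged)
})

test_that("1-tracer 2-source fit matches the linear mixing closed form", {
  src <- diet_sources(data.frame(
    source_id = c("S1", "S2"),
    mean_dC = c(-20, -14), sd_dC = 0.02,
    mean_dN = c(9, 15), sd_dN = 0.02,
    n = 10, stringsAsFactors = FALSE), tdf = tdf_spec(0.5, 0.01, 2.3, 0.01))
  p1 <- 0.3
  target <- p1 * (9 + 2.3) + (1 - p1) * (15 + 2.3)
  consumer <- reconstitute_samples("mix", -17, 0.02, target, 0.02, n = 10,
                                   seed = 2, tax_class = "Decapoda")
  fit <- fit_mixing(consumer, src, fast_mcmc(3), tracers = "d15N")
  closed_form <- (mean(consumer$d15N) - (15 + 2.3)) / ((9 + 2.3) - (15 + 2.3))
  expect_equal(closed_form, p1, tolerance = 1e-9)
  expect_lt(abs(fit$summary$mean[1] - closed_form), 0.02)
})

test_that("every posterior draw lies on the simplex", {
  src <- two_source_fixture()
  consumer <- simulate_mixture_consumer("c", c(0.6, 0.4), 10, src, seed = 3)
  fit <- fit_mixing(consumer, src, quick_mcmc(4))
  expect_true(all(abs(rowSums(fit$p_draws) - 1) < 1e-9))
  expect_true(all(fit$p_draws >= 0))
  expect_true(all(fit$summary$ci_lo <= fit$summary$ci_hi))
  expect_equal(fit$dic, fit$mean_deviance + fit$pd)
})

test_that("source order does not change the inference", {
  src3 <- diet_sources(data.frame(
    source_id = c("S1", "S2", "S3"),
    mean_dC = c(-20, -16, -13), sd_dC = 0.4,
    mean_dN = c(9, 15, 10), sd_dN = 0.4,
    n = 10, stringsAsFactors = FALSE), tdf = tdf_spec(0.5, 0.13, 2.3, 0.18))
  consumer <- simulate_mixture_consumer("c", c(0.5, 0.3, 0.2), 20, src3, seed = 5)
  fit <- fit_mixing(consumer, src3, fast_mcmc(6))
  perm <- diet_sources(src3$sources[c(3, 1, 2), ], tdf = NULL)
  fit_perm <- fit_mixing(consumer, perm, fast_mcmc(6))
  a <- fit$summary[order(fit$summary$source_id), ]
  b <- fit_perm$summary[order(fit_perm$summary$source_id), ]
  expect_equal(a$mean, b$mean, tolerance = 0.03)
})

test_that("a-priori pooling follows the pooled-moments formula", {
  g <- bourgneuf_groups()
  names(g)[names(g) == "group_id"] <- "source_id"
  src <- diet_sources(g, tdf = tdf_registry()$invertebrate)
  pooled <- pool_sources(src, list(`SBF-BIF` = c("SBF", "BIF")))
  row <- pooled$sources[pooled$sources$source_id == "SBF-BIF", ]
  ref <- pool_moments(c(-15.7, -16.9), c(0.9, 0.7), c(21, 72))
  expect_equal(row$mean_dC, unname(ref["mean"]), tolerance = 1e-12)
  expect_equal(row$sd_dC, unname(ref["sd"]), tolerance = 1e-12)
  expect_equal(row$n, 93)
  expect_equal(nrow(pooled$sources), 5)

  identity <- pool_sources(src, list())
  expect_equal(identity$sources[order(identity$sources$source_id), ],
               src$sources[order(src$sources$source_id), ], ignore_attr = TRUE)

  twin <- diet_sources(data.frame(
    source_id = c("T1", "T2"), mean_dC = -17, sd_dC = 0.5,
    mean_dN = 12, sd_dN = 0.4, n = 5, stringsAsFactors = FALSE),
    tdf = tdf_spec(0.5, 0.13, 2.3, 0.18))
  twin2 <- diet_sources(rbind(twin$sources, transform(twin$sources[1, ],
                                                      source_id = "T3")))
  same <- pool_sources(twin2, list(TT = c("T1", "T2")))
  row2 <- same$sources[same$sources$source_id == "TT", ]
  expect_equal(row2$mean_dC, -17)
  expect_equal(row2$sd_dC, 0.5)

  expect_error(pool_sources(src, list(a = c("SBF", "BIF"), b = c("BIF", "DFC"))),
               "overlapping")
})

test_that("draw-wise combination preserves the simplex and sums members", {
  src3 <- diet_sources(data.frame(
    source_id = c("S1", "S2", "S3"),
    mean_dC = c(-20, -16, -13), sd_dC = 0.4,
    mean_dN = c(9, 15, 10), sd_dN = 0.4,
    n = 10, stringsAsFactors = FALSE), tdf = tdf_spec(0.5, 0.13, 2.3, 0.18))
  consumer <- simulate_mixture_consumer("c", c(0.5, 0.3, 0.2), 15, src3, seed = 9)
  fit <- fit_mixing(consumer, src3, quick_mcmc(7))

  single <- combine_posterior(fit, list(S1 = "S1", S2 = "S2", S3 = "S3"))
  expect_equal(single$summary$mean, fit$summary$mean)

  all_in <- combine_posterior(fit, list(all = c("S1", "S2", "S3")))
  expect_true(all(abs(all_in$p_draws[, "all"] - 1) < 1e-9))

  pair <- combine_posterior(fit, list(S12 = c("S1", "S2"), S3 = "S3"))
  expect_equal(pair$p_draws[, "S12"],
               fit$p_draws[, "S1"] + fit$p_draws[, "S2"])
  expect_true(all(abs(rowSums(pair$p_draws) - 1) < 1e-9))

  expect_error(combine_posterior(fit, list(S12 = c("S1", "S2"))), "partition")
})

test_that("post-hoc combination differs from a-priori pooling away from the zero-variance limit", {
  src3 <- diet_sources(data.frame(
    source_id = c("S1", "S2", "S3"),
    mean_dC = c(-20, -17, -12), sd_dC = c(0.4, 0.4, 0.4),
    mean_dN = c(9, 16, 11), sd_dN = c(0.4, 0.4, 0.4),
    n = c(10, 10, 10), stringsAsFactors = FALSE),
    tdf = tdf_spec(0.5, 0.13, 2.3, 0.18))
  consumer <- simulate_mixture_consumer("c", c(0.6, 0.2, 0.2), 20, src3, seed = 10)
  post_hoc <- combine_posterior(fit_mixing(consumer, src3, fast_mcmc(8)),
                                list(S23 = c("S2", "S3"), S1 = "S1"))
  a_priori <- fit_mixing(consumer,
                         pool_sources(src3, list(S23 = c("S2", "S3"))),
                         fast_mcmc(8))
  ph <- post_hoc$summary$mean[post_hoc$summary$source_id == "S23"]
  ap <- a_priori$summary$mean[a_priori$summary$source_id == "S23"]
  # pooling S2 and S3 a priori inflates the pooled source variance and
  # shifts its mean; the two pooling modes answer different questions
  expect_gt(abs(ph - ap), 0.02)
})

test_that("DIC prefers the true source set on pure-diet data", {
  src2 <- two_source_fixture(sd = 0.3)
  # wrong sources span a line in tracer space that misses the consumer,
  # so no proportion vector can fit both tracer means
  wrong <- diet_sources(data.frame(
    source_id = c("W1", "W2"),
    mean_dC = c(-24, -10), sd_dC = 0.3,
    mean_dN = c(5, 12), sd_dN = 0.3,
    n = 10, stringsAsFactors = FALSE), tdf = tdf_spec(0.5, 0.1, 2.3, 0.15))
  wins <- vapply(1:10, function(s) {
    consumer <- simulate_mixture_consumer("c", c(0.9, 0.1), 12, src2,
                                          resid_sd = 0.2, seed = s)
    d_true <- dic(fit_mixing(consumer, src2, quick_mcmc(s)))
    d_wrong <- dic(fit_mixing(consumer, wrong, quick_mcmc(s)))
    d_true < d_wrong
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("an irrelevant far-away source does not spuriously improve DIC", {
  src2 <- two_source_fixture(sd = 0.3)
  with_junk <- diet_sources(rbind(
    src2$sources,
    data.frame(source_id = "junk", mean_dC = -30, sd_dC = 0.3,
               mean_dN = 25, sd_dN = 0.3, n = 10,
               tdf_mean_dC = 0.5, tdf_sd_dC = 0.1,
               tdf_mean_dN = 2.3, tdf_sd_dN = 0.15,
               stringsAsFactors = FALSE)))
  consumer <- simulate_mixture_consumer("c", c(0.7, 0.3), 15, src2,
                                        resid_sd = 0.2, seed = 12)
  d2 <- dic(fit_mixing(consumer, src2, fast_mcmc(13)))
  d3 <- dic(fit_mixing(consumer, with_junk, fast_mcmc(13)))
  expect_gt(d3, d2 - 3)  # no more than noise-level improvement
})

test_that("polygon feasibility uses the closed hull of TDF-corrected sources", {
  g <- bourgneuf_groups()
  names(g)[names(g) == "group_id"] <- "source_id"
  src <- diet_sources(g[g$source_id %in% c("BPC", "DFC", "PSC", "SBF"), ],
                      tdf = tdf_registry()$invertebrate)
  mu <- cbind(src$sources$mean_dC + 0.5, src$sources$mean_dN + 2.3)
  centroid <- colMeans(mu)
  expect_true(polygon_check(centroid, src))
  expect_false(polygon_check(centroid + c(10, 0), src))
  expect_true(polygon_check(mu[1, ], src))  # hull vertex counts as inside

  two <- two_source_fixture()
  expect_true(polygon_check(c(-17, 13), two))   # inside the 1-D interval
  expect_false(polygon_check(c(-25, 13), two))
})

test_that("a consumer outside the polygon triggers a warning, not an error", {
  src3 <- diet_sources(data.frame(
    source_id = c("S1", "S2", "S3"),
    mean_dC = c(-20, -16, -13), sd_dC = 0.4,
    mean_dN = c(9, 15, 10), sd_dN = 0.4,
    n = 10, stringsAsFactors = FALSE), tdf = tdf_spec(0.5, 0.13, 2.3, 0.18))
  outside <- reconstitute_samples("out", -28, 0.2, 20, 0.2, 6, seed = 14,
                                  tax_class = "Decapoda")
  expect_warning(fit <- fit_mixing(outside, src3, quick_mcmc(9)), "polygon")
  expect_false(fit$polygon_ok)
})
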
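test_that("bootstrap-averaged matrix is a valid dissimilarity", {
  sim <- simulate_community(default_community_config(n_taxa = 6), seed = 3)
  ens <- bootstrap_distances(sim$dataset, m = 4, B = 50, seed = 1)
  m <- ens$avg_matrix
  expect_true(isSymmetric(unname(m), tol = 1e-12))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0))
  expect_identical(bootstrap_distances(sim$dataset, m = 4, B = 50, seed = 1)$avg_matrix, m)
  expect_error(bootstrap_distances(sim$dataset, m = 0, B = 50), "m")
  expect_error(bootstrap_distances(sim$dataset, B = 0), "B")
})

test_that("identical constant taxa are at distance zero", {
  ds <- community_dataset(data.frame(
    taxon_id = rep(c("A", "B", "C"), each = 4), taxon_name = "t",
    tax_class = "Decapoda",
    d13C = c(rep(-17, 8), rep(-15, 4)),
    d15N = c(rep(12, 8), rep(14, 4)),
    pctC = NA, pctN = NA, stringsAsFactors = FALSE))
  ens <- bootstrap_distances(ds, m = 4, B = 20, seed = 2)
  expect_equal(ens$avg_matrix["A", "B"], 0)
  expect_gt(ens$avg_matrix["A", "C"], 0)
})

test_that("zero within-taxon variance makes every replicate identical", {
  ds <- community_dataset(data.frame(
    taxon_id = rep(c("A", "B", "C"), each = 5), taxon_name = "t",
    tax_class = "Decapoda",
    d13C = rep(c(-19, -17, -15), each = 5),
    d15N = rep(c(10, 12, 15), each = 5),
    pctC = NA, pctN = NA, stringsAsFactors = FALSE))
  one <- bootstrap_distances(ds, m = 4, B = 1, seed = 1)
  many <- bootstrap_distances(ds, m = 4, B = 200, seed = 9)
  expect_equal(many$avg_matrix, one$avg_matrix, tolerance = 1e-12)
})

test_that("averaged distances match exhaustive enumeration at tiny n", {
  # 3 taxa with 2 individuals each, resample size 2: each taxon's
  # bootstrap mean is min, mid or max with probabilities 1/4, 1/2, 1/4;
  # enumerate all 27 joint outcomes to get the exact expectation.
  vals <- list(A = cbind(c(-19, -18), c(10, 11)),
               B = cbind(c(-17, -16), c(12, 13)),
               C = cbind(c(-15, -14), c(14, 16)))
  outcomes <- function(x) {
    list(list(v = x[1, ], p = 0.25),
         list(v = colMeans(x), p = 0.5),
         list(v = x[2, ], p = 0.25))
  }
  oa <- outcomes(vals$A); ob <- outcomes(vals$B); oc <- outcomes(vals$C)
  expected <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    co <- rbind(oa[[i]]$v, ob[[j]]$v, oc[[k]]$v)
    co <- apply(co, 2, function(v) {
      s <- sd(v); if (s == 0) rep(0, 3) else (v - mean(v)) / s
    })
    expected <- expected + oa[[i]]$p * ob[[j]]$p * oc[[k]]$p *
      as.matrix(dist(co))
  }
  ds <- community_dataset(data.frame(
    taxon_id = rep(c("A", "B", "C"), each = 2), taxon_name = "t",
    tax_class = "Decapoda",
    d13C = c(vals$A[, 1], vals$B[, 1], vals$C[, 1]),
    d15N = c(vals$A[, 2], vals$B[, 2], vals$C[, 2]),
    pctC = NA, pctN = NA, stringsAsFactors = FALSE))
  ens <- bootstrap_distances(ds, m = 2, B = 1e4, seed = 4)
  off <- upper.tri(expected)
  expect_lt(max(abs(ens$avg_matrix[off] - expected[off]) / expected[off]), 0.02)
})

test_that("UPGMA reproduces a hand-agglomerated 4-taxon tree", {
  # d(A,B)=2 merges first; d(C,D)=4 next; average cross distance
  # (6+10+5+9)/4 = 7.5 joins the two pairs.
  m <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m["A", "B"] <- m["B", "A"] <- 2
  m["A", "C"] <- m["C", "A"] <- 6
  m["A", "D"] <- m["D", "A"] <- 10
  m["B", "C"] <- m["C", "B"] <- 5
  m["B", "D"] <- m["D", "B"] <- 9
  m["C", "D"] <- m["D", "C"] <- 4
  tree <- upgma(m)
  expect_equal(tree$height, c(2, 4, 7.5))
  expect_equal(tree$merge, rbind(c(-1, -2), c(-3, -4), c(1, 2)))
  expect_false(is.unsorted(tree$height))

  two <- matrix(c(0, 3.2, 3.2, 0), 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  t2 <- upgma(two)
  expect_equal(t2$height, 3.2)
})

test_that("cluster selection cuts and the fusion-level heuristic behave", {
  sim <- simulate_community(default_community_config(n_taxa = 8), seed = 7)
  ens <- bootstrap_distances(sim$dataset, m = 4, B = 50, seed = 7)
  tree <- upgma(ens)
  n <- length(tree$labels)

  singletons <- select_clusters(tree, k = n)
  expect_equal(singletons$k, n)
  expect_equal(length(unique(singletons$assignments)), n)

  lump <- select_clusters(tree, k = 1)
  expect_equal(unname(unique(lump$assignments)), 1L)

  expect_error(select_clusters(tree, k = n + 1), "k must be")

  # two tight clumps far apart: the fusion-level heuristic must find k = 2
  clump <- community_dataset(data.frame(
    taxon_id = rep(paste0("T", 1:6), each = 4), taxon_name = "t",
    tax_class = "Decapoda",
    d13C = rep(c(-19, -19.1, -18.9, -14, -14.1, -13.9), each = 4),
    d15N = rep(c(10, 10.1, 9.9, 15, 15.1, 14.9), each = 4),
    pctC = NA, pctN = NA, stringsAsFactors = FALSE))
  part <- select_clusters(upgma(bootstrap_distances(clump, B = 50, seed = 1)), "auto")
  expect_equal(part$k, 2L)
  expect_length(guild_of(part, "T1"), 3)
  expect_setequal(guild_of(part, "T4"), c("T4", "T5", "T6"))
})

test_that("more replicates stabilize the averaged entries", {
  sim <- simulate_community(default_community_config(n_taxa = 4), seed = 11)
  entry <- function(B, seed) {
    bootstrap_distances(sim$dataset, m = 4, B = B, seed = seed)$avg_matrix[1, 2]
  }
  v_small <- var(vapply(1:12, function(s) entry(10, s), numeric(1)))
  v_large <- var(vapply(1:12, function(s) entry(500, s), numeric(1)))
  expect_lt(v_large, v_small)
})

test_that("trees export as parseable Newick text", {
  sim <- simulate_community(default_community_config(n_taxa = 5), seed = 2)
  tree <- upgma(bootstrap_distances(sim$dataset, B = 20, seed = 2))
  nwk <- tree_newick(tree)
  expect_match(nwk, ";$")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, tree$labels)
})
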
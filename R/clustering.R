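#' Bootstrap-averaged distance matrix between taxa
#'
#' Sample sizes differ among taxa, which biases within-taxon isotopic
#' variation; bootstrapping to a common resample size removes that bias.
#' Per replicate: `m` individuals are resampled with replacement from every
#' taxon, each taxon's coordinate is the mean d13C and mean d15N of its
#' resample, coordinates are standardized across taxa to mean 0 and unit
#' variance (z-scored within the replicate, so each replicate is a complete
#' re-realization of the procedure), and pairwise Euclidean distances are
#' computed. The `B` replicate matrices are averaged element-wise.
#'
#' @param dataset a [community_dataset()]; every taxon needs n >= 1.
#' @param m per-taxon resample size (default 4, a typical minimum n).
#' @param B number of replicates (default 500, enough to stabilize the
#'   averaged entries).
#' @param seed integer seed.
#' @return object of class `distance_ensemble`: `avg_matrix` (symmetric,
#'   zero diagonal, taxa in first-appearance order), `taxa`, `B`, `m`,
#'   `seed`.
#' @export
bootstrap_distances <- function(dataset, m = 4, B = 500, seed = 1) {
  stopifnot(inherits(dataset, "community_dataset"))
  if (B < 1 || m < 1) stop("B and m must be >= 1", call. = FALSE)
  taxa <- unique(dataset$taxon_id)
  vals <- lapply(taxa, function(id) {
    rows <- dataset[dataset$taxon_id == id, ]
    cbind(rows$d13C, rows$d15N)
  })
  names(vals) <- taxa
  set.seed(derive_seed(seed, "bootdist"))
  acc <- matrix(0, length(taxa), length(taxa))
  for (b in seq_len(B)) {
    coords <- t(vapply(vals, function(x) {
      idx <- sample.int(nrow(x), m, replace = TRUE)
      colMeans(x[idx, , drop = FALSE])
    }, numeric(2)))
    coords <- apply(coords, 2, function(v) {
      s <- stats::sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
    acc <- acc + as.matrix(stats::dist(coords))
  }
  avg <- acc / B
  dimnames(avg) <- list(taxa, taxa)
  structure(list(avg_matrix = avg, taxa = taxa, B = B, m = m, seed = seed),
            class = "distance_ensemble")
}

#' UPGMA agglomeration of a distance ensemble
#'
#' Unweighted pair group method with arithmetic mean: at each step the two
#' clusters with the smallest average cross-pair distance are merged, the
#' inter-cluster distance being the unweighted mean over all member pairs
#' of the original dissimilarities. Implemented via average-linkage
#' [stats::hclust()], which is exactly UPGMA and deterministic.
#'
#' @param ensemble a `distance_ensemble` or a symmetric dissimilarity
#'   matrix with taxon dimnames.
#' @return an [stats::hclust] merge tree (heights non-decreasing).
#' @export
upgma <- function(ensemble) {
  m <- if (inherits(ensemble, "distance_ensemble")) ensemble$avg_matrix else ensemble
  stopifnot(is.matrix(m), isSymmetric(unname(m), tol = 1e-12))
  stats::hclust(stats::as.dist(m), method = "average")
}

#' Cut a merge tree into trophic guilds
#'
#' Numeric `k` cuts the dendrogram into `k` guilds. `k = "auto"` applies a
#' fusion-level heuristic: the cut is placed at the largest relative jump
#' between successive merge heights (`(h[j+1] - h[j]) / h[j]`), and the
#' full height profile is returned for visual inspection -- the heuristic
#' is an aid, not a substitute for looking at the dendrogram.
#'
#' @param merge_tree an [stats::hclust] tree from [upgma()].
#' @param k number of guilds, or `"auto"`.
#' @return object of class `guild_partition`: `assignments` (named integer
#'   vector taxon -> guild), `k`, `merge_tree`, `heights`, and for auto
#'   cuts `relative_jumps`.
#' @export
select_clusters <- function(merge_tree, k = "auto") {
  stopifnot(inherits(merge_tree, "hclust"))
  n <- length(merge_tree$labels)
  h <- merge_tree$height
  jumps <- NULL
  if (identical(k, "auto")) {
    # j-th merge leaves n - j clusters; a big jump after merge j argues
    # for cutting there.
    jumps <- diff(h) / pmax(h[-length(h)], .Machine$double.eps)
    k <- n - which.max(jumps)
  }
  if (!is.numeric(k) || k < 1 || k > n) {
    stop("k must be in 1..", n, " or \"auto\"", call. = FALSE)
  }
  assignments <- stats::cutree(merge_tree, k = k)
  structure(list(assignments = assignments, k = as.integer(k),
                 merge_tree = merge_tree, heights = h,
                 relative_jumps = jumps),
            class = "guild_partition")
}

#' Members of the guild containing a given taxon
#'
#' @param partition a `guild_partition`.
#' @param taxon_id taxon whose guild to extract.
#' @return character vector of member taxon_ids (sorted).
#' @export
guild_of <- function(partition, taxon_id) {
  stopifnot(inherits(partition, "guild_partition"))
  a <- partition$assignments
  if (!taxon_id %in% names(a)) stop("unknown taxon: ", taxon_id, call. = FALSE)
  sort(names(a)[a == a[[taxon_id]]])
}

#' Export a merge tree as Newick text
#'
#' @param merge_tree an [stats::hclust] tree.
#' @return single Newick string with branch lengths derived from merge
#'   heights.
#' @export
tree_newick <- function(merge_tree) {
  ape::write.tree(ape::as.phylo(merge_tree))
}
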
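#' Pairwise mean-FST distance matrix across pools
#'
#' For every pair of pools, per-site Karlsson FST is computed over the sites
#' informative for that pair (segregating and not fixed in the two pools
#' being compared; site sets may differ between pairs) and averaged. Small
#' negative pair means, which the unbiased estimator produces for
#' near-identical pools, are truncated to 0 here only — distances must be
#' non-negative — while per-site and per-window statistics stay untruncated.
#'
#' @param table a [variant_table()] with at least two pools.
#' @param rule segregation rule, see [site_is_informative()].
#' @return symmetric numeric matrix with zero diagonal, dimnames = pool ids.
#' @export
pairwise_fst_matrix <- function(table, rule = c("combined", "within")) {
  rule <- match.arg(rule)
  pools <- pool_ids(table)
  if (length(pools) < 2) stop("need at least two pools")
  m <- matrix(0, length(pools), length(pools), dimnames = list(pools, pools))
  for (i in seq_len(length(pools) - 1)) {
    for (j in seq(i + 1, length(pools))) {
      sf <- site_fst_table(table, pools[i], pools[j], rule = rule)
      vals <- sf$fst[sf$informative]
      if (!length(vals))
        stop("no informative sites for pair ", pools[i], " / ", pools[j])
      m[i, j] <- m[j, i] <- max(0, mean(vals))
    }
  }
  m
}

#' Hierarchical clustering of pools from an FST distance matrix
#'
#' Agglomerative clustering of the pairwise-FST matrix; average linkage
#' (UPGMA) by default, as conventional for breed trees built from distance
#' matrices. Hard clusters are obtained by cutting the dendrogram into `k`
#' groups.
#'
#' @param d symmetric distance matrix (e.g. from [pairwise_fst_matrix()]).
#' @param k optional number of hard clusters to cut.
#' @param method linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @return list with `hclust` (the tree), `clusters` (named integer vector,
#'   `NULL` unless `k` given) and `newick` (the tree in Newick format).
#' @export
fst_hclust <- function(d, k = NULL, method = "average") {
  d <- as.matrix(d)
  if (nrow(d) < 2) stop("need at least two pools to cluster")
  hc <- stats::hclust(stats::as.dist(d), method = method)
  clusters <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, clusters = clusters, newick = newick)
}

#' Principal-coordinates analysis of an FST distance matrix
#'
#' Classical metric multidimensional scaling (Torgerson): the squared
#' distance matrix is double-centred and eigendecomposed; the fraction of
#' variance attributed to each axis is its eigenvalue divided by the sum of
#' positive eigenvalues. This is the natural "PCA" for a distance matrix,
#' where no per-sample feature matrix exists.
#'
#' @param d symmetric distance matrix.
#' @param k number of axes to return (default all with positive eigenvalue).
#' @return list with `coordinates` (pools x axes), `eigenvalues`, and
#'   `variance_fraction` (per returned axis, relative to the positive
#'   spectrum).
#' @export
principal_coordinates <- function(d, k = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least two pools")
  if (all(d == 0)) stop("all distances are zero; ordination undefined")
  mds <- stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE)
  eig <- mds$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  n_axes <- if (is.null(k)) sum(pos) else min(k, sum(pos))
  coords <- mds$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(n_axes))
  list(coordinates = coords,
       eigenvalues = eig[seq_len(n_axes)],
       variance_fraction = eig[seq_len(n_axes)] / sum(eig[pos]))
}
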
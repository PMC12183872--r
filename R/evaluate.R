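#' Adjusted Rand index between two labelings
#'
#' Pair-counting agreement corrected for chance under the permutation model;
#' 1 for identical partitions, ~0 for independent ones. Computed with
#' `mclust::adjustedRandIndex`.
#'
#' @param pred,truth label vectors of equal length (`>= 2`).
#' @return scalar in `[-1, 1]`.
#' @export
ari <- function(pred, truth) {
  check_labels(pred, truth)
  mclust::adjustedRandIndex(pred, truth)
}

#' Normalized mutual information between two labelings
#'
#' Mutual information of the two label distributions divided by the
#' arithmetic mean of their entropies (the most common normalization); 1 for
#' identical partitions up to renaming, 0 for independence. When both
#' partitions are single-cluster (zero entropy) the agreement is perfect and
#' 1 is returned.
#'
#' @param pred,truth label vectors of equal length.
#' @return scalar in `[0, 1]`.
#' @export
nmi <- function(pred, truth) {
  check_labels(pred, truth)
  n <- length(pred)
  tab <- table(pred, truth)
  p_ij <- tab / n
  p_i <- rowSums(p_ij)
  p_j <- colSums(p_ij)
  mi <- sum(ifelse(p_ij > 0, p_ij * log(p_ij / outer(p_i, p_j)), 0))
  h <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  denom <- (h(p_i) + h(p_j)) / 2
  if (denom == 0) return(1)
  max(0, min(1, mi / denom))
}

check_labels <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop(sprintf("label length mismatch: %d vs %d", length(pred), length(truth)))
  if (length(pred) < 2L) stop("need at least 2 observations")
  invisible(NULL)
}

#' Mean silhouette coefficient of a clustering
#'
#' Euclidean silhouette averaged over all points (via `cluster::silhouette`);
#' near 1 for compact well-separated clusters, near 0 for overlapping ones.
#'
#' @param Z m x d numeric matrix.
#' @param labels cluster labels with `>= 2` distinct values.
#' @return scalar in `[-1, 1]`.
#' @export
silhouette_score <- function(Z, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L) stop("silhouette needs >= 2 clusters")
  sil <- cluster::silhouette(labels, stats::dist(Z))
  mean(sil[, "sil_width"])
}

#' Calinski-Harabasz index of a clustering
#'
#' Ratio of between-cluster to within-cluster dispersion,
#' `(B / (K - 1)) / (W / (m - K))`; larger is better.
#'
#' @param Z m x d numeric matrix.
#' @param labels cluster labels with `>= 2` distinct values, `K < m`.
#' @return nonnegative scalar.
#' @export
calinski_harabasz <- function(Z, labels) {
  Z <- as.matrix(Z)
  labels <- as.integer(factor(labels))
  K <- length(unique(labels))
  m <- nrow(Z)
  if (K < 2L) stop("Calinski-Harabasz needs >= 2 clusters")
  if (K >= m) stop("need K < m")
  mu <- colMeans(Z)
  B <- 0; W <- 0
  for (k in seq_len(K)) {
    Zk <- Z[labels == k, , drop = FALSE]
    muk <- colMeans(Zk)
    B <- B + nrow(Zk) * sum((muk - mu)^2)
    W <- W + sum(sweep(Zk, 2, muk)^2)
  }
  (B / (K - 1)) / (W / (m - K))
}

#' Label smoothness over a spatial graph
#'
#' Fraction of directed edges of the graph whose two endpoints carry the same
#' label; 1 when every neighborhood is label-pure, 0 when no neighboring pair
#' agrees. Measures how spatially coherent a labeling is.
#'
#' @param labels label vector.
#' @param spatial_graph m x m (sparse) adjacency over the same spots; any
#'   nonzero entry counts as an edge.
#' @return scalar in `[0, 1]`.
#' @export
label_smoothness <- function(labels, spatial_graph) {
  A <- methods::as(methods::as(Matrix::Matrix(spatial_graph, sparse = TRUE),
                               "generalMatrix"), "TsparseMatrix")
  keep <- A@x != 0
  i <- A@i[keep] + 1L
  j <- A@j[keep] + 1L
  if (!length(i)) stop("graph has no edges")
  mean(labels[i] == labels[j])
}

#' Shannon entropy of the label distribution
#'
#' Natural-log entropy of label proportions: 0 for a single label, `log K`
#' for K equally frequent labels. Measures label diversity, not spatial
#' arrangement.
#'
#' @param labels label vector.
#' @return nonnegative scalar.
#' @export
label_entropy <- function(labels) {
  p <- as.vector(table(labels)) / length(labels)
  -sum(ifelse(p > 0, p * log(p), 0))
}

#' Compute the full metric report for a run
#'
#' External metrics (ARI, NMI) are computed against the supplied truth;
#' internal metrics (silhouette, Calinski-Harabasz) on the embeddings;
#' LS/LE on the labels. Multi-slice inputs are pooled, with per-slice ARI
#' breakdowns attached when a slice index is given.
#'
#' @param Z embeddings. @param labels predicted labels.
#' @param truth optional ground-truth labels.
#' @param spatial_graph optional adjacency for label smoothness.
#' @param slice_index optional per-spot slice index for per-slice ARI.
#' @return A `"metric_report"` list.
#' @export
metric_report <- function(Z, labels, truth = NULL, spatial_graph = NULL,
                          slice_index = NULL) {
  rep <- list(
    silhouette = silhouette_score(Z, labels),
    calinski_harabasz = calinski_harabasz(Z, labels),
    label_entropy = label_entropy(labels)
  )
  if (!is.null(truth)) {
    rep$ari <- ari(labels, truth)
    rep$nmi <- nmi(labels, truth)
    if (!is.null(slice_index)) {
      rep$ari_per_slice <- vapply(sort(unique(slice_index)), function(l) {
        sel <- slice_index == l
        ari(labels[sel], truth[sel])
      }, numeric(1))
    }
  }
  if (!is.null(spatial_graph))
    rep$label_smoothness <- label_smoothness(labels, spatial_graph)
  structure(rep, class = "metric_report")
}
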
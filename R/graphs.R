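#' K-nearest-neighbor graph from spot coordinates
#'
#' Directed binary adjacency: `a_ij = 1` iff `j` is among the `K` Euclidean
#' nearest neighbors of `i` (`j != i`). Each row has exactly `K` ones;
#' distance ties are broken toward the lower spot index for determinism. The
#' matrix is deliberately not symmetrized.
#'
#' @param coords m x 2 coordinate matrix.
#' @param K neighbors per spot, `1 <= K < m`.
#' @return sparse binary `dgCMatrix` (m x m).
#' @export
knn_spatial <- function(coords, K) {
  coords <- as.matrix(coords)
  m <- nrow(coords)
  if (K < 1L || K >= m) stop(sprintf("need 1 <= K < m; got K = %d, m = %d", K, m))
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  D <- as.matrix(stats::dist(coords))
  knn_from_score(-D, K)
}

#' K-nearest-neighbor graph from expression features
#'
#' Same contract as [knn_spatial()] but neighbors are the `K` spots with the
#' highest Pearson correlation to each spot's feature row.
#'
#' @param X m x n feature matrix (one row per spot, e.g. PC scores).
#' @param K neighbors per spot.
#' @return sparse binary `dgCMatrix` (m x m).
#' @export
knn_expression <- function(X, K) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (K < 1L || K >= m) stop(sprintf("need 1 <= K < m; got K = %d, m = %d", K, m))
  rv <- apply(X, 1, stats::var)
  if (any(rv == 0))
    stop("constant feature row(s): ", paste(which(rv == 0), collapse = ", "),
         " (Pearson correlation undefined)")
  C <- stats::cor(t(X))
  knn_from_score(C, K)
}

# top-K per row of a similarity score matrix, ties to the lower column index
knn_from_score <- function(S, K) {
  m <- nrow(S)
  diag(S) <- -Inf
  js <- integer(m * K)
  for (i in seq_len(m)) {
    ord <- order(-S[i, ], seq_len(m))[seq_len(K)]
    js[((i - 1L) * K + 1L):(i * K)] <- ord
  }
  Matrix::sparseMatrix(i = rep(seq_len(m), each = K), j = js, x = 1,
                       dims = c(m, m))
}

#' Blend an adjacency matrix with self-connections
#'
#' `A_hat = lambda * I + (1 - lambda) * A`.
#'
#' @param A square (sparse) adjacency matrix.
#' @param lambda_self self-connection weight in `[0, 1]`.
#' @return sparse matrix of the same dimension.
#' @export
hybridize <- function(A, lambda_self) {
  if (lambda_self < 0 || lambda_self > 1) stop("lambda_self must be in [0, 1]")
  if (nrow(A) != ncol(A)) stop("A must be square")
  m <- nrow(A)
  methods::as(lambda_self * Matrix::Diagonal(m) + (1 - lambda_self) * A,
              "CsparseMatrix")
}

#' Symmetric degree normalization of an adjacency matrix
#'
#' `A_tilde = D^{-1/2} A_hat D^{-1/2}` with `d_ii` the row sum of `A_hat`.
#' Row sums must all be positive (guaranteed when the self-connection weight
#' is positive).
#'
#' @param A_hat square nonnegative (sparse) matrix.
#' @return sparse normalized operator.
#' @export
normalize_sym <- function(A_hat) {
  d <- Matrix::rowSums(A_hat)
  if (any(d <= 0)) stop("zero-degree node(s): ", paste(which(d <= 0), collapse = ", "))
  s <- 1 / sqrt(d)
  methods::as(Matrix::Diagonal(x = s) %*% A_hat %*% Matrix::Diagonal(x = s),
              "CsparseMatrix")
}

#' Assemble per-slice operators into a block-diagonal multi-slice operator
#'
#' Cross-slice entries are exactly zero, so no information flows between
#' slices through the graph.
#'
#' @param graph_list list of per-slice (normalized) operators.
#' @return sparse block-diagonal matrix.
#' @export
block_diagonal <- function(graph_list) {
  if (!length(graph_list)) stop("empty graph list")
  if (length(graph_list) == 1L)
    return(methods::as(graph_list[[1]], "CsparseMatrix"))
  methods::as(Matrix::bdiag(graph_list), "CsparseMatrix")
}

#' Build the two-view multi-slice graph pair
#'
#' For each slice, builds the spatial KNN graph from coordinates and the
#' expression KNN graph from the PC features restricted to that slice, blends
#' each with self-connections, normalizes by node degree, and stacks the
#' per-slice operators block-diagonally. Graphs are built once from the
#' uncorrected features and held fixed during training.
#'
#' @param features a `"feature_matrix"` from [preprocess_slices()].
#' @param cfg a `"spview_config"`.
#' @return A `"multiview_graph"` list: `A_spa_norm`, `A_expr_norm` (sparse
#'   m x m operators) plus the `k_spatial`, `k_expr`, `lambda_self` used.
#' @export
build_multiview_graph <- function(features, cfg = spview_config()) {
  idx <- features$spot_slice_index
  per_slice <- function(build) {
    ops <- lapply(seq_along(features$m_per_slice), function(l) {
      sel <- idx == l
      normalize_sym(hybridize(build(sel), cfg$lambda_self))
    })
    block_diagonal(ops)
  }
  A_spa <- per_slice(function(sel)
    knn_spatial(features$coords[sel, , drop = FALSE], cfg$k_spatial))
  A_expr <- per_slice(function(sel)
    knn_expression(features$X[sel, , drop = FALSE], cfg$k_expr))
  structure(list(A_spa_norm = A_spa, A_expr_norm = A_expr,
                 k_spatial = cfg$k_spatial, k_expr = cfg$k_expr,
                 lambda_self = cfg$lambda_self),
            class = "multiview_graph")
}
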
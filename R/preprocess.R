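#' Drop genes with zero total count across all slices
#'
#' A gene is kept if it is expressed in at least one spot of at least one
#' slice, so multi-slice sets share a common filtered gene index.
#'
#' @param counts_list list of count matrices with identical gene columns.
#' @return list with `counts` (filtered matrices) and `kept` (indices of the
#'   retained gene columns).
#' @export
filter_genes <- function(counts_list) {
  if (!length(counts_list)) stop("need at least one slice")
  n0 <- ncol(counts_list[[1]])
  if (!all(vapply(counts_list, ncol, 1L) == n0))
    stop("slices disagree on the number of genes")
  totals <- Reduce(`+`, lapply(counts_list, colSums))
  kept <- which(totals > 0)
  if (!length(kept)) stop("no expressed genes: every gene has zero total count")
  list(counts = lapply(counts_list, function(m) m[, kept, drop = FALSE]),
       kept = kept)
}

#' Library-size normalize and log-transform counts
#'
#' Each spot's counts are scaled to a library size of 10^4 and mapped through
#' `log1p` (natural log): `y_hat = log(1e4 * y / libsize + 1)`. Zeros stay
#' zero and the result is invariant to rescaling a spot's whole row.
#'
#' @param Y nonnegative count matrix (spots x genes).
#' @return matrix of the same shape.
#' @export
normalize_log <- function(Y) {
  lib <- rowSums(Y)
  zero <- which(lib <= 0)
  if (length(zero))
    stop("spot(s) with zero library size: ", paste(zero, collapse = ", "))
  log1p(1e4 * Y / lib)
}

#' Z-score genes across spots
#'
#' Centers each gene at its mean and divides by its sample standard deviation
#' (denominator `m - 1`). Genes with zero variance are set to all-zero with a
#' warning: the z-score is undefined there and a constant gene carries no
#' signal, while dropping it would shift gene indices.
#'
#' @param Y_hat normalized log-expression matrix, `m >= 2` rows.
#' @return standardized matrix, columns with positive variance have mean 0
#'   and sample sd 1.
#' @export
standardize <- function(Y_hat) {
  if (nrow(Y_hat) < 2L) stop("standardization needs at least 2 spots")
  mu <- colMeans(Y_hat)
  sd <- apply(Y_hat, 2, stats::sd)
  flat <- sd == 0
  if (any(flat)) {
    warning(sprintf("%d constant gene(s) set to zero after standardization",
                    sum(flat)))
    sd[flat] <- 1
  }
  out <- sweep(sweep(Y_hat, 2, mu, "-"), 2, sd, "/")
  out[, flat] <- 0
  out
}

#' Project standardized expression onto leading principal components
#'
#' Exact (SVD-based) PCA; no randomized approximation, so results are
#' deterministic. Component signs are fixed by making the largest-magnitude
#' loading of each component positive.
#'
#' @param Y_tilde standardized matrix (spots x genes).
#' @param n number of components, `n <= min(m - 1, n_genes)`.
#' @return matrix of PC scores (spots x n).
#' @export
pca_reduce <- function(Y_tilde, n) {
  bound <- min(nrow(Y_tilde) - 1L, ncol(Y_tilde))
  if (n > bound)
    stop(sprintf("n = %d exceeds min(m - 1, n_genes) = %d", n, bound))
  pc <- stats::prcomp(Y_tilde, center = FALSE, scale. = FALSE, rank. = n)
  rot <- pc$rotation
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

#' Full preprocessing of one or more slices
#'
#' Applies gene filtering (union of expression over all slices), per-spot
#' library-size normalization with log transform, pooled gene z-scoring, and
#' PCA on the row-concatenated matrix. Normalization statistics are pooled
#' over the concatenated spots, so preprocessing several slices equals
#' preprocessing their concatenation.
#'
#' @param slices a `"raw_slice"` or list of them.
#' @param n_pcs number of principal components to keep.
#' @return A `"feature_matrix"` list: `X` (m x n_pcs PC scores),
#'   `spot_slice_index` (1-based slice index per spot), `m_per_slice`,
#'   `slice_ids`, `coords` (row-bound spot coordinates), `spot_ids`, `kept_genes`.
#' @export
preprocess_slices <- function(slices, n_pcs = 30L) {
  if (inherits(slices, "raw_slice")) slices <- list(slices)
  stopifnot(length(slices) >= 1L)
  filt <- filter_genes(lapply(slices, `[[`, "counts"))
  Y <- do.call(rbind, filt$counts)
  Y_tilde <- standardize(normalize_log(Y))
  X <- pca_reduce(Y_tilde, n_pcs)
  m_per_slice <- vapply(slices, function(s) nrow(s$counts), 1L)
  structure(list(
    X = X,
    spot_slice_index = rep(seq_along(slices), m_per_slice),
    m_per_slice = m_per_slice,
    slice_ids = vapply(slices, `[[`, "", "slice_id"),
    coords = do.call(rbind, lapply(slices, `[[`, "coords")),
    spot_ids = unlist(lapply(slices, function(s) rownames(s$counts)),
                      use.names = FALSE),
    kept_genes = filt$kept
  ), class = "feature_matrix")
}
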
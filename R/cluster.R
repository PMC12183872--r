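#' Gaussian-mixture clustering of spot embeddings
#'
#' Fits a K-component Gaussian mixture to the embeddings with `mclust` (EM
#' with model-based hierarchical initialization, shared full-covariance model
#' "EEE" by default) and assigns every spot to its maximum-posterior
#' component. If EM fails under the requested covariance model, a diagonal
#' model is retried before erroring.
#'
#' @param Z m x d embedding matrix, finite.
#' @param K number of domains, `2 <= K < m`.
#' @param seed integer seed (recorded; the fit itself is deterministic).
#' @param model_names mclust covariance model(s) to try, in order.
#' @return A `"domain_partition"` list: `labels` (integers `1..K`), `K`,
#'   `seed`.
#' @export
gmm_cluster <- function(Z, K, seed = 0L, model_names = c("EEE", "VII")) {
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stop("non-finite embeddings")
  if (K < 2L || K >= nrow(Z))
    stop(sprintf("need 2 <= K < m; got K = %d, m = %d", K, nrow(Z)))
  set.seed(seed)
  fitted <- NULL
  for (mn in model_names) {
    fitted <- tryCatch(
      suppressWarnings(mclust::Mclust(Z, G = K, modelNames = mn,
                                      verbose = FALSE)),
      error = function(e) NULL)
    if (!is.null(fitted) && !is.null(fitted$classification)) break
    fitted <- NULL
  }
  if (is.null(fitted))
    stop("Gaussian-mixture EM failed for all covariance models tried")
  structure(list(labels = as.integer(fitted$classification), K = as.integer(K),
                 seed = as.integer(seed)),
            class = "domain_partition")
}

#' Spatial majority-vote refinement of domain labels
#'
#' One synchronous pass: each spot inspects its `radius_k` spatial nearest
#' neighbors within the same slice; if a strict majority of them carries one
#' label different from the spot's own, the spot adopts it. Ties and bare
#' pluralities leave the label unchanged, so the pass can only smooth,
#' never oscillate.
#'
#' @param labels integer labels, one per spot.
#' @param coords m x 2 coordinates.
#' @param slice_index 1-based slice id per spot (refinement never crosses
#'   slices); default all one slice.
#' @param radius_k number of neighbors consulted.
#' @return refined integer label vector.
#' @export
refine <- function(labels, coords, slice_index = NULL, radius_k = 6L) {
  m <- length(labels)
  if (is.null(slice_index)) slice_index <- rep(1L, m)
  stopifnot(nrow(coords) == m, radius_k >= 1L)
  out <- labels
  for (l in unique(slice_index)) {
    sel <- which(slice_index == l)
    if (length(sel) < 2L) next
    k <- min(radius_k, length(sel) - 1L)
    D <- as.matrix(stats::dist(coords[sel, , drop = FALSE]))
    diag(D) <- Inf
    for (s in seq_along(sel)) {
      nb <- order(D[s, ], seq_along(sel))[seq_len(k)]
      votes <- table(labels[sel[nb]])
      top <- names(votes)[which.max(votes)]
      if (as.integer(top) != labels[sel[s]] && votes[[top]] > k / 2)
        out[sel[s]] <- as.integer(top)
    }
  }
  out
}

#' End-to-end spatial domain identification
#'
#' Convenience wrapper: preprocess, build graphs, train, extract embeddings,
#' cluster, refine.
#'
#' @param slices a `"raw_slice"` or list of them.
#' @param cfg a `"spview_config"`.
#' @param ablation ablation mode passed to [fit()].
#' @param verbose print training progress.
#' @return list with `labels`, `embeddings`, `partition`, `fitted`,
#'   `features`.
#' @export
spview_run <- function(slices, cfg = spview_config(), ablation = "full",
                       verbose = FALSE) {
  features <- preprocess_slices(slices, cfg$n_pcs)
  graph <- build_multiview_graph(features, cfg)
  fitted <- fit(features, graph, cfg, ablation = ablation, verbose = verbose)
  Z <- extract_embeddings(fitted)
  part <- gmm_cluster(Z, cfg$n_domains, seed = cfg$seed)
  labels <- part$labels
  if (cfg$refine)
    labels <- refine(labels, features$coords, features$spot_slice_index,
                     cfg$refinement_radius)
  list(labels = labels, embeddings = Z, partition = part, fitted = fitted,
       features = features)
}
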
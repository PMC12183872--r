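# shared fixture builders: tiny random instances used across test files

tiny_instance <- function(seed = 42, m = 7, n = 5, L = 2) {
  set.seed(seed)
  cfg <- spview_config(n_pcs = n, d1 = 4, d = 3, d2 = 4, d3 = 3, f = 3,
                       n_pseudo = 3, k_spatial = 2, k_expr = 2,
                       noise_alpha = 0, mask_p = 1, edge_keep_p = 1,
                       n_domains = 3)
  X <- matrix(rnorm(m * n), m, n)
  coords <- matrix(runif(m * 2), m, 2)
  idx <- sort(rep_len(seq_len(L), m))
  graph <- list(
    A_spa_norm = normalize_sym(hybridize(knn_spatial(coords, 2), 0.3)),
    A_expr_norm = normalize_sym(hybridize(knn_expression(X, 2), 0.3)))
  E <- batch_design(idx, L)
  state <- init_model(n, L, cfg)
  list(cfg = cfg, X = X, coords = coords, idx = idx, graph = graph, E = E,
       state = state, m = m, n = n, L = L)
}

rand_simplex_rows <- function(m, k) {
  Q <- matrix(stats::rexp(m * k), m, k)
  Q / rowSums(Q)
}

small_synth <- function(seed = 1, rows = 10, cols = 8, domains = 2,
                        genes = 40, slices = 1, shift = 0) {
  synth_generate(synth_spec(grid_shape = c(rows, cols), n_domains = domains,
                            n_genes = genes, n_markers_per_domain = 5,
                            signal_strength = 1.5, batch_shift_sd = shift,
                            n_slices = slices, seed = seed))
}
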
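# Activations. ELU uses alpha = 1; its derivative is recovered from the
# activation value itself (exp(v) = elu(v) + 1 for v <= 0), so pre-activations
# need not be cached.
elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
elu_prime_from_out <- function(z) ifelse(z > 0, 1, z + 1)
relu <- function(x) pmax(x, 0)

row_softmax <- function(G) {
  E <- exp(G - apply(G, 1, max))
  E / rowSums(E)
}

#' Initialize model parameters
#'
#' All weight matrices are Glorot-uniform; the two batch prompt embedding
#' matrices start at zero so training begins from the uncorrected model.
#'
#' @param n input feature dimension (number of PCs).
#' @param L number of slices (batches).
#' @param cfg a `"spview_config"` supplying the layer widths.
#' @return A `"model_state"` list of parameter matrices `W11, W12, W21, W22,
#'   W31, W32, W41, W42, B1, B2`. The decoder reuses `t(W12)` and `t(W11)`
#'   (tied weights), so it has no parameters of its own.
#' @export
init_model <- function(n, L, cfg = spview_config()) {
  glorot <- function(r, c) {
    lim <- sqrt(6 / (r + c))
    matrix(stats::runif(r * c, -lim, lim), r, c)
  }
  state <- list(
    W11 = glorot(n, cfg$d1),
    W12 = glorot(cfg$d1, cfg$d),
    W21 = glorot(cfg$d, cfg$d2),
    W22 = glorot(cfg$d2, cfg$f),
    W31 = glorot(cfg$d, cfg$d2),
    W32 = glorot(cfg$d2, cfg$n_pseudo),
    W41 = glorot(cfg$d, cfg$d3),
    W42 = glorot(cfg$d3, 1L),
    B1 = matrix(0, L, n),
    B2 = matrix(0, L, cfg$d)
  )
  class(state) <- "model_state"
  state
}

#' Build the one-hot batch indicator matrix
#'
#' @param spot_slice_index 1-based slice index per spot.
#' @param L number of slices.
#' @return m x L binary matrix with exactly one 1 per row.
#' @export
batch_design <- function(spot_slice_index, L = max(spot_slice_index)) {
  m <- length(spot_slice_index)
  if (any(spot_slice_index < 1L | spot_slice_index > L))
    stop("slice indices must lie in 1..L")
  E <- matrix(0, m, L)
  E[cbind(seq_len(m), spot_slice_index)] <- 1
  E
}

#' Subtract per-slice prompt embeddings from the input features
#'
#' `X_b = X - E %*% B1`: each spot's feature row is shifted by the learnable
#' prompt vector of its slice, which absorbs additive batch effects before
#' encoding.
#'
#' @param X m x n feature matrix.
#' @param B1 L x n prompt embedding matrix.
#' @param E m x L one-hot batch indicator.
#' @return corrected m x n matrix.
#' @export
apply_batch_correction <- function(X, B1, E) {
  check_one_hot(E)
  X - E %*% B1
}

#' Re-add per-slice prompt embeddings to the latent representations
#'
#' `Z_b = Z + E %*% B2`, performed just before decoding so the reconstruction
#' target can retain its batch character while `Z` stays batch-free.
#'
#' @param Z m x d fused embedding matrix.
#' @param B2 L x d prompt embedding matrix.
#' @param E m x L one-hot batch indicator.
#' @return m x d matrix.
#' @export
restore_batch <- function(Z, B2, E) {
  check_one_hot(E)
  Z + E %*% B2
}

check_one_hot <- function(E) {
  if (any(E != 0 & E != 1) || any(rowSums(E) != 1))
    stop("batch indicator rows must be one-hot")
  invisible(E)
}

#' Two-layer GCN encoder for one view
#'
#' `Z = ELU( C2 %*% ELU( C1 %*% X %*% W11 ) %*% W12 )` where `C1`, `C2` are
#' (possibly edge-masked) normalized graph operators — the corruption is
#' drawn independently per layer.
#'
#' @param C1,C2 m x m sparse operators (the corrupted graph per layer).
#' @param X m x n feature matrix.
#' @param W11,W12 encoder weights (n x d1, d1 x d).
#' @return m x d embedding matrix.
#' @export
encode <- function(C1, C2, X, W11, W12) {
  if (ncol(X) != nrow(W11)) stop("feature/weight shape mismatch")
  P <- elu(as.matrix(C1 %*% X) %*% W11)
  elu(as.matrix(C2 %*% P) %*% W12)
}

#' Instance projection head: `H = ReLU(Z %*% W21) %*% W22`
#' @param Z m x d embeddings. @param W21,W22 head weights.
#' @return m x f projection matrix.
#' @export
project_instance <- function(Z, W21, W22) relu(Z %*% W21) %*% W22

#' Cluster projection head: `Q = softmax(ReLU(Z %*% W31) %*% W32)`
#' Softmax is taken row-wise over the pseudo-cluster columns, so each row of
#' `Q` is a probability vector.
#' @param Z m x d embeddings. @param W31,W32 head weights.
#' @return m x N_c row-stochastic matrix.
#' @export
project_cluster <- function(Z, W31, W32) row_softmax(relu(Z %*% W31) %*% W32)

#' Per-spot attention weights over the two views
#'
#' Scores `att_v = tanh(Z_v %*% W41) %*% W42` are per-spot scalars; a two-way
#' softmax turns them into weights `alpha_spa + alpha_expr = 1`, constant
#' across the embedding columns.
#'
#' @param Z_spa,Z_expr m x d view embeddings.
#' @param W41,W42 attention weights (d x d3, d3 x 1).
#' @return list with vectors `alpha_spa`, `alpha_expr` (length m).
#' @export
attend <- function(Z_spa, Z_expr, W41, W42) {
  att_s <- tanh(Z_spa %*% W41) %*% W42
  att_e <- tanh(Z_expr %*% W41) %*% W42
  a <- 1 / (1 + exp(att_e - att_s))
  list(alpha_spa = as.vector(a), alpha_expr = as.vector(1 - a))
}

#' Fuse the two view embeddings with attention weights
#' @param Z_spa,Z_expr m x d matrices. @param alphas list from [attend()].
#' @return m x d convex combination per entry.
#' @export
fuse <- function(Z_spa, Z_expr, alphas) {
  Z_spa * alphas$alpha_spa + Z_expr * alphas$alpha_expr
}

#' Tied-weight decoder: `X_hat = ReLU(Z_b %*% t(W12)) %*% t(W11)`
#' @param Z_b m x d latent matrix (batch prompts re-added).
#' @param W12,W11 the *encoder* weights, reused transposed.
#' @return m x n reconstruction.
#' @export
decode <- function(Z_b, W12, W11) relu(Z_b %*% t(W12)) %*% t(W11)

#' Full forward pass
#'
#' Executes the whole chain: batch correction, (optional) feature and edge
#' augmentation, per-view GCN encoding, projection heads, attention fusion,
#' batch restore, decoding. With `training = FALSE` the augmentations are
#' identities and no random numbers are drawn.
#'
#' @param state a `"model_state"`.
#' @param X m x n feature matrix.
#' @param graph a `"multiview_graph"`.
#' @param E m x L one-hot batch indicator.
#' @param cfg a `"spview_config"` (augmentation rates).
#' @param training logical; draw fresh augmentations and keep the
#'   backpropagation cache.
#' @return A `"forward_outputs"` list: `Z_spa`, `Z_expr`, `H_spa`, `H_expr`,
#'   `Q_spa`, `Q_expr`, `alpha_spa`, `alpha_expr`, `Z`, `Z_b`, `X_hat`, and
#'   (when `training`) a `cache` of intermediates.
#' @export
forward_pass <- function(state, X, graph, E, cfg = spview_config(),
                         training = FALSE) {
  check_one_hot(E)
  Xb <- X - E %*% state$B1
  if (training) {
    Xt <- perturb_features(Xb, cfg$noise_alpha, cfg$mask_p)
    feat_mask <- attr(Xt, "mask")
    attr(Xt, "mask") <- NULL
  } else {
    Xt <- Xb
    feat_mask <- NULL
  }

  run_view <- function(A) {
    C1 <- if (training) corrupt_graph(A, cfg$edge_keep_p) else A
    C2 <- if (training) corrupt_graph(A, cfg$edge_keep_p) else A
    CX <- as.matrix(C1 %*% Xt)
    P <- elu(CX %*% state$W11)
    CP <- as.matrix(C2 %*% P)
    Z <- elu(CP %*% state$W12)
    R <- relu(Z %*% state$W21)
    H <- R %*% state$W22
    S <- relu(Z %*% state$W31)
    G <- S %*% state$W32
    Q <- row_softmax(G)
    Tn <- tanh(Z %*% state$W41)
    att <- Tn %*% state$W42
    list(C1 = C1, C2 = C2, CX = CX, P = P, CP = CP, Z = Z,
         R = R, H = H, S = S, Q = Q, Tn = Tn, att = att)
  }
  vs <- run_view(graph$A_spa_norm)
  ve <- run_view(graph$A_expr_norm)

  a <- as.vector(1 / (1 + exp(ve$att - vs$att)))
  Z <- vs$Z * a + ve$Z * (1 - a)
  Zb <- Z + E %*% state$B2
  Dpre <- Zb %*% t(state$W12)
  Dr <- relu(Dpre)
  Xhat <- Dr %*% t(state$W11)

  out <- list(Z_spa = vs$Z, Z_expr = ve$Z,
              H_spa = vs$H, H_expr = ve$H,
              Q_spa = vs$Q, Q_expr = ve$Q,
              alpha_spa = a, alpha_expr = 1 - a,
              Z = Z, Z_b = Zb, X_hat = Xhat)
  if (training)
    out$cache <- list(vs = vs, ve = ve, a = a, Xt = Xt, feat_mask = feat_mask,
                      E = E, Z = Z, Zb = Zb, Dr = Dr)
  class(out) <- "forward_outputs"
  out
}

# Reverse pass for the fixed architecture. `d_out` carries the loss gradients
# with respect to H_spa/H_expr, Q_spa/Q_expr and X_hat (any may be NULL).
# Returns gradients for every parameter in `state`.
backward_pass <- function(state, out, d_out) {
  cc <- out$cache
  if (is.null(cc)) stop("forward pass was run without training = TRUE")
  vs <- cc$vs; ve <- cc$ve
  m <- nrow(out$Z)
  zeros_like <- function(M) array(0, dim(M))
  g <- lapply(state, zeros_like)

  dXhat <- d_out$dX_hat
  dZ <- matrix(0, m, ncol(out$Z))
  if (!is.null(dXhat)) {
    g$W11 <- g$W11 + t(dXhat) %*% cc$Dr
    dDpre <- (dXhat %*% state$W11) * (cc$Dr > 0)
    g$W12 <- g$W12 + t(dDpre) %*% cc$Zb
    dZb <- dDpre %*% state$W12
    g$B2 <- g$B2 + t(cc$E) %*% dZb
    dZ <- dZ + dZb
  }

  # fusion: Z = a * Z_spa + (1 - a) * Z_expr, a = sigmoid(att_spa - att_expr)
  a <- cc$a
  dZv <- list(spa = dZ * a, expr = dZ * (1 - a))
  da <- rowSums(dZ * (vs$Z - ve$Z))
  datt <- matrix(da * a * (1 - a), ncol = 1)
  datt_view <- list(spa = datt, expr = -datt)

  dXt <- matrix(0, nrow(cc$Xt), ncol(cc$Xt))
  for (v in c("spa", "expr")) {
    vv <- if (v == "spa") vs else ve
    dZl <- dZv[[v]]

    dH <- d_out[[paste0("dH_", v)]]
    if (!is.null(dH)) {
      g$W22 <- g$W22 + t(vv$R) %*% dH
      dRpre <- (dH %*% t(state$W22)) * (vv$R > 0)
      g$W21 <- g$W21 + t(vv$Z) %*% dRpre
      dZl <- dZl + dRpre %*% t(state$W21)
    }
    dQ <- d_out[[paste0("dQ_", v)]]
    if (!is.null(dQ)) {
      dG <- vv$Q * (dQ - rowSums(dQ * vv$Q))
      g$W32 <- g$W32 + t(vv$S) %*% dG
      dSpre <- (dG %*% t(state$W32)) * (vv$S > 0)
      g$W31 <- g$W31 + t(vv$Z) %*% dSpre
      dZl <- dZl + dSpre %*% t(state$W31)
    }
    # attention branch
    dTn <- (datt_view[[v]] %*% t(state$W42)) * (1 - vv$Tn^2)
    g$W42 <- g$W42 + t(vv$Tn) %*% datt_view[[v]]
    g$W41 <- g$W41 + t(vv$Z) %*% dTn
    dZl <- dZl + dTn %*% t(state$W41)

    # encoder
    dV <- dZl * elu_prime_from_out(vv$Z)
    g$W12 <- g$W12 + t(vv$CP) %*% dV
    dP <- as.matrix(Matrix::crossprod(vv$C2, dV %*% t(state$W12)))
    dU <- dP * elu_prime_from_out(vv$P)
    g$W11 <- g$W11 + t(vv$CX) %*% dU
    dXt <- dXt + as.matrix(Matrix::crossprod(vv$C1, dU %*% t(state$W11)))
  }

  dXb <- if (is.null(cc$feat_mask)) dXt else dXt * cc$feat_mask
  g$B1 <- g$B1 - t(cc$E) %*% dXb
  g
}
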
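# cosine-normalize rows / columns with a small norm floor for gradient
# stability; with strict = TRUE exact-zero rows (columns) raise, with
# strict = FALSE (training path) they are treated as zero vectors under the
# floored norm, giving cosine 0 against everything.
unit_rows <- function(H, what = "row", strict = TRUE) {
  nrm <- sqrt(rowSums(H^2))
  if (strict && any(nrm == 0))
    stop(sprintf("zero-norm %s(s): %s", what,
                 paste(which(nrm == 0), collapse = ", ")))
  nrm <- pmax(nrm, 1e-8)
  list(U = H / nrm, nrm = nrm)
}

# backprop through row normalization u = h / ||h||
denorm_rows <- function(dU, U, nrm) (dU - U * rowSums(dU * U)) / nrm

#' Instance-level contrastive loss
#'
#' Symmetric InfoNCE over spots with cosine similarity: for anchor `h_i` in
#' one view the positive is the same spot `i` in the *other* view and the
#' negatives are the other spots of the other view only — same-view pairs are
#' deliberately absent from the denominator, since pushing apart spots that
#' the GCN smooths together would fight the encoder. Both anchor directions
#' are averaged over spots and summed.
#'
#' @param H_spa,H_expr m x f projection matrices, no zero rows.
#' @param tau temperature, `> 0`.
#' @param grad logical; also return gradients.
#' @param strict raise on exact-zero rows (the documented contract); the
#'   training loop runs with `strict = FALSE`, where zero rows fall back to
#'   the floored-norm cosine.
#' @return the scalar loss, or (with `grad`) a list `value`, `dH_spa`,
#'   `dH_expr`.
#' @export
instance_loss <- function(H_spa, H_expr, tau, grad = FALSE, strict = TRUE) {
  m <- nrow(H_spa)
  stopifnot(nrow(H_expr) == m, ncol(H_expr) == ncol(H_spa), tau > 0)
  ns <- unit_rows(H_spa, strict = strict)
  ne <- unit_rows(H_expr, strict = strict)
  S <- (ns$U %*% t(ne$U)) / tau          # S[i, k] = s(h_i^spa, h_k^expr)/tau

  # spa anchors: softmax over rows; expr anchors: softmax over columns
  rmax <- apply(S, 1, max)
  Er <- exp(S - rmax)
  P1 <- Er / rowSums(Er)
  cmax <- apply(S, 2, max)
  Ec <- exp(sweep(S, 2, cmax))
  P2 <- sweep(Ec, 2, colSums(Ec), "/")

  val <- -mean(log(diag(P1))) - mean(log(diag(P2)))
  if (!grad) return(val)

  I <- diag(m)
  dS <- (P1 - I) / m + (P2 - I) / m
  dUs <- (dS %*% ne$U) / tau
  dUe <- (t(dS) %*% ns$U) / tau
  list(value = val,
       dH_spa = denorm_rows(dUs, ns$U, ns$nrm),
       dH_expr = denorm_rows(dUe, ne$U, ne$nrm))
}

#' Cluster-level contrastive loss with entropy regularization
#'
#' The contrast runs over the `N_c` pseudo-cluster *columns* of the soft
#' assignment matrices: for anchor column `q_j` of one view, the positive is
#' column `j` of the other view; the denominator holds all cross-view columns
#' plus the same-view columns `k != j`. Each view-anchored term carries an
#' entropy regularizer `sum_j pi_j log pi_j` over the column-mass fractions
#' `pi_j`, which is minimal (`-log N_c`) at uniform cluster usage and
#' prevents collapse into one cluster.
#'
#' @param Q_spa,Q_expr m x N_c row-stochastic assignment matrices.
#' @param tau temperature, `> 0`.
#' @param grad logical; also return gradients.
#' @param strict raise on exact-zero columns; see [instance_loss()].
#' @return list with `L_cls_spa`, `L_cls_expr` (each contrast + its
#'   regularizer), `L_reg_spa`, `L_reg_expr`, and with `grad` also `dQ_spa`,
#'   `dQ_expr`.
#' @export
cluster_loss <- function(Q_spa, Q_expr, tau, grad = FALSE, strict = TRUE) {
  nc <- ncol(Q_spa)
  stopifnot(ncol(Q_expr) == nc, nrow(Q_expr) == nrow(Q_spa), tau > 0)
  us <- unit_rows(t(Q_spa), "column", strict = strict)
  ue <- unit_rows(t(Q_expr), "column", strict = strict)
  Us <- t(us$U); Ue <- t(ue$U)          # columns unit-normalized

  Ccr <- crossprod(Us, Ue) / tau        # Ccr[j, k] = s(q_j^spa, q_k^expr)/tau
  Css <- crossprod(Us) / tau
  Cee <- crossprod(Ue) / tau

  # one anchored direction: anchors columns of `A` (cross matrix Cx rows),
  # same-view similarities Cs (diagonal excluded from the denominator)
  one_side <- function(Cx, Cs) {
    mx <- pmax(apply(Cx, 1, max), apply(Cs, 1, max))
    W1 <- exp(Cx - mx)
    W2 <- exp(Cs - mx); diag(W2) <- 0
    denom <- rowSums(W1) + rowSums(W2)
    val <- -mean(diag(Cx) - mx - log(denom))
    dCx <- (W1 / denom - diag(nc)) / nc
    dCs <- (W2 / denom) / nc
    list(val = val, dCx = dCx, dCs = dCs)
  }
  spa <- one_side(Ccr, Css)
  expr <- one_side(t(Ccr), Cee)

  ent <- function(Q) {
    cs <- colSums(Q)
    pi_ <- cs / sum(cs)
    sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
  }
  reg_s <- ent(Q_spa); reg_e <- ent(Q_expr)

  res <- list(L_cls_spa = spa$val + reg_s,
              L_cls_expr = expr$val + reg_e,
              L_reg_spa = reg_s, L_reg_expr = reg_e)
  if (!grad) return(res)

  dCcr <- (spa$dCx + t(expr$dCx)) / tau
  dCss <- spa$dCs / tau
  dCee <- expr$dCs / tau
  dUs <- Ue %*% t(dCcr) + Us %*% (dCss + t(dCss))
  dUe <- Us %*% dCcr + Ue %*% (dCee + t(dCee))
  dQs <- t(denorm_rows(t(dUs), us$U, us$nrm))
  dQe <- t(denorm_rows(t(dUe), ue$U, ue$nrm))

  ent_grad <- function(Q) {
    cs <- colSums(Q)
    tot <- sum(cs)
    pi_ <- cs / tot
    lp <- ifelse(pi_ > 0, log(pi_), 0)
    gcol <- (lp + 1 - sum(pi_ * (lp + 1))) / tot
    matrix(gcol, nrow(Q), ncol(Q), byrow = TRUE)
  }
  res$dQ_spa <- dQs + ent_grad(Q_spa)
  res$dQ_expr <- dQe + ent_grad(Q_expr)
  res
}

#' Mean-squared reconstruction loss
#' @param X,X_hat matrices of identical shape.
#' @param grad logical; also return the gradient with respect to `X_hat`.
#' @return scalar, or list `value`, `dX_hat`.
#' @export
recon_loss <- function(X, X_hat, grad = FALSE) {
  if (!all(dim(X) == dim(X_hat))) stop("shape mismatch between X and X_hat")
  R <- X_hat - X
  val <- mean(R^2)
  if (!grad) return(val)
  list(value = val, dX_hat = 2 * R / length(R))
}

#' Combine loss components into the training objective
#'
#' `total = L_rec + (L_cls_spa + L_cls_expr) + kappa * L_ins`, with ablation
#' modes zeroing individual terms (`no_instance` drops the instance term,
#' `no_cluster` the cluster term, `no_both` leaves the reconstruction loss
#' only; `no_prompting` changes no loss term).
#'
#' @param parts list with `L_rec`, `L_ins`, `L_cls_spa`, `L_cls_expr`,
#'   `L_reg_spa`, `L_reg_expr`.
#' @param kappa instance-loss weight.
#' @param ablation one of `"full"`, `"no_instance"`, `"no_cluster"`,
#'   `"no_both"`, `"no_prompting"`.
#' @return A `"loss_breakdown"` list: the parts, `kappa`, and `total`.
#' @export
total_loss <- function(parts, kappa, ablation = "full") {
  use_ins <- !(ablation %in% c("no_instance", "no_both"))
  use_cls <- !(ablation %in% c("no_cluster", "no_both"))
  total <- parts$L_rec +
    (if (use_cls) parts$L_cls_spa + parts$L_cls_expr else 0) +
    (if (use_ins) kappa * parts$L_ins else 0)
  structure(c(parts, list(kappa = kappa, ablation = ablation, total = total)),
            class = "loss_breakdown")
}
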
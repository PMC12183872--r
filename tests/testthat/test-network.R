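test_that("batch correction subtracts per-slice rows and inverts known shifts", {
  ti <- tiny_instance()
  expect_equal(apply_batch_correction(ti$X, matrix(0, ti$L, ti$n), ti$E), ti$X)

  # L = 1: every row shifted by -c
  E1 <- matrix(1, 4, 1)
  X1 <- matrix(rnorm(20), 4, 5)
  cshift <- matrix(rnorm(5), 1, 5)
  expect_equal(apply_batch_correction(X1, cshift, E1),
               sweep(X1, 2, as.vector(cshift)), tolerance = 1e-12)

  # constructed inverse: subtracting the true shifts restores the original
  shifts <- matrix(rnorm(2 * ti$n), 2, ti$n)
  Xshift <- ti$X + ti$E %*% shifts
  expect_equal(apply_batch_correction(Xshift, shifts, ti$E), ti$X,
               tolerance = 1e-12)

  Ebad <- ti$E; Ebad[1, ] <- c(1, 1)
  expect_error(apply_batch_correction(ti$X, shifts, Ebad), "one-hot")
})

test_that("encoder reduces to identity and matches a dense reference", {
  # identity graph, identity-padded weights, nonneg X: ELU is identity
  X <- matrix(abs(rnorm(12)), 4, 3)
  I4 <- Matrix::Diagonal(4)
  W11 <- diag(3)
  W12 <- diag(3)
  expect_equal(encode(I4, I4, X, W11, W12), X, tolerance = 1e-12,
               ignore_attr = TRUE)

  set.seed(31)
  m <- 4; n <- 3; d1 <- 2; d <- 2
  A <- normalize_sym(hybridize(knn_spatial(matrix(runif(8), m, 2), 2), 0.3))
  Xr <- matrix(rnorm(m * n), m, n)
  W11r <- matrix(rnorm(n * d1), n, d1)
  W12r <- matrix(rnorm(d1 * d), d1, d)
  eluref <- function(v) ifelse(v > 0, v, exp(v) - 1)
  Ad <- as.matrix(A)
  ref <- eluref(Ad %*% eluref(Ad %*% Xr %*% W11r) %*% W12r)
  expect_equal(encode(A, A, Xr, W11r, W12r), ref, tolerance = 1e-6)
})

test_that("encoder is permutation-equivariant", {
  set.seed(32)
  m <- 6
  A <- normalize_sym(hybridize(knn_spatial(matrix(runif(12), m, 2), 2), 0.3))
  X <- matrix(rnorm(m * 4), m, 4)
  W11 <- matrix(rnorm(8), 4, 2); W12 <- matrix(rnorm(4), 2, 2)
  perm <- sample(m)
  Z <- encode(A, A, X, W11, W12)
  Zp <- encode(A[perm, perm], A[perm, perm], X[perm, ], W11, W12)
  expect_equal(Zp, Z[perm, ], tolerance = 1e-10)
})

test_that("projection heads satisfy simplex/dense-reference contracts", {
  set.seed(33)
  Z <- matrix(rnorm(12), 4, 3)
  W31 <- matrix(rnorm(6), 3, 2); W32 <- matrix(rnorm(6), 2, 3)
  Q <- project_cluster(Z, W31, W32)
  expect_true(all(Q >= 0))
  expect_equal(rowSums(Q), rep(1, 4), tolerance = 1e-6)
  # zero final layer -> exactly uniform
  Qu <- project_cluster(Z, W31, matrix(0, 2, 3))
  expect_true(all(abs(Qu - 1 / 3) < 1e-12))

  W21 <- matrix(rnorm(6), 3, 2); W22 <- matrix(rnorm(4), 2, 2)
  H <- project_instance(Z, W21, W22)
  ref <- pmax(Z %*% W21, 0) %*% W22
  expect_equal(H, ref, tolerance = 1e-6)
})

test_that("attention weights are a two-way softmax over per-spot scores", {
  set.seed(34)
  Z <- matrix(rnorm(10), 5, 2)
  W41 <- matrix(rnorm(4), 2, 2); W42 <- matrix(rnorm(2), 2, 1)
  al <- attend(Z, Z, W41, W42)
  expect_equal(al$alpha_spa, rep(0.5, 5))

  # hand-computed 2-spot case
  Zs <- rbind(c(1, 0), c(0, 1)); Ze <- rbind(c(0, 1), c(1, 0))
  as_ <- tanh(Zs %*% W41) %*% W42
  ae_ <- tanh(Ze %*% W41) %*% W42
  expected <- exp(as_) / (exp(as_) + exp(ae_))
  al2 <- attend(Zs, Ze, W41, W42)
  expect_equal(al2$alpha_spa, as.vector(expected), tolerance = 1e-8)
  expect_equal(al2$alpha_spa + al2$alpha_expr, rep(1, 2), tolerance = 1e-12)

  # saturation: a huge score difference drives the weight to 1
  al3 <- attend(Zs * 1e4, Ze * 1e4, diag(2) * 50, matrix(c(1, 1), 2, 1))
  expect_true(all(al3$alpha_spa %in% c(al3$alpha_spa)))  # finite
  fu <- fuse(Zs, Ze, list(alpha_spa = rep(1, 2), alpha_expr = rep(0, 2)))
  expect_equal(fu, Zs)
  fu2 <- fuse(Zs, Ze, list(alpha_spa = rep(0.5, 2), alpha_expr = rep(0.5, 2)))
  expect_equal(fu2, (Zs + Ze) / 2)
})

test_that("decoder uses tied weights and matches a dense reference", {
  set.seed(35)
  Zb <- matrix(rnorm(6), 3, 2)
  W12 <- matrix(rnorm(6), 3, 2)   # d1 = 3, d = 2
  W11 <- matrix(rnorm(12), 4, 3)  # n = 4, d1 = 3
  ref <- pmax(Zb %*% t(W12), 0) %*% t(W11)
  expect_equal(decode(Zb, W12, W11), ref, tolerance = 1e-6)
  # identity chain with nonneg input
  Zp <- abs(matrix(rnorm(9), 3, 3))
  expect_equal(decode(Zp, diag(3), diag(3)), Zp)
})

test_that("forward pass invariants hold across random configurations", {
  set.seed(36)
  for (rep in 1:25) {
    ti <- tiny_instance(seed = 100 + rep, m = sample(5:9, 1), L = sample(1:2, 1))
    out <- forward_pass(ti$state, ti$X, ti$graph, ti$E, ti$cfg)
    expect_true(all(out$Q_spa >= 0) && all(out$Q_expr >= 0))
    expect_equal(rowSums(out$Q_spa), rep(1, ti$m), tolerance = 1e-6)
    expect_equal(rowSums(out$Q_expr), rep(1, ti$m), tolerance = 1e-6)
    expect_equal(out$alpha_spa + out$alpha_expr, rep(1, ti$m),
                 tolerance = 1e-6)
    lo <- pmin(out$Z_spa, out$Z_expr) - 1e-12
    hi <- pmax(out$Z_spa, out$Z_expr) + 1e-12
    expect_true(all(out$Z >= lo & out$Z <= hi))
  }
})

test_that("single-slice forward with zero prompts reduces to the plain model", {
  ti <- tiny_instance(seed = 50, L = 1)
  out_full <- forward_pass(ti$state, ti$X, ti$graph, ti$E, ti$cfg)
  # bypass the batch module entirely
  state0 <- ti$state
  Xb <- ti$X   # B1 = 0
  C <- list(ti$graph$A_spa_norm, ti$graph$A_expr_norm)
  Zs <- encode(C[[1]], C[[1]], Xb, state0$W11, state0$W12)
  Ze <- encode(C[[2]], C[[2]], Xb, state0$W11, state0$W12)
  al <- attend(Zs, Ze, state0$W41, state0$W42)
  Z <- fuse(Zs, Ze, al)
  Xhat <- decode(Z, state0$W12, state0$W11)
  expect_identical(out_full$Z, Z)
  expect_identical(out_full$X_hat, Xhat)
})

test_that("forward pass is deterministic given the seed and permutation-equivariant", {
  ti <- tiny_instance(seed = 60)
  cfg_aug <- ti$cfg
  cfg_aug$noise_alpha <- 0.2; cfg_aug$mask_p <- 0.8; cfg_aug$edge_keep_p <- 0.8
  set.seed(7); o1 <- forward_pass(ti$state, ti$X, ti$graph, ti$E, cfg_aug,
                                  training = TRUE)
  set.seed(7); o2 <- forward_pass(ti$state, ti$X, ti$graph, ti$E, cfg_aug,
                                  training = TRUE)
  expect_identical(o1$X_hat, o2$X_hat)
  expect_identical(o1$Z, o2$Z)

  perm <- sample(ti$m)
  gperm <- list(A_spa_norm = ti$graph$A_spa_norm[perm, perm],
                A_expr_norm = ti$graph$A_expr_norm[perm, perm])
  op <- forward_pass(ti$state, ti$X[perm, ], gperm, ti$E[perm, , drop = FALSE],
                     ti$cfg)
  ob <- forward_pass(ti$state, ti$X, ti$graph, ti$E, ti$cfg)
  for (fld in c("Z_spa", "Z_expr", "Z", "X_hat", "Q_spa", "H_expr"))
    expect_equal(op[[fld]], ob[[fld]][perm, ], tolerance = 1e-10)
  expect_equal(op$alpha_spa, ob$alpha_spa[perm], tolerance = 1e-10)
})

test_that("analytic gradients of the full model agree with finite differences", {
  ti <- tiny_instance(seed = 70, L = 2)
  state <- ti$state
  set.seed(1)
  state$B1 <- matrix(rnorm(2 * ti$n, 0, 0.1), 2, ti$n)
  state$B2 <- matrix(rnorm(2 * 3, 0, 0.1), 2, 3)
  cfg <- ti$cfg

  loss_of <- function(st) {
    out <- forward_pass(st, ti$X, ti$graph, ti$E, cfg, training = TRUE)
    rec <- recon_loss(ti$X, out$X_hat, grad = TRUE)
    ins <- instance_loss(out$H_spa, out$H_expr, cfg$tau_ins, grad = TRUE)
    cls <- cluster_loss(out$Q_spa, out$Q_expr, cfg$tau_cls, grad = TRUE)
    list(total = rec$value + cls$L_cls_spa + cls$L_cls_expr + ins$value,
         out = out, rec = rec, ins = ins, cls = cls)
  }
  base <- loss_of(state)
  d_out <- list(dX_hat = base$rec$dX_hat,
                dH_spa = base$ins$dH_spa, dH_expr = base$ins$dH_expr,
                dQ_spa = base$cls$dQ_spa, dQ_expr = base$cls$dQ_expr)
  g <- backward_pass(state, base$out, d_out)

  h <- 1e-6
  set.seed(2)
  for (nm in names(state)) {
    for (k in sample(length(state[[nm]]), min(4, length(state[[nm]])))) {
      sp <- state; sp[[nm]][k] <- sp[[nm]][k] + h
      sm <- state; sm[[nm]][k] <- sm[[nm]][k] - h
      fd <- (loss_of(sp)$total - loss_of(sm)$total) / (2 * h)
      expect_equal(g[[nm]][k], fd, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, k))
    }
  }
  # gradient reaches the prompt embeddings when L > 1
  expect_gt(max(abs(g$B1)), 0)
  expect_gt(max(abs(g$B2)), 0)
})

test_that("checkpoints round-trip every parameter tensor", {
  ti <- tiny_instance(seed = 80)
  td <- withr::local_tempdir()
  p <- file.path(td, "ckpt.json")
  save_checkpoint(list(state = ti$state, cfg = ti$cfg), p)
  back <- load_checkpoint(p)
  for (nm in names(ti$state))
    expect_equal(back$state[[nm]], ti$state[[nm]], tolerance = 1e-15,
                 ignore_attr = TRUE)
  expect_equal(back$cfg$d1, ti$cfg$d1)
})
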
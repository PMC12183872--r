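# Scalar brute-force references, written independently of the vectorized
# implementations: double loops over spots/clusters, plain cosine.
cos_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

ref_instance <- function(Hs, He, tau) {
  m <- nrow(Hs)
  t1 <- 0; t2 <- 0
  for (i in seq_len(m)) {
    num <- exp(cos_sim(Hs[i, ], He[i, ]) / tau)
    den <- 0
    for (k in seq_len(m)) den <- den + exp(cos_sim(Hs[i, ], He[k, ]) / tau)
    t1 <- t1 - log(num / den)
    num2 <- exp(cos_sim(He[i, ], Hs[i, ]) / tau)
    den2 <- 0
    for (k in seq_len(m)) den2 <- den2 + exp(cos_sim(He[i, ], Hs[k, ]) / tau)
    t2 <- t2 - log(num2 / den2)
  }
  t1 / m + t2 / m
}

ref_cluster <- function(Qs, Qe, tau) {
  nc <- ncol(Qs)
  side <- function(A, B) {    # anchors: columns of A
    tot <- 0
    for (j in seq_len(nc)) {
      num <- exp(cos_sim(A[, j], B[, j]) / tau)
      den <- 0
      for (k in seq_len(nc)) den <- den + exp(cos_sim(A[, j], B[, k]) / tau)
      for (k in seq_len(nc)) if (k != j)
        den <- den + exp(cos_sim(A[, j], A[, k]) / tau)
      tot <- tot - log(num / den)
    }
    tot / nc
  }
  reg <- function(Q) {
    pi_ <- colSums(Q) / sum(Q)
    sum(pi_ * log(pi_))
  }
  list(spa = side(Qs, Qe) + reg(Qs), expr = side(Qe, Qs) + reg(Qe))
}

test_that("instance loss hand cases", {
  # m = 1: single-term softmax, loss 0
  expect_equal(instance_loss(matrix(c(1, 2), 1), matrix(c(3, 1), 1), 0.5), 0)
  # m = 2, identical orthonormal rows, tau = 1
  H <- diag(2)
  expect_equal(instance_loss(H, H, 1), 2 * (-log(exp(1) / (exp(1) + 1))),
               tolerance = 1e-12)
  expect_error(instance_loss(rbind(c(0, 0), c(1, 1)), H, 1), "zero-norm")
})

test_that("instance loss matches the brute-force oracle on random instances", {
  set.seed(21)
  for (rep in 1:40) {
    m <- sample(2:6, 1); f <- sample(2:4, 1)
    tau <- runif(1, 0.2, 2)
    Hs <- matrix(rnorm(m * f), m, f)
    He <- matrix(rnorm(m * f), m, f)
    expect_equal(instance_loss(Hs, He, tau), ref_instance(Hs, He, tau),
                 tolerance = 1e-6)
  }
})

test_that("instance loss analytic gradients match finite differences", {
  set.seed(22)
  Hs <- matrix(rnorm(12), 4, 3); He <- matrix(rnorm(12), 4, 3)
  g <- instance_loss(Hs, He, 0.7, grad = TRUE)
  h <- 1e-6
  for (k in sample(12, 5)) {
    Hp <- Hs; Hp[k] <- Hp[k] + h
    Hm <- Hs; Hm[k] <- Hm[k] - h
    fd <- (instance_loss(Hp, He, 0.7) - instance_loss(Hm, He, 0.7)) / (2 * h)
    expect_equal(g$dH_spa[k], fd, tolerance = 1e-5)
  }
})

test_that("instance loss is invariant to a common rotation and decreases as views align", {
  set.seed(23)
  Hs <- matrix(rnorm(15), 5, 3); He <- matrix(rnorm(15), 5, 3)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(instance_loss(Hs %*% R, He %*% R, 0.5),
               instance_loss(Hs, He, 0.5), tolerance = 1e-10)
  vals <- sapply(seq(0, 1, length.out = 5), function(t)
    instance_loss(Hs, (1 - t) * He + t * Hs, 0.5))
  expect_true(all(diff(vals) < 0))
})

test_that("cluster loss hand cases", {
  # single pseudo-cluster: empty negative set, pi = 1 -> everything 0
  q <- matrix(rep(1, 4), 4, 1)
  r <- cluster_loss(q, q, 1)
  expect_equal(r$L_cls_spa, 0, tolerance = 1e-12)
  expect_equal(r$L_reg_spa, 0)

  # uniform Q attains the entropy minimum -log(Nc)
  Qu <- matrix(1 / 3, 6, 3)
  r2 <- cluster_loss(Qu, Qu, 1)
  expect_equal(r2$L_reg_spa, -log(3), tolerance = 1e-12)

  expect_error(cluster_loss(cbind(c(1, 1), 0), cbind(c(1, 1), 0), 1),
               "zero-norm")
})

test_that("cluster loss matches the brute-force oracle on random instances", {
  set.seed(24)
  for (rep in 1:40) {
    m <- sample(3:8, 1); nc <- sample(2:4, 1)
    tau <- runif(1, 0.3, 2)
    Qs <- rand_simplex_rows(m, nc); Qe <- rand_simplex_rows(m, nc)
    ref <- ref_cluster(Qs, Qe, tau)
    got <- cluster_loss(Qs, Qe, tau)
    expect_equal(got$L_cls_spa, ref$spa, tolerance = 1e-6)
    expect_equal(got$L_cls_expr, ref$expr, tolerance = 1e-6)
  }
})

test_that("cluster loss analytic gradients match finite differences", {
  set.seed(25)
  Qs <- rand_simplex_rows(5, 3); Qe <- rand_simplex_rows(5, 3)
  g <- cluster_loss(Qs, Qe, 0.8, grad = TRUE)
  h <- 1e-6
  tot <- function(Qa, Qb) {
    r <- cluster_loss(Qa, Qb, 0.8)
    r$L_cls_spa + r$L_cls_expr
  }
  for (k in sample(15, 5)) {
    Qp <- Qs; Qp[k] <- Qp[k] + h
    Qm <- Qs; Qm[k] <- Qm[k] - h
    fd <- (tot(Qp, Qe) - tot(Qm, Qe)) / (2 * h)
    expect_equal(g$dQ_spa[k], fd, tolerance = 1e-4)
  }
})

test_that("entropy regularizer is minimal only at uniform cluster mass", {
  Qu <- matrix(1 / 4, 8, 4)
  base <- cluster_loss(Qu, Qu, 1)$L_reg_spa
  expect_equal(base, -log(4), tolerance = 1e-12)
  set.seed(26)
  for (rep in 1:10) {
    P <- rand_simplex_rows(8, 4)
    Qp <- 0.8 * Qu + 0.2 * P     # stays on the simplex, non-uniform mass
    if (max(abs(colSums(Qp) - 2)) < 1e-9) next
    expect_gt(cluster_loss(Qp, Qu, 1)$L_reg_spa, base)
  }
})

test_that("reconstruction loss equals the elementwise mean square", {
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(recon_loss(X, X), 0)
  Xh <- X; Xh[2, 3] <- Xh[2, 3] + 0.37
  expect_equal(recon_loss(X, Xh), 0.37^2 / 12, tolerance = 1e-14)
  set.seed(27)
  A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(12), 4, 3)
  slow <- 0
  for (i in 1:4) for (j in 1:3) slow <- slow + (A[i, j] - B[i, j])^2
  expect_equal(recon_loss(A, B), slow / 12, tolerance = 1e-10)
  expect_error(recon_loss(A, matrix(0, 3, 4)), "shape")
})

test_that("total loss combines parts per contract and is linear in kappa", {
  parts <- list(L_rec = 1.5, L_ins = 0.7, L_cls_spa = 0.2, L_cls_expr = 0.3,
                L_reg_spa = -0.1, L_reg_expr = -0.2)
  expect_equal(total_loss(parts, 0)$total, 2.0)
  expect_equal(total_loss(parts, 2)$total - total_loss(parts, 1)$total, 0.7,
               tolerance = 1e-12)
  z <- list(L_rec = 0, L_ins = 0, L_cls_spa = 0, L_cls_expr = 0,
            L_reg_spa = 0, L_reg_expr = 0)
  expect_equal(total_loss(z, 1)$total, 0)
  # ablation switches
  expect_equal(total_loss(parts, 1, "no_both")$total, parts$L_rec)
  expect_equal(total_loss(parts, 1, "no_instance")$total, 2.0)
  expect_equal(total_loss(parts, 1, "no_cluster")$total, 1.5 + 0.7)
  lb <- total_loss(parts, 1)
  expect_equal(lb$total, lb$L_rec + lb$L_cls_spa + lb$L_cls_expr +
                 lb$kappa * lb$L_ins, tolerance = 1e-8)
})
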
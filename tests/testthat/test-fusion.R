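# Cross-coupled fusion: association matrix, depthwise convolution,
# residual rounds, pooling/projection, cat baseline, masking.

test_that("association matrix is the row softmax of Fp Fd^T", {
  set.seed(1)
  Fp <- matrix(rnorm(3 * 64), 3, 64)
  Fd <- matrix(rnorm(4 * 64), 4, 64)
  C <- compute_association(Fp, Fd)
  expect_equal(C, oracle_association(Fp, Fd), tolerance = 1e-6)
  expect_equal(rowSums(C), rep(1, 3), tolerance = 1e-6)
  expect_true(all(C >= 0))
  # zero protein features -> uniform rows
  Cz <- compute_association(Fp * 0, Fd)
  expect_equal(Cz, matrix(1 / 4, 3, 4), tolerance = 1e-12)
  # 1x1 case
  expect_equal(compute_association(Fp[1, , drop = FALSE],
                                   Fd[1, , drop = FALSE]),
               matrix(1, 1, 1))
  expect_error(compute_association(Fp, Fd[, 1:10]), "mismatch")
})

test_that("depthwise convolution matches the sliding-window oracle", {
  p <- seeded_fusion_params(2)
  set.seed(3)
  X <- matrix(rnorm(6 * 64), 6, 64)
  expect_equal(depthwise_conv_protein(X, p),
               oracle_dwc(X, p$K, p$kb), tolerance = 1e-6)
  # identity kernel (0,1,0) with zero bias reproduces the input
  pid <- p
  pid$K <- rbind(0, rep(1, 64), 0)
  pid$kb <- numeric(64)
  expect_equal(depthwise_conv_protein(X, pid), X, tolerance = 1e-12)
  # single residue: only the center tap and bias contribute
  x1 <- X[1, , drop = FALSE]
  expect_equal(depthwise_conv_protein(x1, p)[1, ],
               p$K[2, ] * x1[1, ] + p$kb, tolerance = 1e-12)
})

test_that("a fusion round matches the dense oracle and preserves shapes", {
  p <- seeded_fusion_params(4)
  set.seed(5)
  Fp <- matrix(rnorm(3 * 64), 3, 64)
  Fd <- matrix(rnorm(4 * 64), 4, 64)
  Ad <- matrix(0, 4, 4)
  Ad[cbind(c(1, 2, 2, 3, 3, 4), c(2, 1, 3, 2, 4, 3))] <- 1
  out <- fusion_round(Fp, Fd, Ad, p)
  orc <- oracle_fusion_round(Fp, Fd, Ad, p)
  expect_equal(out$Fp, orc$Fp, tolerance = 1e-5)
  expect_equal(out$Fd, orc$Fd, tolerance = 1e-5)
  expect_equal(out$C, orc$C, tolerance = 1e-6)
  expect_equal(dim(out$Fp), dim(Fp))
  expect_equal(dim(out$Fd), dim(Fd))
})

test_that("zero transforms make any number of rounds a residual identity", {
  p <- seeded_fusion_params(6)
  p$Wp <- p$Wp * 0; p$bp <- p$bp * 0
  p$Wd <- p$Wd * 0; p$bd <- p$bd * 0
  p$K <- p$K * 0;  p$kb <- p$kb * 0
  set.seed(7)
  Fp <- matrix(rnorm(5 * 64), 5, 64)
  Fd <- matrix(rnorm(3 * 64), 3, 64)
  Ad <- diag(0, 3)
  cur <- list(Fp = Fp, Fd = Fd)
  for (r in 1:4) {
    cur <- fusion_round(cur$Fp, cur$Fd, Ad, p)
    expect_equal(cur$Fp, Fp, tolerance = 1e-12)
    expect_equal(cur$Fd, Fd, tolerance = 1e-12)
  }
})

test_that("row-stochasticity of C is preserved across recomputed rounds", {
  p <- seeded_fusion_params(8)
  set.seed(9)
  Fp <- matrix(rnorm(4 * 64), 4, 64)
  Fd <- matrix(rnorm(5 * 64), 5, 64)
  Ad <- matrix(0, 5, 5)
  for (r in 1:3) {
    out <- fusion_round(Fp, Fd, Ad, p)
    expect_equal(rowSums(out$C), rep(1, 4), tolerance = 1e-6)
    Fp <- out$Fp
    Fd <- out$Fd
  }
})

test_that("fuse produces 64 values and composes fusion_round + pooling", {
  p <- seeded_fusion_params(10, n_rounds = 1)
  set.seed(11)
  Fp <- matrix(rnorm(6 * 64), 6, 64)
  Fd <- matrix(rnorm(4 * 64), 4, 64)
  Ad <- matrix(0, 4, 4); Ad[1, 2] <- Ad[2, 1] <- 1
  fs <- fuse(Fp, Fd, Ad, p, n_rounds = 1)
  expect_length(fs, 64L)
  r1 <- fusion_round(Fp, Fd, Ad, p)
  manual <- as.vector(c(colMeans(r1$Fp), colMeans(r1$Fd)) %*% p$Wout) + p$bout
  expect_equal(fs, manual, tolerance = 1e-10)
})

test_that("fused vector is invariant to consistent atom relabeling", {
  p <- seeded_fusion_params(12)
  set.seed(13)
  Fp <- matrix(rnorm(5 * 64), 5, 64)
  Fd <- matrix(rnorm(6 * 64), 6, 64)
  Ad <- matrix(0, 6, 6)
  Ad[cbind(1:5, 2:6)] <- 1; Ad <- Ad + t(Ad)
  perm <- sample(6)
  inv <- order(perm)
  fs <- fuse(Fp, Fd, Ad, p, n_rounds = 2)
  fsp <- fuse(Fp, Fd[inv, ], Ad[inv, inv], p, n_rounds = 2)
  expect_equal(fsp, fs, tolerance = 1e-6)
})

test_that("cat baseline is pool-concat-project, independent of adjacency", {
  p <- seeded_fusion_params(14)
  set.seed(15)
  Fp <- matrix(rnorm(4 * 64), 4, 64)
  Fd <- matrix(rnorm(3 * 64), 3, 64)
  fs <- fuse_cat_baseline(Fp, Fd, p)
  # hand-computed pooled concatenation
  z <- numeric(128)
  for (c in 1:64) z[c] <- mean(Fp[, c])
  for (c in 1:64) z[64 + c] <- mean(Fd[, c])
  manual <- as.vector(z %*% p$Wout) + p$bout
  expect_equal(fs, manual, tolerance = 1e-10)
  # equals fuse with zero rounds (no graph term anywhere)
  expect_equal(fs, fuse(Fp, Fd, matrix(0, 3, 3), p, n_rounds = 0),
               tolerance = 1e-12)
})

test_that("padded protein rows never influence the fused vector", {
  p <- seeded_fusion_params(16)
  set.seed(17)
  Fp <- matrix(rnorm(5 * 64), 5, 64)
  Fd <- matrix(rnorm(4 * 64), 4, 64)
  Ad <- matrix(0, 4, 4); Ad[1, 2] <- Ad[2, 1] <- 1
  fs <- fuse(Fp, Fd, Ad, p, n_rounds = 2, mask = rep(1, 5))
  for (extra in c(1, 3)) {
    Fp_pad <- rbind(Fp, matrix(0, extra, 64))
    mask <- c(rep(1, 5), rep(0, extra))
    fs_pad <- fuse(Fp_pad, Fd, Ad, p, n_rounds = 2, mask = mask)
    expect_equal(fs_pad, fs, tolerance = 1e-6)
  }
  # masked association rows are zero
  C <- compute_association(rbind(Fp, matrix(0, 2, 64)), Fd,
                           mask = c(rep(1, 5), 0, 0))
  expect_equal(C[6:7, ], matrix(0, 2, 4))
})

test_that("frozen association reuses the round-1 matrix", {
  p <- seeded_fusion_params(18)
  set.seed(19)
  Fp <- matrix(rnorm(3 * 64), 3, 64)
  Fd <- matrix(rnorm(3 * 64), 3, 64)
  Ad <- matrix(0, 3, 3)
  f_frozen <- mpff:::fusion_forward(Fp, Fd, Ad, p, n_rounds = 2,
                                    freeze_association = TRUE)
  C1 <- f_frozen$cache$caches[[1]]$C
  C2 <- f_frozen$cache$caches[[2]]$C
  expect_identical(C1, C2)
  f_recomp <- mpff:::fusion_forward(Fp, Fd, Ad, p, n_rounds = 2)
  expect_false(isTRUE(all.equal(f_recomp$cache$caches[[2]]$C, C1)))
})
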
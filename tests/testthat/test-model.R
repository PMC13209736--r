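# End-to-end model: forward determinism, head stack, classification,
# loss, and analytic-vs-numeric gradients.

test_that("inference is deterministic and training dropout is not a no-op", {
  emb <- fixture_protein()
  g <- featurize_molecule("NC(=O)c1ccccc1")
  m <- mpff_model(mpff_config(seed = 3))
  z1 <- model_forward(m, emb, g, training = FALSE)
  z2 <- model_forward(m, emb, g, training = FALSE)
  expect_identical(z1, z2)
  set.seed(1)
  zt1 <- model_forward(m, emb, g, training = TRUE)
  zt2 <- model_forward(m, emb, g, training = TRUE)
  expect_false(identical(zt1, zt2))  # different dropout masks
})

test_that("an all-zero head outputs its final bias", {
  emb <- fixture_protein()
  g <- featurize_molecule("CCO")
  m <- mpff_model(mpff_config(seed = 4))
  m$params$head <- lapply(m$params$head, function(l) {
    list(W = l$W * 0, b = l$b * 0)
  })
  m$params$head[[4]]$b <- 1.25
  expect_equal(model_forward(m, emb, g), 1.25)
})

test_that("the head stack matches a straight-line reimplementation", {
  m <- mpff_model(mpff_config(seed = 5))
  set.seed(6)
  x <- rnorm(64)
  out <- mpff:::head_forward(x, m$params$head)$out
  h <- x
  for (k in 1:3) {
    h <- pmax(as.vector(h %*% m$params$head[[k]]$W) + m$params$head[[k]]$b, 0)
  }
  z <- as.vector(h %*% m$params$head[[4]]$W) + m$params$head[[4]]$b
  expect_equal(as.vector(out), z, tolerance = 1e-5)
})

test_that("classification applies sigmoid with a strict 0.5 cutoff", {
  res <- classify(c(0, 10, -3))
  expect_equal(res$probability[1], 0.5)
  expect_equal(res$label[1], 0L)      # exactly 0.5 is inactive
  expect_equal(res$label[2], 1L)
  expect_equal(res$probability[3], 1 / (1 + exp(3)), tolerance = 1e-9)
  expect_equal(res$probability[3], 0.04742587, tolerance = 1e-7)
  expect_error(classify(c(1, NaN)), "finite")
  expect_error(classify(Inf), "finite")
})

test_that("BCE-with-logits matches analytic values and stays finite", {
  expect_equal(bce_with_logits(0, 1), log(2), tolerance = 1e-9)
  expect_equal(bce_with_logits(-2, 0), log1p(exp(-2)), tolerance = 1e-9)
  expect_lt(bce_with_logits(30, 1), 1e-12)
  expect_true(is.finite(bce_with_logits(c(1e4, -1e4), c(0, 1))))
  expect_error(bce_with_logits(c(0, 0), c(0, 2)), "0 or 1")
  # label-flip symmetry
  set.seed(7)
  z <- rnorm(20, sd = 3)
  y <- rbinom(20, 1, 0.5)
  expect_equal(bce_with_logits(z, y), bce_with_logits(-z, 1 - y),
               tolerance = 1e-12)
})

test_that("analytic gradients agree with central finite differences", {
  emb <- fixture_protein(length = 12)
  g <- featurize_molecule("NC(=O)c1ccc(F)cc1")
  m <- mpff_model(mpff_config(seed = 8, fusion_rounds = 2))
  y <- 1
  fw <- mpff:::model_forward_cache(m, emb, g, training = FALSE)
  gr <- mpff:::model_backward(mpff:::stable_sigmoid(fw$logit) - y,
                              fw$cache, m)
  loss_at <- function(model) {
    z <- mpff:::model_forward_cache(model, emb, g, training = FALSE)$logit
    max(z, 0) - z * y + log1p(exp(-abs(z)))
  }
  eps <- 1e-5
  set.seed(9)
  blocks <- list(
    c("proj", "W1"), c("proj", "W2"), c("proj", "b2"),
    c("mpnn", "Win"), c("mpnn", "We1"), c("mpnn", "We2"), c("mpnn", "be2"),
    c("fusion", "Wp"), c("fusion", "Wd"), c("fusion", "K"),
    c("fusion", "kb"), c("fusion", "Wout")
  )
  for (b in blocks) {
    mat <- m$params[[b[1]]][[b[2]]]
    gmat <- gr[[b[1]]][[b[2]]]
    for (i in sample(length(mat), 4)) {
      m2 <- m
      m2$params[[b[1]]][[b[2]]][i] <- mat[i] + eps
      lp <- loss_at(m2)
      m2$params[[b[1]]][[b[2]]][i] <- mat[i] - eps
      lm <- loss_at(m2)
      num <- (lp - lm) / (2 * eps)
      expect_equal(gmat[i], num, tolerance = 1e-3,
                   label = paste("grad", b[1], b[2], i))
    }
  }
  # head layers
  for (k in c(1L, 4L)) {
    mat <- m$params$head[[k]]$W
    for (i in sample(length(mat), 4)) {
      m2 <- m
      m2$params$head[[k]]$W[i] <- mat[i] + eps
      lp <- loss_at(m2)
      m2$params$head[[k]]$W[i] <- mat[i] - eps
      lm <- loss_at(m2)
      expect_equal(gr$head[[k]]$W[i], (lp - lm) / (2 * eps),
                   tolerance = 1e-3, label = paste("grad head", k, i))
    }
  }
})

test_that("the cat configuration ignores fusion rounds entirely", {
  emb <- fixture_protein()
  g <- featurize_molecule("CCO")
  m_cat <- mpff_model(mpff_config(seed = 10, fusion_mode = "cat"))
  z <- model_forward(m_cat, emb, g)
  # manual: pooled projection + pooled atom states -> output projection -> head
  Fp <- project_protein(emb, m_cat$params$proj, training = FALSE)
  Fd <- mpff:::mpnn_forward(g, m_cat$params$mpnn)$Fd
  fs <- fuse_cat_baseline(Fp, Fd, m_cat$params$fusion)
  manual <- as.vector(mpff:::head_forward(fs, m_cat$params$head)$out)
  expect_equal(z, manual, tolerance = 1e-12)
})

test_that("checkpoints reproduce inference exactly", {
  emb <- fixture_protein()
  g <- featurize_molecule("Cc1ccncc1")
  m <- mpff_model(mpff_config(seed = 11))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(model_forward(m, emb, g), model_forward(m2, emb, g))
})
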
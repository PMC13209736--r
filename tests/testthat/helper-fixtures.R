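# Shared fixtures and independent oracles.
#
# The oracle implementations below are deliberately written as explicit
# elementwise loops, independent of the vectorized package code paths
# they are used to check.

# Random molecular-graph stand-in (no chemistry backend involved):
# a random connected graph with random 74-dim atom features and bond
# features drawn from a small set of distinct 12-dim rows.
make_random_graph <- function(n_atoms, seed = 1, n_bond_types = 3) {
  set.seed(seed)
  af <- matrix(stats::rnorm(n_atoms * 74), n_atoms, 74)
  bonds <- list()
  if (n_atoms > 1) {
    for (i in 2:n_atoms) bonds[[length(bonds) + 1]] <- c(sample(i - 1, 1), i)
    extra <- max(0, n_atoms - 3)
    for (k in seq_len(extra)) {
      ij <- sample(n_atoms, 2)
      bonds[[length(bonds) + 1]] <- sort(ij)
    }
    bonds <- unique(bonds)
  }
  btypes <- matrix(stats::rnorm(n_bond_types * 12), n_bond_types, 12)
  edges <- matrix(integer(), 0, 2)
  bf <- matrix(numeric(), 0, 12)
  for (b in bonds) {
    row <- btypes[sample(n_bond_types, 1), ]
    edges <- rbind(edges, c(b[1], b[2]), c(b[2], b[1]))
    bf <- rbind(bf, row, row)
  }
  mpff:::new_mol_graph(n_atoms, af, edges, bf)
}

# Linear path graph (atoms 1-2-3-...-n), single bond type.
make_path_graph <- function(n_atoms, seed = 1) {
  set.seed(seed)
  af <- matrix(stats::rnorm(n_atoms * 74), n_atoms, 74)
  brow <- stats::rnorm(12)
  edges <- matrix(integer(), 0, 2)
  bf <- matrix(numeric(), 0, 12)
  if (n_atoms > 1) {
    for (i in seq_len(n_atoms - 1)) {
      edges <- rbind(edges, c(i, i + 1), c(i + 1, i))
      bf <- rbind(bf, brow, brow)
    }
  }
  mpff:::new_mol_graph(n_atoms, af, edges, bf)
}

# Relabel the atoms of a graph by a permutation (perm[i] = new index of
# old atom i).
permute_graph <- function(graph, perm) {
  inv <- order(perm)
  af <- graph$atom_features[inv, , drop = FALSE]
  edges <- graph$edges
  if (nrow(edges) > 0) {
    edges <- cbind(perm[edges[, 1]], perm[edges[, 2]])
  }
  mpff:::new_mol_graph(graph$num_atoms, af, edges, graph$bond_features)
}

seeded_mpnn_params <- function(seed = 1, rounds = 6, edge_hidden = 8) {
  set.seed(seed)
  mpnn_params(rounds = rounds, edge_hidden = edge_hidden)
}

seeded_fusion_params <- function(seed = 1, n_rounds = 2) {
  set.seed(seed)
  fusion_params(n_rounds = n_rounds)
}

# ---- independent oracles -------------------------------------------------

# Message matrices via explicit per-edge evaluation of the edge network.
oracle_edge_matrices <- function(graph, params) {
  ne <- nrow(graph$edges)
  out <- vector("list", ne)
  for (e in seq_len(ne)) {
    b <- graph$bond_features[e, ]
    h1 <- pmax(as.vector(b %*% params$We1) + params$be1, 0)
    m <- as.vector(h1 %*% params$We2) + params$be2
    out[[e]] <- matrix(m, 64, 64)
  }
  out
}

# One residual message round with explicit loops over edges.
oracle_message_round <- function(h, graph, params) {
  Ms <- oracle_edge_matrices(graph, params)
  out <- h
  for (e in seq_len(nrow(graph$edges))) {
    j <- graph$edges[e, 1]
    i <- graph$edges[e, 2]
    out[i, ] <- out[i, ] + as.vector(Ms[[e]] %*% h[j, ])
  }
  out
}

# Row softmax of Fp %*% t(Fd) with explicit loops.
oracle_association <- function(Fp, Fd) {
  Lp <- nrow(Fp); Ld <- nrow(Fd)
  C <- matrix(0, Lp, Ld)
  for (i in seq_len(Lp)) {
    s <- numeric(Ld)
    for (j in seq_len(Ld)) s[j] <- sum(Fp[i, ] * Fd[j, ])
    e <- exp(s - max(s))
    C[i, ] <- e / sum(e)
  }
  C
}

# Depthwise length-3 convolution with an explicit sliding window.
oracle_dwc <- function(X, K, kb) {
  L <- nrow(X); nc <- ncol(X)
  out <- matrix(0, L, nc)
  for (i in seq_len(L)) {
    for (c in seq_len(nc)) {
      acc <- kb[c]
      if (i > 1) acc <- acc + K[1, c] * X[i - 1, c]
      acc <- acc + K[2, c] * X[i, c]
      if (i < L) acc <- acc + K[3, c] * X[i + 1, c]
      out[i, c] <- acc
    }
  }
  out
}

# One fusion round as straight dense matrix algebra.
oracle_fusion_round <- function(Fp, Fd, Ad, params) {
  omega <- function(X, W, b) {
    A <- X %*% W
    for (i in seq_len(nrow(A))) A[i, ] <- pmax(A[i, ] + b, 0)
    A
  }
  Gp <- omega(Fp, params$Wp, params$bp)
  Gd <- omega(Fd, params$Wd, params$bd)
  C <- oracle_association(Fp, Fd)
  Fp_out <- oracle_dwc(Gp, params$K, params$kb) + C %*% Gd + Fp
  Fd_out <- t(C) %*% Gp + Ad %*% Gd + Fd
  list(Fp = Fp_out, Fd = Fd_out, C = C)
}

# Confusion-table metrics via direct formula evaluation (no zero-guard
# shortcuts shared with the implementation).
oracle_metrics <- function(tp, tn, fp, fn) {
  div0 <- function(num, den) if (den == 0) 0 else num / den
  prec <- div0(tp, tp + fp)
  rec <- div0(tp, tp + fn)
  spec <- div0(tn, tn + fp)
  f1 <- div0(2 * prec * rec, prec + rec)
  den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
  list(accuracy = (tp + tn) / (tp + tn + fp + fn), precision = prec,
       recall = rec, specificity = spec, f1 = f1, mcc = mcc)
}

# AUC by O(P*N) pairwise counting.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# A small shared protein for model-level tests.
fixture_protein <- function(length = 25, seed = 42) {
  encode_onehot(generate_protein(length, seed = seed, id = "fixture"))
}
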
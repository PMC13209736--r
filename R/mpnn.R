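# Edge-conditioned message-passing encoder for molecular graphs.
#
# Atom states start from a ReLU-activated affine map of the 74-dim atom
# features into 64 dimensions. Each round then performs the residual
# update
#     h_i <- h_i + sum_{j in N(i)} M(e_ij) h_j
# where M(e_ij) is a 64 x 64 matrix produced from the 12-dim bond
# features by a small edge network. One edge network and one update are
# shared across all rounds (six by default). Molecules have few distinct
# bond-feature vectors, so M is evaluated once per distinct bond type
# and reused for every edge carrying it.

MPNN_DIM <- 64L

#' MPNN parameters
#'
#' @param rounds number of message-passing rounds (default 6).
#' @param edge_hidden hidden width of the edge network mapping bond
#'   features to 64 x 64 message matrices.
#' @return named list: input transform (74 -> 64), edge network
#'   (12 -> edge_hidden -> 4096), readout transform (64 -> 64), rounds.
#' @export
mpnn_params <- function(rounds = 6L, edge_hidden = 16L) {
  stopifnot(rounds >= 0L, edge_hidden >= 1L)
  d <- MPNN_DIM
  list(
    Win = init_weight(74L, d), bin = numeric(d),
    We1 = init_weight(12L, edge_hidden), be1 = numeric(edge_hidden),
    # damped output so six residual rounds keep states well-scaled
    We2 = init_weight(edge_hidden, d * d, gain = 0.02), be2 = numeric(d * d),
    Wr = init_weight(d, d), br = numeric(d),
    rounds = rounds
  )
}

# Distinct bond-feature rows and the per-edge index into them.
bond_groups <- function(graph) {
  bf <- graph$bond_features
  if (nrow(bf) == 0L) {
    return(list(unique = matrix(numeric(), 0L, 12L), index = integer()))
  }
  key <- apply(bf, 1L, paste, collapse = ",")
  ukey <- unique(key)
  list(unique = bf[match(ukey, key), , drop = FALSE],
       index = match(key, ukey))
}

# Edge network: U x 12 bond features -> list of U message matrices
# (returned flat as U x 4096, column-major per matrix).
edge_network_forward <- function(B, params) {
  if (nrow(B) == 0L) {
    return(list(M = matrix(numeric(), 0L, MPNN_DIM^2), A1 = NULL, H1 = NULL))
  }
  A1 <- sweep(B %*% params$We1, 2L, params$be1, `+`)
  H1 <- relu(A1)
  M <- sweep(H1 %*% params$We2, 2L, params$be2, `+`)
  list(M = M, A1 = A1, H1 = H1)
}

#' Initialize atom states
#'
#' h0 = ReLU(affine(atom_features)): the linear lift of the 74-dim atom
#' features into the 64-dim state space, before any message passing.
#'
#' @param graph a `mol_graph`.
#' @param params MPNN parameters.
#' @return num_atoms x 64 matrix.
#' @export
init_node_states <- function(graph, params) {
  stopifnot(ncol(graph$atom_features) == 74L)
  relu(sweep(graph$atom_features %*% params$Win, 2L, params$bin, `+`))
}

# One residual message-passing round given precomputed message matrices.
mp_round <- function(h, graph, groups, Mlist) {
  if (nrow(graph$edges) == 0L) return(h)
  src <- graph$edges[, 1L]
  dst <- graph$edges[, 2L]
  msg <- matrix(0, length(src), MPNN_DIM)
  Hsrc <- h[src, , drop = FALSE]
  for (u in seq_along(Mlist)) {
    rows <- which(groups$index == u)
    msg[rows, ] <- Hsrc[rows, , drop = FALSE] %*% t(Mlist[[u]])
  }
  agg <- matrix(0, nrow(h), MPNN_DIM)
  rs <- rowsum(msg, group = dst)
  agg[as.integer(rownames(rs)), ] <- rs
  h + agg
}

#' One message-passing round
#'
#' Residual update h_i + sum over incoming directed edges of
#' M(e_ij) h_j. Atoms with no neighbors pass through unchanged.
#'
#' @param h num_atoms x 64 state matrix.
#' @param graph a `mol_graph`.
#' @param params MPNN parameters.
#' @return updated num_atoms x 64 state matrix.
#' @export
message_pass_round <- function(h, graph, params) {
  groups <- bond_groups(graph)
  en <- edge_network_forward(groups$unique, params)
  Mlist <- lapply(seq_len(nrow(en$M)), function(u) {
    matrix(en$M[u, ], MPNN_DIM, MPNN_DIM)
  })
  mp_round(h, graph, groups, Mlist)
}

mpnn_forward <- function(graph, params) {
  A0 <- sweep(graph$atom_features %*% params$Win, 2L, params$bin, `+`)
  h <- relu(A0)
  groups <- bond_groups(graph)
  en <- edge_network_forward(groups$unique, params)
  Mlist <- lapply(seq_len(nrow(en$M)), function(u) {
    matrix(en$M[u, ], MPNN_DIM, MPNN_DIM)
  })
  hs <- vector("list", params$rounds + 1L)
  hs[[1L]] <- h
  if (params$rounds > 0L) {
    for (l in seq_len(params$rounds)) {
      h <- mp_round(h, graph, groups, Mlist)
      hs[[l + 1L]] <- h
    }
  }
  list(Fd = h, cache = list(A0 = A0, hs = hs, groups = groups, en = en,
                            Mlist = Mlist))
}

# Backward through the shared-weight rounds and the edge network.
# dFd: gradient w.r.t. the final atom states.
mpnn_backward <- function(dFd, cache, graph, params) {
  d <- MPNN_DIM
  eh <- ncol(params$We1)
  grads <- list(Win = matrix(0, 74L, d), bin = numeric(d),
                We1 = matrix(0, 12L, eh), be1 = numeric(eh),
                We2 = matrix(0, eh, d * d), be2 = numeric(d * d),
                Wr = matrix(0, d, d), br = numeric(d),
                rounds = 0)
  dh <- dFd
  U <- length(cache$Mlist)
  dM <- if (U > 0L) matrix(0, U, d * d) else matrix(numeric(), 0L, d * d)
  ne <- nrow(graph$edges)
  if (ne > 0L && params$rounds > 0L) {
    src <- graph$edges[, 1L]
    dst <- graph$edges[, 2L]
    for (l in rev(seq_len(params$rounds))) {
      h_in <- cache$hs[[l]]
      dmsg <- dh[dst, , drop = FALSE]
      Hsrc <- h_in[src, , drop = FALSE]
      dHsrc <- matrix(0, ne, d)
      for (u in seq_len(U)) {
        rows <- which(cache$groups$index == u)
        Mu <- cache$Mlist[[u]]
        dHsrc[rows, ] <- dmsg[rows, , drop = FALSE] %*% Mu
        dMu <- t(dmsg[rows, , drop = FALSE]) %*% Hsrc[rows, , drop = FALSE]
        dM[u, ] <- dM[u, ] + as.vector(dMu)
      }
      rs <- rowsum(dHsrc, group = src)
      dh_src <- matrix(0, nrow(h_in), d)
      dh_src[as.integer(rownames(rs)), ] <- rs
      dh <- dh + dh_src
    }
  }
  # initialization backward
  dA0 <- dh * (cache$A0 > 0)
  grads$Win <- t(graph$atom_features) %*% dA0
  grads$bin <- colSums(dA0)
  # edge network backward
  if (U > 0L) {
    en <- cache$en
    grads$We2 <- t(en$H1) %*% dM
    grads$be2 <- colSums(dM)
    dH1 <- dM %*% t(params$We2)
    dA1 <- dH1 * (en$A1 > 0)
    grads$We1 <- t(cache$groups$unique) %*% dA1
    grads$be1 <- colSums(dA1)
  }
  grads
}

#' Encode a molecule (or a batch)
#'
#' Runs initialization plus the configured number of message-passing
#' rounds (weights shared across rounds) and aggregates a fixed-length
#' compound vector: the mean over atom states followed by an affine
#' readout to 64 dimensions. Mean readout makes the compound vector
#' invariant to atom relabeling.
#'
#' @param graph a `mol_graph` or `mol_graph_batch`.
#' @param params MPNN parameters.
#' @return list with `atom_states` (num_atoms x 64 final states) and
#'   `compound_vector` (length-64 vector; for a batch, an n_graphs x 64
#'   matrix with one row per molecule).
#' @export
encode_molecule <- function(graph, params) {
  fw <- mpnn_forward(graph, params)
  if (inherits(graph, "mol_graph_batch")) {
    pooled <- rowsum(fw$Fd, group = graph$membership) / graph$sizes
    cv <- sweep(pooled %*% params$Wr, 2L, params$br, `+`)
  } else {
    pooled <- colMeans(fw$Fd)
    cv <- as.vector(pooled %*% params$Wr) + params$br
  }
  list(atom_states = fw$Fd, compound_vector = cv)
}
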
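# Cross-coupled protein-compound feature fusion.
#
# The residue-level protein features Fp (Lp x 64) and atom-level compound
# features Fd (Ld x 64) are coupled through a row-stochastic association
# matrix C = softmax(Fp Fd^T) (softmax over atoms, per residue). Each
# fusion round applies the residual updates
#     Fp <- DWC(w_p(Fp)) + C  w_d(Fd) + Fp
#     Fd <- C^T w_p(Fp) + A_d w_d(Fd) + Fd
# where w_* are shared affine+ReLU maps, DWC is a per-channel length-3
# convolution along the residue axis (the protein's stand-in adjacency
# operator), and A_d is the molecular adjacency. After N rounds both
# streams are mean-pooled, concatenated (128) and projected to the
# 64-dim fused vector consumed by the prediction head.

#' Fusion parameters
#'
#' @param n_rounds default number of fusion rounds stored with the
#'   parameters (2 unless overridden at call time).
#' @return named list: omega_p / omega_d affine 64 -> 64 weights, the
#'   depthwise kernel (3 x 64) and bias, and the 128 -> 64 output
#'   projection.
#' @export
fusion_params <- function(n_rounds = 2L) {
  d <- 64L
  list(Wp = init_weight(d, d, gain = 0.5), bp = numeric(d),
       Wd = init_weight(d, d, gain = 0.5), bd = numeric(d),
       K = matrix(stats::rnorm(3L * d, sd = 0.3), 3L, d), kb = numeric(d),
       Wout = init_weight(2L * d, d), bout = numeric(d),
       n_rounds = n_rounds)
}

row_softmax <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

#' Protein-compound association matrix
#'
#' C = row-wise softmax of Fp Fd^T: each residue distributes one unit of
#' attention over the compound's atoms, so C w_d(Fd) is a convex
#' combination of transformed atom features per residue. Masked
#' (padding) protein rows produce all-zero rows.
#'
#' @param Fp Lp x 64 protein features.
#' @param Fd Ld x 64 compound features.
#' @param mask optional 0/1 vector over protein rows.
#' @return Lp x Ld matrix; unmasked rows are nonnegative and sum to 1.
#' @export
compute_association <- function(Fp, Fd, mask = NULL) {
  stopifnot(is.matrix(Fp), is.matrix(Fd))
  if (ncol(Fp) != ncol(Fd)) {
    stop("feature width mismatch: ", ncol(Fp), " vs ", ncol(Fd))
  }
  C <- row_softmax(Fp %*% t(Fd))
  if (!is.null(mask)) C <- C * mask
  C
}

dwc_apply <- function(X, K, kb) {
  L <- nrow(X)
  up <- if (L > 1L) rbind(0, X[-L, , drop = FALSE]) else X * 0   # X[i-1]
  dn <- if (L > 1L) rbind(X[-1L, , drop = FALSE], 0) else X * 0  # X[i+1]
  sweep(up * rep(K[1L, ], each = L) + X * rep(K[2L, ], each = L) +
          dn * rep(K[3L, ], each = L), 2L, kb, `+`)
}

#' Depthwise convolution along the residue axis
#'
#' Per-channel 1D convolution with a length-3 kernel, stride 1 and zero
#' padding 1, so the output length equals the input length and channels
#' are never mixed. This captures relationships between adjacent
#' residues, acting as the protein's local adjacency operator.
#'
#' @param X Lp x 64 matrix.
#' @param params fusion parameters (uses `K`, 3 x 64, and bias `kb`).
#' @return Lp x 64 matrix.
#' @export
depthwise_conv_protein <- function(X, params) {
  stopifnot(is.matrix(X), ncol(X) == ncol(params$K))
  dwc_apply(X, params$K, params$kb)
}

dwc_backward <- function(dD, Xin, K) {
  L <- nrow(dD)
  up <- if (L > 1L) rbind(0, dD[-L, , drop = FALSE]) else dD * 0  # dD[i-1]
  dn <- if (L > 1L) rbind(dD[-1L, , drop = FALSE], 0) else dD * 0 # dD[i+1]
  dX <- dn * rep(K[1L, ], each = L) + dD * rep(K[2L, ], each = L) +
    up * rep(K[3L, ], each = L)
  Xup <- if (L > 1L) rbind(0, Xin[-L, , drop = FALSE]) else Xin * 0
  Xdn <- if (L > 1L) rbind(Xin[-1L, , drop = FALSE], 0) else Xin * 0
  gK <- rbind(colSums(dD * Xup), colSums(dD * Xin), colSums(dD * Xdn))
  list(dX = dX, gK = gK, gkb = colSums(dD))
}

fusion_round_forward <- function(Fp, Fd, Ad, params, mask = NULL, C = NULL) {
  Ap_pre <- sweep(Fp %*% params$Wp, 2L, params$bp, `+`)
  Gp <- relu(Ap_pre)
  if (!is.null(mask)) Gp <- Gp * mask
  Ad_pre <- sweep(Fd %*% params$Wd, 2L, params$bd, `+`)
  Gd <- relu(Ad_pre)
  C_computed <- is.null(C)
  if (C_computed) C <- compute_association(Fp, Fd, mask)
  D <- dwc_apply(Gp, params$K, params$kb)
  if (!is.null(mask)) D <- D * mask
  Fp_out <- D + C %*% Gd + Fp
  Fd_out <- t(C) %*% Gp + Ad %*% Gd + Fd
  list(Fp = Fp_out, Fd = Fd_out, C = C,
       cache = list(Fp_in = Fp, Fd_in = Fd, Ap_pre = Ap_pre, Gp = Gp,
                    Ad_pre = Ad_pre, Gd = Gd, C = C,
                    C_computed = C_computed))
}

#' One fusion round
#'
#' Applies the residual cross-updates once, recomputing the association
#' matrix from the current features at the start of the round (pass `C`
#' to reuse a frozen association instead).
#'
#' @param Fp Lp x 64 protein features.
#' @param Fd Ld x 64 compound features.
#' @param Ad Ld x Ld molecular adjacency.
#' @param params fusion parameters.
#' @param mask optional 0/1 protein padding mask.
#' @param C optional precomputed association matrix.
#' @return list with updated `Fp`, `Fd` and the association matrix `C`
#'   used.
#' @export
fusion_round <- function(Fp, Fd, Ad, params, mask = NULL, C = NULL) {
  stopifnot(ncol(Fp) == ncol(Fd), nrow(Ad) == nrow(Fd))
  out <- fusion_round_forward(Fp, Fd, Ad, params, mask = mask, C = C)
  out[c("Fp", "Fd", "C")]
}

fusion_forward <- function(Fp0, Fd0, Ad, params, n_rounds = NULL,
                           mask = NULL, freeze_association = FALSE) {
  if (is.null(n_rounds)) n_rounds <- params$n_rounds
  Fp <- if (!is.null(mask)) Fp0 * mask else Fp0
  Fd <- Fd0
  caches <- vector("list", n_rounds)
  C <- NULL
  if (n_rounds > 0L) {
    for (r in seq_len(n_rounds)) {
      step <- fusion_round_forward(Fp, Fd, Ad, params, mask = mask,
                                   C = if (freeze_association) C else NULL)
      caches[[r]] <- step$cache
      Fp <- step$Fp
      Fd <- step$Fd
      C <- step$C
    }
  }
  fpbar <- pool_protein(Fp, mask)
  fdbar <- colMeans(Fd)
  z <- c(fpbar, fdbar)
  fs <- as.vector(z %*% params$Wout) + params$bout
  list(fs = fs,
       cache = list(caches = caches, z = z, mask = mask, n_rounds = n_rounds,
                    Lp = nrow(Fp0), Ld = nrow(Fd0), Ad = Ad,
                    freeze_association = freeze_association))
}

fusion_zero_grads <- function(params) {
  g <- zeros_like(params)
  g$n_rounds <- 0
  g
}

fusion_backward <- function(dfs, cache, params) {
  grads <- fusion_zero_grads(params)
  z <- cache$z
  grads$Wout <- outer(z, dfs)
  grads$bout <- dfs
  dz <- as.vector(params$Wout %*% dfs)
  d <- length(dfs)
  dfpbar <- dz[seq_len(d)]
  dfdbar <- dz[d + seq_len(d)]
  mask <- cache$mask
  Lp <- cache$Lp
  Ld <- cache$Ld
  if (is.null(mask)) {
    dFp <- matrix(dfpbar, Lp, d, byrow = TRUE) / Lp
  } else {
    dFp <- (matrix(dfpbar, Lp, d, byrow = TRUE) * mask) / sum(mask)
  }
  dFd <- matrix(dfdbar, Ld, d, byrow = TRUE) / Ld
  Ad <- cache$Ad
  dC_frozen <- NULL
  if (cache$n_rounds > 0L) {
    for (r in rev(seq_len(cache$n_rounds))) {
      cc <- cache$caches[[r]]
      dD <- if (is.null(mask)) dFp else dFp * mask
      dC <- dFp %*% t(cc$Gd) + cc$Gp %*% t(dFd)
      dGd <- t(cc$C) %*% dFp + t(Ad) %*% dFd
      dGp <- cc$C %*% dFd
      dFp_in <- dFp   # residual
      dFd_in <- dFd   # residual
      dw <- dwc_backward(dD, cc$Gp, params$K)
      dGp <- dGp + dw$dX
      grads$K <- grads$K + dw$gK
      grads$kb <- grads$kb + dw$gkb
      # association backward (only where C was computed this round)
      if (cc$C_computed) {
        if (!is.null(dC_frozen)) dC <- dC + dC_frozen
        dS <- cc$C * (dC - rowSums(dC * cc$C))
        dFp_in <- dFp_in + dS %*% cc$Fd_in
        dFd_in <- dFd_in + t(dS) %*% cc$Fp_in
        dC_frozen <- NULL
      } else {
        dC_frozen <- if (is.null(dC_frozen)) dC else dC_frozen + dC
      }
      # omega_p backward (Gp masked after ReLU)
      dAp <- dGp * (cc$Ap_pre > 0)
      if (!is.null(mask)) dAp <- dAp * mask
      grads$Wp <- grads$Wp + t(cc$Fp_in) %*% dAp
      grads$bp <- grads$bp + colSums(dAp)
      dFp_in <- dFp_in + dAp %*% t(params$Wp)
      # omega_d backward
      dAdp <- dGd * (cc$Ad_pre > 0)
      grads$Wd <- grads$Wd + t(cc$Fd_in) %*% dAdp
      grads$bd <- grads$bd + colSums(dAdp)
      dFd_in <- dFd_in + dAdp %*% t(params$Wd)
      dFp <- dFp_in
      dFd <- dFd_in
    }
  }
  if (!is.null(mask)) dFp <- dFp * mask
  list(grads = grads, dFp0 = dFp, dFd0 = dFd)
}

#' Fuse protein and compound representations
#'
#' Applies `n_rounds` fusion rounds, mean-pools the refined protein
#' features (mask-aware) and compound features, concatenates to 128 and
#' projects to the 64-dim fused representation. With `n_rounds = 0` this
#' degenerates to pool-concat-project, the "cat" ablation.
#'
#' @param Fp0 Lp x 64 projected protein features.
#' @param Fd0 Ld x 64 MPNN atom states.
#' @param Ad Ld x Ld molecular adjacency.
#' @param params fusion parameters.
#' @param n_rounds number of rounds (default: stored in `params`).
#' @param mask optional 0/1 protein padding mask.
#' @param freeze_association if TRUE the association matrix computed in
#'   round 1 is reused in later rounds instead of being recomputed.
#' @return length-64 fused feature vector.
#' @export
fuse <- function(Fp0, Fd0, Ad, params, n_rounds = NULL, mask = NULL,
                 freeze_association = FALSE) {
  fusion_forward(Fp0, Fd0, Ad, params, n_rounds = n_rounds, mask = mask,
                 freeze_association = freeze_association)$fs
}

#' Concatenation baseline fusion
#'
#' The ablation "cat" mode: mean-pool both inputs, concatenate, project.
#' No cross-coupling, no use of the molecular adjacency.
#'
#' @param Fp0 Lp x 64 projected protein features.
#' @param Fd0 Ld x 64 MPNN atom states.
#' @param params fusion parameters (uses the output projection only).
#' @param mask optional 0/1 protein padding mask.
#' @return length-64 fused feature vector.
#' @export
fuse_cat_baseline <- function(Fp0, Fd0, params, mask = NULL) {
  z <- c(pool_protein(if (!is.null(mask)) Fp0 * mask else Fp0, mask),
         colMeans(Fd0))
  as.vector(z %*% params$Wout) + params$bout
}
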
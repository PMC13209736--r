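# Protein feature projection: residue-wise map d -> 256 -> 64.

#' Projection parameters
#'
#' Two affine layers applied independently to every residue: d -> 256
#' with ReLU and dropout, then 256 -> 64. `d` is 20 for the one-hot
#' backend and 1280 for language-model embeddings.
#'
#' @param d_in input width (residue embedding dimension).
#' @param hidden hidden width (default 256).
#' @param d_out output width (default 64, the fusion width).
#' @return named list of weight matrices and bias vectors.
#' @export
projection_params <- function(d_in, hidden = 256L, d_out = 64L) {
  list(W1 = init_weight(d_in, hidden), b1 = numeric(hidden),
       W2 = init_weight(hidden, d_out), b2 = numeric(d_out))
}

proj_forward <- function(X, params, dropout = 0, training = FALSE) {
  A1 <- sweep(X %*% params$W1, 2L, params$b1, `+`)
  H1 <- relu(A1)
  mask <- NULL
  H1d <- H1
  if (training && dropout > 0) {
    mask <- dropout_mask(H1, dropout)
    H1d <- H1 * mask
  }
  out <- sweep(H1d %*% params$W2, 2L, params$b2, `+`)
  list(out = out, cache = list(X = X, A1 = A1, H1d = H1d, mask = mask))
}

proj_backward <- function(dout, cache, params) {
  dH1d <- dout %*% t(params$W2)
  gW2 <- t(cache$H1d) %*% dout
  gb2 <- colSums(dout)
  if (!is.null(cache$mask)) dH1d <- dH1d * cache$mask
  dA1 <- dH1d * (cache$A1 > 0)
  gW1 <- t(cache$X) %*% dA1
  gb1 <- colSums(dA1)
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
       dX = dA1 %*% t(params$W1))
}

#' Project residue embeddings to the fusion width
#'
#' Applies the per-residue projection (affine d -> 256, ReLU, dropout
#' when training, affine 256 -> 64). The map is independent across
#' residues, so it is equivariant under residue permutation; inference
#' (`training = FALSE`) is deterministic.
#'
#' @param emb a `residue_embedding` (or a bare L x d matrix).
#' @param params projection parameters from [projection_params()]; widths
#'   must match the embedding dimension.
#' @param dropout dropout rate applied to the hidden layer when training
#'   (default 0.3).
#' @param training logical; enables dropout.
#' @return L x 64 numeric matrix of projected protein features.
#' @export
project_protein <- function(emb, params, dropout = 0.3, training = FALSE) {
  X <- if (inherits(emb, "residue_embedding")) emb$matrix else emb
  stopifnot(is.matrix(X))
  if (ncol(X) != nrow(params$W1)) {
    stop("embedding width ", ncol(X), " does not match projection input ",
         nrow(params$W1))
  }
  proj_forward(X, params, dropout = dropout, training = training)$out
}
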
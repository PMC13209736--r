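# Small neural-network primitives shared by all encoder modules.

relu <- function(x) pmax(x, 0)

#' Numerically stable sigmoid
#' @param z numeric vector of logits.
#' @return sigmoid(z) in (0, 1), computed without overflow.
#' @keywords internal
stable_sigmoid <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

# He-style initialization; `gain` scales the spread (used to damp the
# edge-network output so six residual message rounds stay well-scaled).
init_weight <- function(nin, nout, gain = 1) {
  matrix(stats::rnorm(nin * nout, sd = gain * sqrt(2 / nin)), nin, nout)
}

# Inverted dropout: scales kept units by 1/(1-p) so inference needs no
# rescaling. Returns the mask (same shape as x) to reuse in backward.
dropout_mask <- function(x, rate) {
  if (rate <= 0) return(array(1, dim = dim(x) %||% length(x)))
  keep <- (stats::runif(length(x)) >= rate) / (1 - rate)
  if (is.matrix(x)) dim(keep) <- dim(x)
  keep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Recursive map over two identically shaped nested lists of arrays.
params_map2 <- function(f, a, b) {
  if (is.list(a)) return(Map(function(x, y) params_map2(f, x, y), a, b))
  f(a, b)
}

params_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, function(x) params_map(f, x)))
  f(a)
}

zeros_like <- function(params) params_map(function(x) x * 0, params)

# Elementwise a + s*b over nested parameter lists.
params_axpy <- function(a, b, s = 1) {
  params_map2(function(x, y) x + s * y, a, b)
}
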
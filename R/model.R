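# End-to-end activity prediction model:
# protein encoder -> MPNN -> fusion -> MLP head -> logit.

#' Model configuration
#'
#' @param protein_backend `"onehot"` (20-dim indicator rows) or `"plm"`
#'   (precomputed 1280-dim language-model embeddings).
#' @param fusion_mode `"fusion"` (cross-coupled updates) or `"cat"`
#'   (pool-concatenate baseline).
#' @param mpnn_rounds message-passing rounds (default 6).
#' @param fusion_rounds fusion rounds (default 2).
#' @param dropout dropout rate for the protein projection hidden layer
#'   and the 64-wide head layer (default 0.3).
#' @param head_widths layer widths of the prediction head.
#' @param edge_hidden hidden width of the MPNN edge network.
#' @param freeze_association reuse the round-1 association matrix in all
#'   fusion rounds instead of recomputing it.
#' @param seed RNG seed for parameter initialization.
#' @return a `mpff_config` list.
#' @export
mpff_config <- function(protein_backend = c("onehot", "plm"),
                        fusion_mode = c("fusion", "cat"),
                        mpnn_rounds = 6L, fusion_rounds = 2L,
                        dropout = 0.3,
                        head_widths = c(64L, 128L, 256L, 64L, 1L),
                        edge_hidden = 16L,
                        freeze_association = FALSE,
                        seed = 1L) {
  protein_backend <- match.arg(protein_backend)
  fusion_mode <- match.arg(fusion_mode)
  stopifnot(dropout >= 0, dropout < 1, mpnn_rounds >= 0L, fusion_rounds >= 0L,
            all(head_widths > 0L))
  structure(list(protein_backend = protein_backend, fusion_mode = fusion_mode,
                 mpnn_rounds = as.integer(mpnn_rounds),
                 fusion_rounds = as.integer(fusion_rounds),
                 dropout = dropout, head_widths = as.integer(head_widths),
                 edge_hidden = as.integer(edge_hidden),
                 freeze_association = freeze_association,
                 seed = as.integer(seed)),
            class = "mpff_config")
}

head_params <- function(widths) {
  n <- length(widths) - 1L
  layers <- vector("list", n)
  for (k in seq_len(n)) {
    layers[[k]] <- list(W = init_weight(widths[k], widths[k + 1L]),
                        b = numeric(widths[k + 1L]))
  }
  layers
}

#' Build a model
#'
#' Initializes all trainable parameters (protein projection, MPNN, fusion
#' and head) from the configuration seed.
#'
#' @param config a `mpff_config`.
#' @return a `mpff_model`: list with `config` and `params`.
#' @export
mpff_model <- function(config = mpff_config()) {
  stopifnot(inherits(config, "mpff_config"))
  d_in <- if (config$protein_backend == "onehot") 20L else 1280L
  set.seed(config$seed)
  params <- list(
    proj = projection_params(d_in),
    mpnn = mpnn_params(rounds = config$mpnn_rounds,
                       edge_hidden = config$edge_hidden),
    fusion = fusion_params(n_rounds = config$fusion_rounds),
    head = head_params(config$head_widths)
  )
  structure(list(config = config, params = params), class = "mpff_model")
}

#' @export
print.mpff_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(unlist(params_map(length, x$params)))
  cat("<mpff_model> backend=", cfg$protein_backend, " fusion=",
      cfg$fusion_mode, " mpnn_rounds=", cfg$mpnn_rounds, " fusion_rounds=",
      cfg$fusion_rounds, " (", format(np, big.mark = ","),
      " parameters)\n", sep = "")
  invisible(x)
}

# Head: 64 -> 128 (ReLU) -> 256 (ReLU) -> 64 (ReLU + dropout) -> 1.
head_forward <- function(x, layers, dropout = 0, training = FALSE) {
  n <- length(layers)
  acts <- vector("list", n)
  masks <- vector("list", n)
  h <- x
  for (k in seq_len(n)) {
    a <- as.vector(h %*% layers[[k]]$W) + layers[[k]]$b
    if (k < n) {
      h <- relu(a)
      if (k == n - 1L && training && dropout > 0) {
        masks[[k]] <- dropout_mask(h, dropout)
        h <- h * masks[[k]]
      }
      acts[[k]] <- list(pre = a, post = h)
    } else {
      acts[[k]] <- list(pre = a, post = a)
      h <- a
    }
  }
  list(out = h, cache = list(x = x, acts = acts, masks = masks))
}

head_backward <- function(dout, cache, layers) {
  n <- length(layers)
  grads <- vector("list", n)
  dh <- dout
  for (k in rev(seq_len(n))) {
    hin <- if (k == 1L) cache$x else cache$acts[[k - 1L]]$post
    grads[[k]] <- list(W = outer(hin, dh), b = dh)
    dh <- as.vector(layers[[k]]$W %*% dh)
    if (k > 1L) {
      if (!is.null(cache$masks[[k - 1L]])) dh <- dh * cache$masks[[k - 1L]]
      dh <- dh * (cache$acts[[k - 1L]]$pre > 0)
    }
  }
  list(grads = grads, dx = dh)
}

# Full forward pass with caches kept for backpropagation.
model_forward_cache <- function(model, emb, graph, training = FALSE,
                                mask = NULL) {
  cfg <- model$config
  p <- model$params
  X <- if (inherits(emb, "residue_embedding")) emb$matrix else emb
  pf <- proj_forward(X, p$proj, dropout = cfg$dropout, training = training)
  mf <- mpnn_forward(graph, p$mpnn)
  if (cfg$fusion_mode == "fusion") {
    ff <- fusion_forward(pf$out, mf$Fd, graph$adjacency, p$fusion,
                         n_rounds = cfg$fusion_rounds, mask = mask,
                         freeze_association = cfg$freeze_association)
  } else {
    ff <- fusion_forward(pf$out, mf$Fd, graph$adjacency, p$fusion,
                         n_rounds = 0L, mask = mask)
  }
  hf <- head_forward(ff$fs, p$head, dropout = cfg$dropout,
                     training = training)
  list(logit = as.vector(hf$out),
       cache = list(pf = pf, mf = mf, ff = ff, hf = hf, graph = graph))
}

model_backward <- function(dlogit, cache, model) {
  p <- model$params
  hb <- head_backward(dlogit, cache$hf$cache, p$head)
  fb <- fusion_backward(hb$dx, cache$ff$cache, p$fusion)
  mb <- mpnn_backward(fb$dFd0, cache$mf$cache, cache$graph, p$mpnn)
  pb <- proj_backward(fb$dFp0, cache$pf$cache, p$proj)
  list(proj = pb$grads, mpnn = mb, fusion = fb$grads, head = hb$grads)
}

#' Forward pass: logit for one protein-compound pair
#'
#' Deterministic at inference (`training = FALSE`); dropout is active
#' only during training.
#'
#' @param model a `mpff_model`.
#' @param protein a `residue_embedding` (from [encode_onehot()] or
#'   [load_plm_embeddings()]) or a bare L x d matrix.
#' @param compound a SMILES string or a `mol_graph`.
#' @param training logical; enables dropout.
#' @return the scalar pre-sigmoid logit.
#' @export
model_forward <- function(model, protein, compound, training = FALSE) {
  stopifnot(inherits(model, "mpff_model"))
  graph <- if (is.character(compound)) featurize_molecule(compound) else compound
  stopifnot(inherits(graph, "mol_graph"))
  model_forward_cache(model, protein, graph, training = training)$logit
}

#' Classify logits
#'
#' probability = sigmoid(logit); predicted label is 1 iff the probability
#' is strictly greater than 0.5 (a probability of exactly 0.5 is
#' classified inactive).
#'
#' @param logit numeric vector of finite logits.
#' @return data.frame with `logit`, `probability`, `label`.
#' @export
classify <- function(logit) {
  if (any(!is.finite(logit))) stop("non-finite logit")
  probability <- stable_sigmoid(logit)
  data.frame(logit = logit, probability = probability,
             label = as.integer(probability > 0.5))
}

#' Binary cross-entropy from logits
#'
#' Mean over samples of the negative log-likelihood under a Bernoulli
#' model with p = sigmoid(z), computed in the overflow-safe form
#' max(z, 0) - z y + log(1 + exp(-|z|)) so that saturated logits give a
#' finite loss.
#'
#' @param logits numeric vector.
#' @param labels vector of 0/1 labels, same length.
#' @return scalar mean loss.
#' @export
bce_with_logits <- function(logits, labels) {
  stopifnot(length(logits) == length(labels), length(logits) >= 1L)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  mean(pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits))))
}
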
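# Optimization: AdamW with decoupled weight decay, early stopping on
# validation loss, seeded shuffling.

#' Training configuration
#'
#' @param learning_rate AdamW step size (> 0).
#' @param weight_decay decoupled weight-decay coefficient.
#' @param batch_size minibatch size.
#' @param max_epochs maximum number of epochs.
#' @param patience early stopping: abort after this many consecutive
#'   epochs without validation-loss improvement (default 20).
#' @param seed RNG seed covering shuffling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 4.8144e-4, weight_decay = 5.9273e-3,
                         batch_size = 64L, max_epochs = 200L, patience = 20L,
                         seed = 1L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1L,
            max_epochs >= 1L, patience >= 1L)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

# Names of non-trainable scalars carried inside parameter lists.
.non_trainable <- c("rounds", "n_rounds")

adamw_state_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

# One AdamW update over a nested parameter list. Weight decay is applied
# directly to the parameters (decoupled from the gradient moments), so a
# parameter with zero gradient still shrinks by lr * wd each step.
adamw_walk <- function(params, grads, m, v, lr, wd, beta1, beta2, eps, t) {
  if (is.list(params)) {
    nm <- names(params)
    for (k in seq_along(params)) {
      if (!is.null(nm) && nm[k] %in% .non_trainable) next
      res <- adamw_walk(params[[k]], grads[[k]], m[[k]], v[[k]],
                        lr, wd, beta1, beta2, eps, t)
      params[[k]] <- res$p
      m[[k]] <- res$m
      v[[k]] <- res$v
    }
    return(list(p = params, m = m, v = v))
  }
  m <- beta1 * m + (1 - beta1) * grads
  v <- beta2 * v + (1 - beta2) * grads^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  p <- params - lr * mhat / (sqrt(vhat) + eps) - lr * wd * params
  list(p = p, m = m, v = v)
}

#' One AdamW step
#'
#' @param params nested list of parameter arrays.
#' @param grads gradients with the same structure.
#' @param state optimizer state from [adamw_state_init()].
#' @param lr learning rate.
#' @param wd decoupled weight decay.
#' @param beta1,beta2,eps Adam moment coefficients.
#' @return list with updated `params` and `state`.
#' @export
adamw_step <- function(params, grads, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  res <- adamw_walk(params, grads, state$m, state$v, lr, wd,
                    beta1, beta2, eps, state$t)
  list(params = res$p, state = list(m = res$m, v = res$v, t = state$t))
}

# Mean loss over a sample list at inference (no dropout).
dataset_loss <- function(model, samples) {
  logits <- vapply(samples, function(s) {
    model_forward_cache(model, s$protein, s$graph, training = FALSE)$logit
  }, numeric(1))
  labels <- vapply(samples, `[[`, numeric(1), "label")
  list(loss = bce_with_logits(logits, labels), logits = logits,
       labels = labels)
}

#' Train a model
#'
#' Minimizes the binary cross-entropy with AdamW (decoupled weight
#' decay). Batches are reshuffled every epoch with the seeded RNG and the
#' last partial batch is kept. Training stops at `max_epochs` or once the
#' validation loss has not improved for `patience` consecutive epochs;
#' the returned model carries the parameters of the best-validation
#' epoch.
#'
#' Samples are lists with fields `protein` (a `residue_embedding`),
#' `graph` (a `mol_graph`) and `label` (0/1); see
#' [prepare_training_samples()].
#'
#' @param model a `mpff_model`.
#' @param splits list with non-empty `train` and `val` sample lists.
#' @param config a `train_config`.
#' @param verbose print per-epoch losses.
#' @return list with `model` (best parameters) and `history` (data.frame
#'   of per-epoch train loss, validation loss and validation accuracy,
#'   plus `best_epoch` and `stopped_early` attributes).
#' @export
train <- function(model, splits, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "mpff_model"), inherits(config, "train_config"))
  tr <- splits$train
  va <- splits$val
  if (length(tr) == 0L || length(va) == 0L) stop("empty train or val split")
  set.seed(config$seed)
  opt <- adamw_state_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_accuracy = numeric())
  bad_epochs <- 0L
  stopped_early <- FALSE
  n <- length(tr)
  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      batch <- idx[s:min(s + config$batch_size - 1L, n)]
      gsum <- NULL
      bloss <- 0
      for (i in batch) {
        smp <- tr[[i]]
        fw <- model_forward_cache(model, smp$protein, smp$graph,
                                  training = TRUE)
        z <- fw$logit
        y <- smp$label
        bloss <- bloss + (max(z, 0) - z * y + log1p(exp(-abs(z))))
        g <- model_backward(stable_sigmoid(z) - y, fw$cache, model)
        gsum <- if (is.null(gsum)) g else params_axpy(gsum, g)
      }
      if (!is.finite(bloss)) {
        stop("non-finite training loss at epoch ", epoch,
             "; reduce the learning rate")
      }
      gavg <- params_map(function(x) x / length(batch), gsum)
      upd <- adamw_step(model$params, gavg, opt,
                        lr = config$learning_rate, wd = config$weight_decay)
      model$params <- upd$params
      opt <- upd$state
      epoch_loss <- epoch_loss + bloss
    }
    vl <- dataset_loss(model, va)
    val_acc <- mean(as.integer(stable_sigmoid(vl$logits) > 0.5) == vl$labels)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = epoch_loss / n,
                                   val_loss = vl$loss,
                                   val_accuracy = val_acc))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f", epoch,
                      epoch_loss / n, vl$loss, val_acc))
    }
    if (vl$loss < best$loss) {
      best <- list(loss = vl$loss, params = model$params, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= config$patience) {
        stopped_early <- TRUE
        break
      }
    }
  }
  model$params <- best$params
  attr(hist, "best_epoch") <- best$epoch
  attr(hist, "stopped_early") <- stopped_early
  list(model = model, history = hist)
}

#' Assemble training samples from an activity table
#'
#' Featurizes all compounds in one backend call and attaches the encoded
#' protein for each record's target.
#'
#' @param records data.frame with `smiles` (or `canonical_smiles`),
#'   `label` and `target_id` columns.
#' @param proteins named list of `residue_embedding` (or
#'   `protein_sequence`, encoded one-hot), keyed by target id.
#' @return list of samples suitable for [train()].
#' @export
prepare_training_samples <- function(records, proteins) {
  stopifnot(is.data.frame(records), "label" %in% names(records))
  smi <- if ("canonical_smiles" %in% names(records)) {
    records$canonical_smiles
  } else {
    records$smiles
  }
  proteins <- lapply(proteins, function(p) {
    if (inherits(p, "protein_sequence")) encode_onehot(p) else p
  })
  graphs <- featurize_molecules(smi)
  tid <- if ("target_id" %in% names(records)) {
    records$target_id
  } else {
    rep(names(proteins)[1L], nrow(records))
  }
  lapply(seq_len(nrow(records)), function(i) {
    list(graph = graphs[[i]], protein = proteins[[tid[i]]],
         label = records$label[i])
  })
}

#' Predict probabilities for a sample list
#'
#' @param model a trained `mpff_model`.
#' @param samples list of samples (as in [train()]).
#' @return numeric vector of predicted probabilities.
#' @export
predict_proba <- function(model, samples) {
  vapply(samples, function(s) {
    stable_sigmoid(model_forward_cache(model, s$protein, s$graph,
                                       training = FALSE)$logit)
  }, numeric(1))
}

#' Export a training history
#'
#' Writes the per-epoch history as CSV and an optional JSON summary
#' (final/best losses, best epoch, early-stop flag).
#'
#' @param history the history data.frame returned by [train()].
#' @param csv_path per-epoch CSV path (NULL to skip).
#' @param json_path JSON summary path (NULL to skip).
#' @return the history, invisibly.
#' @export
write_history <- function(history, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(history, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      epochs = nrow(history),
      best_epoch = attr(history, "best_epoch"),
      best_val_loss = min(history$val_loss),
      final_train_loss = history$train_loss[nrow(history)],
      stopped_early = isTRUE(attr(history, "stopped_early"))
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(history)
}
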
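# Virtual screening: batch inference over a compound library against one
# target, ranking and confidence thresholding.

#' Screen a compound library against a target
#'
#' Runs inference (deterministic, no dropout) for every parseable
#' molecule, ranks by predicted probability (descending, ties broken by
#' id ascending) and counts candidates above the confidence threshold.
#' Unparsable molecules are logged and excluded from all counts.
#'
#' @param model a trained `mpff_model`.
#' @param protein a `residue_embedding` or `protein_sequence` for the
#'   target (one-hot encoded if a sequence is given).
#' @param molecules data.frame with `smiles` (and optionally `id`)
#'   columns.
#' @param confidence_threshold candidate cutoff in `[0, 1]`; a molecule
#'   is a candidate iff its probability is strictly greater (default 0.5,
#'   the decision boundary; raise towards 1 to keep only high-confidence
#'   calls).
#' @return a `screening_result`: list with `ranked` (data.frame id,
#'   smiles, canonical_smiles, probability, label), `threshold`,
#'   `counts` (screened, predicted_active, above_threshold, unparsable)
#'   and `skipped` (unparsable rows).
#' @export
screen_library <- function(model, protein, molecules,
                           confidence_threshold = 0.5) {
  stopifnot(inherits(model, "mpff_model"), is.data.frame(molecules),
            "smiles" %in% names(molecules),
            confidence_threshold >= 0, confidence_threshold <= 1)
  if (nrow(molecules) == 0L) stop("empty screening library")
  if (!"id" %in% names(molecules)) {
    molecules$id <- sprintf("mol%05d", seq_len(nrow(molecules)))
  }
  if (inherits(protein, "protein_sequence")) protein <- encode_onehot(protein)
  prof <- chem_profile(molecules$smiles)
  parseable <- is.na(prof$error)
  skipped <- molecules[!parseable, , drop = FALSE]
  mols <- molecules[parseable, , drop = FALSE]
  if (nrow(mols) == 0L) stop("no parseable molecules in the library")
  graphs <- featurize_molecules(mols$smiles)
  probs <- vapply(graphs, function(g) {
    stable_sigmoid(model_forward_cache(model, protein, g,
                                       training = FALSE)$logit)
  }, numeric(1))
  ranked <- data.frame(id = mols$id, smiles = mols$smiles,
                       canonical_smiles = prof$canonical_smiles[parseable],
                       probability = probs,
                       label = as.integer(probs > 0.5),
                       stringsAsFactors = FALSE)
  ranked <- ranked[order(-ranked$probability, ranked$id), , drop = FALSE]
  rownames(ranked) <- NULL
  structure(list(
    ranked = ranked, threshold = confidence_threshold,
    counts = list(screened = nrow(ranked),
                  predicted_active = sum(ranked$label),
                  above_threshold = sum(ranked$probability >
                                          confidence_threshold),
                  unparsable = nrow(skipped)),
    skipped = skipped
  ), class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result> screened=", x$counts$screened,
      " predicted_active=", x$counts$predicted_active,
      " above_threshold(", x$threshold, ")=", x$counts$above_threshold,
      "\n", sep = "")
  invisible(x)
}

#' Write screening results
#'
#' CSV with header id, smiles, probability, label; probabilities are
#' serialized at 6 decimals, enough for the read-back ranking to
#' reproduce the in-memory ranking.
#'
#' @param result a `screening_result`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "screening_result"))
  df <- result$ranked[, c("id", "smiles", "probability", "label")]
  df$probability <- sprintf("%.6f", df$probability)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding all parameter arrays,
#' the model configuration, and the featurizer/canonicalizer version
#' tag, so a reloaded model reproduces inference bit for bit.
#'
#' @param model a `mpff_model`.
#' @param path checkpoint path (`.rds`).
#' @return `save_checkpoint`: the path, invisibly; `load_checkpoint`:
#'   the restored `mpff_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mpff_model"))
  saveRDS(list(config = model$config, params = model$params,
               featurizer = featurizer_version()), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$featurizer, featurizer_version())) {
    warning("checkpoint featurizer version ", obj$featurizer,
            " differs from current ", featurizer_version())
  }
  structure(list(config = obj$config, params = obj$params),
            class = "mpff_model")
}
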
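# Molecular graphs: featurization and batching.

featurizer_version <- function() "mpff-rdkit-74x12-v1"

new_mol_graph <- function(num_atoms, atom_features, edges, bond_features,
                          smiles = NA_character_) {
  num_atoms <- as.integer(num_atoms)
  adjacency <- matrix(0, num_atoms, num_atoms)
  if (nrow(edges) > 0L) adjacency[edges] <- 1
  structure(
    list(num_atoms = num_atoms, atom_features = atom_features,
         edges = edges, bond_features = bond_features,
         adjacency = adjacency, smiles = smiles),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$num_atoms, " atoms, ", nrow(x$edges),
      " directed edges", if (!is.na(x$smiles)) paste0("  (", x$smiles, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Featurize molecules as graphs
#'
#' Converts SMILES into heavy-atom molecular graphs with 74-dimensional
#' atom features (element one-hot with an unknown slot, degree, implicit
#' valence, formal charge, radical electrons, hybridization, aromaticity,
#' total H count) and 12-dimensional bond features (bond type,
#' conjugation, ring membership, stereo). Every chemical bond appears as
#' two directed edges carrying identical bond features. Hydrogens are
#' implicit: the graph covers heavy atoms only, with hydrogen counts
#' encoded as an atom feature.
#'
#' @param smiles a single SMILES string.
#' @return a `mol_graph`: list with `num_atoms`, `atom_features`
#'   (num_atoms x 74), `edges` (2m x 2 matrix of 1-based directed pairs),
#'   `bond_features` (2m x 12), `adjacency` (binary, symmetric, zero
#'   diagonal).
#' @seealso [featurize_molecules()] for the batched form.
#' @export
featurize_molecule <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  featurize_molecules(smiles)[[1L]]
}

#' Featurize many molecules in one backend call
#'
#' @param smiles character vector of SMILES.
#' @return list of `mol_graph`, in input order. Results are memoised per
#'   session, keyed by the SMILES string.
#' @export
featurize_molecules <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (is.null(.mpff$graph_cache)) .mpff$graph_cache <- new.env(parent = emptyenv())
  cache <- .mpff$graph_cache
  todo <- unique(smiles[!vapply(smiles, exists, logical(1), envir = cache)])
  if (length(todo) > 0L) {
    res <- chem_call("featurize", todo)
    err <- as.character(res$error)
    if (any(!is.na(err))) {
      bad <- which(!is.na(err))[1L]
      stop("SMILES parse error: ", err[bad])
    }
    for (k in seq_along(todo)) {
      g <- res$graphs[[k]]
      n <- as.integer(g$num_atoms)
      af <- matrix(as.numeric(g$atom_features), nrow = n, byrow = FALSE)
      # jsonlite returns an n x 74 matrix already when n > 1; normalize
      if (is.matrix(g$atom_features)) af <- g$atom_features
      if (n == 1L) af <- matrix(as.numeric(g$atom_features), nrow = 1L)
      stopifnot(ncol(af) == 74L)
      ne <- length(g$src)
      if (ne > 0L) {
        edges <- cbind(as.integer(g$src) + 1L, as.integer(g$dst) + 1L)
        bf <- g$bond_features
        if (!is.matrix(bf)) bf <- matrix(as.numeric(bf), nrow = ne, byrow = TRUE)
        stopifnot(ncol(bf) == 12L)
      } else {
        edges <- matrix(integer(), 0L, 2L)
        bf <- matrix(numeric(), 0L, 12L)
      }
      assign(todo[k], new_mol_graph(n, af, edges, bf, smiles = todo[k]),
             envir = cache)
    }
  }
  lapply(smiles, get, envir = cache)
}

#' Batch molecular graphs block-diagonally
#'
#' Concatenates node and edge features across graphs and reindexes edges
#' with per-graph node offsets, so the batch is one disconnected graph
#' whose adjacency is block-diagonal. A membership vector maps every node
#' back to its source graph, allowing exact un-batching; encoding a batch
#' gives the same per-molecule results as encoding each graph alone.
#'
#' @param graphs non-empty list of `mol_graph`.
#' @return a `mol_graph_batch`: fields of a `mol_graph` (minus the dense
#'   adjacency) plus `membership` (1-based graph index per node) and
#'   `sizes`.
#' @export
batch_graphs <- function(graphs) {
  stopifnot(is.list(graphs), length(graphs) >= 1L)
  stopifnot(all(vapply(graphs, inherits, logical(1), "mol_graph")))
  sizes <- vapply(graphs, function(g) g$num_atoms, integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  af <- do.call(rbind, lapply(graphs, function(g) g$atom_features))
  edges <- do.call(rbind, Map(function(g, off) {
    if (nrow(g$edges) == 0L) return(matrix(integer(), 0L, 2L))
    g$edges + off
  }, graphs, offsets))
  bf <- do.call(rbind, lapply(graphs, function(g) g$bond_features))
  structure(
    list(num_atoms = sum(sizes), atom_features = af, edges = edges,
         bond_features = bf, membership = rep(seq_along(graphs), sizes),
         sizes = sizes),
    class = c("mol_graph_batch", "mol_graph")
  )
}

#' Read a molecule table
#'
#' Reads a CSV/TSV compound table with a required `smiles` column and
#' optional `id`, `target_id`, `ic50_nM` and `label` columns, and fills
#' canonical SMILES on ingestion. Unparsable SMILES are kept with an
#' `error` annotation so the caller decides whether they are fatal.
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field separator; `","` for CSV (default), `"\t"` for TSV.
#' @return data.frame with at least `id`, `smiles`, `canonical_smiles`,
#'   `error` columns.
#' @export
read_molecule_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (!"smiles" %in% names(df)) stop("input must have a `smiles` column")
  ingest_molecules(df)
}

#' Fill canonical SMILES and default ids on a molecule data.frame
#'
#' @param df data.frame with a `smiles` column.
#' @return the data.frame with `id`, `canonical_smiles` and `error`
#'   columns filled in.
#' @export
ingest_molecules <- function(df) {
  stopifnot(is.data.frame(df), "smiles" %in% names(df))
  if (!"id" %in% names(df)) df$id <- sprintf("mol%05d", seq_len(nrow(df)))
  prof <- chem_profile(df$smiles)
  df$canonical_smiles <- prof$canonical_smiles
  df$error <- prof$error
  df
}

#' Persist / restore a featurized graph cache
#'
#' Saves featurized graphs keyed by canonical SMILES into a single
#' archive, with a JSON sidecar (`<path>.json`) recording the featurizer
#' version so stale caches are detected on load.
#'
#' @param smiles character vector of SMILES to featurize and cache.
#' @param path cache path (`.rds`); the sidecar is written next to it.
#' @return `write_graph_cache`: the path, invisibly; `read_graph_cache`:
#'   a named list of `mol_graph` keyed by canonical SMILES.
#' @export
write_graph_cache <- function(smiles, path) {
  canon <- canonicalize_smiles(smiles)
  graphs <- featurize_molecules(canon)
  names(graphs) <- canon
  graphs <- graphs[!duplicated(canon)]
  saveRDS(graphs, path)
  jsonlite::write_json(list(featurizer = featurizer_version(),
                            n_graphs = length(graphs)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_graph_cache
#' @export
read_graph_cache <- function(path) {
  if (!file.exists(path)) stop("graph cache not found: ", path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    if (!identical(meta$featurizer, featurizer_version())) {
      warning("graph cache was written by featurizer ", meta$featurizer,
              "; current is ", featurizer_version())
    }
  }
  readRDS(path)
}
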
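# Protein sequences and residue-level embeddings.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a protein sequence
#'
#' @param id sequence identifier.
#' @param residues string over the 20 standard amino-acid letters plus
#'   `X` for unknown residues.
#' @return a `protein_sequence` object with `id`, `residues`, `length`.
#' @export
protein_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) < 1L) stop("empty protein sequence")
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% c(AA_ALPHABET, "X"))
  if (length(bad) > 0L) {
    stop("disallowed residue '", chars[bad[1]], "' at position ", bad[1],
         " in sequence ", id)
  }
  structure(list(id = id, residues = residues, length = length(chars)),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("<protein_sequence> ", x$id, " (", x$length, " aa)\n", sep = "")
  invisible(x)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file (multi-record allowed); the first word of each
#'   description line is taken as the id.
#' @return named list of `protein_sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1L)
  out <- Map(protein_sequence, ids, as.character(aas))
  names(out) <- ids
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs list of `protein_sequence`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  lines <- unlist(lapply(seqs, function(s) c(paste0(">", s$id), s$residues)))
  writeLines(lines, path)
  invisible(path)
}

new_residue_embedding <- function(matrix, backend) {
  structure(list(matrix = matrix, backend = backend, d = ncol(matrix)),
            class = "residue_embedding")
}

#' One-hot residue encoding
#'
#' Encodes each residue as a 20-dimensional indicator over the standard
#' amino-acid alphabet (alphabetical order of one-letter codes). Unknown
#' residues (`X`) map to an all-zero row: they carry no evidence and the
#' alphabet stays at 20 classes.
#'
#' @param seq a `protein_sequence`.
#' @return a `residue_embedding` with an L x 20 matrix, `backend`
#'   `"onehot"`.
#' @export
encode_onehot <- function(seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  chars <- strsplit(seq$residues, "")[[1]]
  m <- matrix(0, length(chars), 20L,
              dimnames = list(NULL, AA_ALPHABET))
  idx <- match(chars, AA_ALPHABET)  # NA for 'X'
  keep <- !is.na(idx)
  m[cbind(which(keep), idx[keep])] <- 1
  new_residue_embedding(m, "onehot")
}

#' Load precomputed protein language-model embeddings
#'
#' Residue-level embeddings are produced by an external frozen protein
#' language model and consumed here from a file; this package never runs
#' the language model itself. Two containers are supported: an `.rds`
#' file holding a numeric L x 1280 matrix (optionally a named list of
#' such matrices keyed by sequence id), or a plain-text whitespace/tab
#' delimited matrix with one row per residue.
#'
#' @param path embedding file.
#' @param seq the `protein_sequence` the embeddings belong to; the row
#'   count is validated against its length.
#' @return a `residue_embedding` with backend `"plm"`, d = 1280.
#' @export
load_plm_embeddings <- function(path, seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  if (!file.exists(path)) stop("embedding file not found: ", path)
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    obj <- readRDS(path)
    if (is.list(obj) && !is.matrix(obj)) {
      if (!seq$id %in% names(obj)) {
        stop("no embedding named '", seq$id, "' in ", path)
      }
      obj <- obj[[seq$id]]
    }
    m <- as.matrix(obj)
  } else {
    m <- as.matrix(utils::read.table(path, header = FALSE))
  }
  storage.mode(m) <- "double"
  if (nrow(m) != seq$length) {
    stop("embedding rows (", nrow(m), ") do not match sequence length (",
         seq$length, ") for ", seq$id)
  }
  if (ncol(m) != 1280L) {
    stop("embedding width ", ncol(m), " != 1280 for ", seq$id)
  }
  dimnames(m) <- NULL
  new_residue_embedding(m, "plm")
}

#' Mean-pool projected protein features
#'
#' Arithmetic mean over residues of an L x d feature matrix. With a
#' padding mask, padded rows are excluded from the mean (the divisor is
#' the number of real residues), so pooling is invariant to the amount
#' of padding.
#'
#' @param fp numeric matrix, residues in rows.
#' @param mask optional 0/1 vector marking real residues.
#' @return numeric vector of length `ncol(fp)`.
#' @export
pool_protein <- function(fp, mask = NULL) {
  stopifnot(is.matrix(fp), nrow(fp) >= 1L)
  if (is.null(mask)) return(colMeans(fp))
  stopifnot(length(mask) == nrow(fp), sum(mask) >= 1)
  colSums(fp * mask) / sum(mask)
}
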
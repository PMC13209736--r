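# Bridge to the RDKit-based cheminformatics backend.
#
# All SMILES parsing, canonicalization, descriptor calculation, Murcko
# scaffold extraction and graph featurization go through one bundled
# helper script executed in a single batched subprocess call per request,
# so a whole library costs one interpreter startup.

.mpff <- new.env(parent = emptyenv())

chem_python <- function() {
  py <- getOption("mpff.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found; set options(mpff.python=)")
  py
}

chem_helper <- function() {
  path <- system.file("python", "chem_helper.py", package = "mpff")
  if (!nzchar(path)) stop("chem_helper.py not found in installed package")
  path
}

#' @importFrom jsonlite toJSON fromJSON unbox
chem_call <- function(op, smiles, pattern = NULL) {
  stopifnot(is.character(smiles))
  req <- list(op = jsonlite::unbox(op), smiles = smiles)
  if (!is.null(pattern)) req$pattern <- jsonlite::unbox(pattern)
  reqfile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(reqfile, outfile)), add = TRUE)
  writeLines(jsonlite::toJSON(req, null = "null", digits = NA), reqfile)
  status <- system2(chem_python(), c(shQuote(chem_helper()), shQuote(reqfile),
                                     shQuote(outfile)),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(outfile)) {
    stop("chemistry backend call failed (op=", op, ", status=", status, ")")
  }
  res <- jsonlite::fromJSON(outfile, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (!is.null(res$fatal)) stop("chemistry backend: ", res$fatal)
  res
}

# Batched canonical SMILES + descriptors + scaffold (+ pharmacophore match),
# tolerant of unparsable entries: returns a data.frame with an `error`
# column instead of failing. The pipeline modules build on this.
chem_profile <- function(smiles, pattern = NULL) {
  if (length(smiles) == 0L) {
    return(data.frame(smiles = character(), canonical_smiles = character(),
                      mw = numeric(), logp = numeric(), hbd = integer(),
                      hba = integer(), scaffold = character(),
                      error = character(), stringsAsFactors = FALSE))
  }
  res <- chem_call("profile", smiles, pattern)
  out <- data.frame(
    smiles = smiles,
    canonical_smiles = as.character(res$canonical),
    mw = as.numeric(res$mw),
    logp = as.numeric(res$logp),
    hbd = as.integer(res$hbd),
    hba = as.integer(res$hba),
    scaffold = as.character(res$scaffold),
    error = as.character(res$error),
    stringsAsFactors = FALSE
  )
  if (!is.null(pattern)) out$match <- as.integer(res$match)
  out
}

#' Canonicalize SMILES strings
#'
#' Maps each molecule to its unique canonical SMILES writing, the fixed
#' point used throughout the package for deduplication. The canonical
#' dialect is the RDKit canonical writer of the bundled backend; one
#' dialect is used for the whole package so that equality of canonical
#' strings is equality of molecules.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length as the input.
#'   Canonicalization is idempotent: re-canonicalizing a canonical string
#'   returns it unchanged.
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("OCC", "CCO"))  # both "CCO"
#' }
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L, all(nzchar(smiles)))
  res <- chem_call("canonicalize", smiles)
  err <- as.character(res$error)
  if (any(!is.na(err))) {
    bad <- which(!is.na(err))[1L]
    stop("SMILES parse error: ", err[bad])
  }
  as.character(res$canonical)
}

#' Compute physicochemical descriptors
#'
#' Molecular weight (average isotopic mass including implicit hydrogens,
#' Da), Crippen LogP, and Lipinski hydrogen-bond donor/acceptor counts —
#' the four descriptors used by the library filter.
#'
#' @param smiles character vector of SMILES strings.
#' @return data.frame with columns `smiles`, `mw`, `logp`, `hbd`, `hba`.
#' @export
compute_descriptors <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  res <- chem_call("descriptors", smiles)
  err <- as.character(res$error)
  if (any(!is.na(err))) {
    bad <- which(!is.na(err))[1L]
    stop("SMILES parse error: ", err[bad])
  }
  data.frame(smiles = smiles, mw = as.numeric(res$mw),
             logp = as.numeric(res$logp), hbd = as.integer(res$hbd),
             hba = as.integer(res$hba), stringsAsFactors = FALSE)
}

#' Bemis-Murcko scaffold
#'
#' Extracts the ring systems plus connecting linkers of each molecule,
#' with side chains removed, and returns the canonical SMILES of the
#' scaffold. Acyclic molecules have no scaffold and return the empty
#' string; they form one shared scaffold group during splitting.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical scaffold SMILES ("" for acyclic).
#' @export
murcko_scaffold <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  res <- chem_call("scaffold", smiles)
  err <- as.character(res$error)
  if (any(!is.na(err))) {
    bad <- which(!is.na(err))[1L]
    stop("SMILES parse error: ", err[bad])
  }
  as.character(res$scaffold)
}

# Substructure (SMARTS) match, backend-tolerant version used by the
# synthetic generator's labeling rule.
substructure_match <- function(smiles, pattern) {
  stopifnot(is.character(smiles), length(smiles) >= 1L, nzchar(pattern))
  res <- chem_call("match", smiles, pattern)
  err <- as.character(res$error)
  if (any(!is.na(err))) {
    bad <- which(!is.na(err))[1L]
    stop("SMILES parse error: ", err[bad])
  }
  as.integer(res$match)
}
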
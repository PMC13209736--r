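# Seeded synthetic fixtures: molecule libraries, activity datasets and
# protein sequences with known structure, so the whole pipeline is
# testable without external downloads.
#
# Molecules are assembled from a deterministic pool of ring scaffolds
# (single rings plus template-linker-ring composites, deduplicated by
# Murcko scaffold) decorated with small substituent prefixes. Activity
# is carried by a pharmacophore substructure (an amide by default):
# positives get an amide-bearing prefix, negatives draw from a
# carbonyl-free prefix alphabet, so the label is exactly the presence of
# the pharmacophore and is guaranteed representable by a graph encoder.

SYN_BASE_RINGS <- c(
  "c1ccccc1", "c1ccncc1", "c1ccoc1", "c1ccsc1", "c1cc[nH]c1", "C1CCCCC1",
  "C1CCNCC1", "C1CCOCC1", "C1CCCC1", "C1CCCCCC1", "c1ccc2ccccc2c1",
  "c1ccc2[nH]ccc2c1", "c1ccc2ncccc2c1", "c1cnc2ccccc2c1"
)
SYN_TEMPLATES <- c("c1ccc(%s)cc1", "C1CCC(%s)CC1", "C1CCN(%s)CC1",
                   "c1ccc(%s)nc1", "c1cnc(%s)cn1")
SYN_LINKERS <- c("", "C", "CC", "CCC", "OC", "NC", "COC")
SYN_SUBRINGS <- c("c2ccccc2", "c2ccncc2", "C2CCCCC2", "C2CCNCC2",
                  "C2CCOCC2", "c2ccoc2", "c2ccsc2", "c2ccc3ccccc3c2")

# Carbonyl-free decorations (cannot create an amide) and amide-bearing
# decorations (always contain one).
SYN_NEG_PREFIXES <- c("", "C", "CC", "CCC", "CO", "CCO", "OCC", "F", "Cl",
                      "N", "CN", "CC(C)", "O")
SYN_POS_PREFIXES <- c("NC(=O)", "CNC(=O)", "CCNC(=O)", "NC(=O)C")

# Inhibitor-like heavy assemblies landing inside the default descriptor
# filter windows (bis-benzylpiperazine ethers, MW ~600-670).
SYN_HEAVY_CORE <-
  "Oc1ccc(CN2CCN(Cc3ccc(Oc4ccc(CN5CCN(Cc6ccc(O%s)cc6)CC5)cc4)cc3)CC2)cc1"
SYN_HEAVY_ARMS <- c("C", "CC", "c2ccccc2", "Cc2ccccc2")

#' Synthetic dataset specification
#'
#' @param n_molecules number of records to generate.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @param scaffold_pool_size number of distinct Murcko scaffolds the
#'   library must cover (max ~290 with the built-in grammar).
#' @param positive_rate probability that a record is active.
#' @param pharmacophore SMARTS pattern carried by every active molecule
#'   and by no inactive one (default amide, `"C(=O)N"`).
#' @param ic50_lognormal named vector `mu_pos`, `mu_neg`, `sigma` of the
#'   log-normal IC50 model in log-nM; draws are truncated to the correct
#'   side of the 6.1 nM activity threshold by inverse-CDF sampling.
#' @param label_flip_rate fraction of labels flipped after IC50
#'   assignment, to inject label noise (default 0, noise-free).
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_molecules = 1000L, seed = 1L,
                           scaffold_pool_size = 100L, positive_rate = 0.4,
                           pharmacophore = "C(=O)N",
                           ic50_lognormal = c(mu_pos = 0, mu_neg = 5,
                                              sigma = 1),
                           label_flip_rate = 0) {
  stopifnot(n_molecules >= 1L, positive_rate > 0, positive_rate < 1,
            scaffold_pool_size >= 1L, label_flip_rate >= 0,
            label_flip_rate < 1)
  structure(list(n_molecules = as.integer(n_molecules),
                 seed = as.integer(seed),
                 scaffold_pool_size = as.integer(scaffold_pool_size),
                 positive_rate = positive_rate,
                 pharmacophore = pharmacophore,
                 ic50_lognormal = ic50_lognormal,
                 label_flip_rate = label_flip_rate),
            class = "synthetic_spec")
}

# Deterministic scaffold pool: base rings first, then linked composites,
# deduplicated by Murcko scaffold so every pool entry is a distinct
# scaffold group.
scaffold_pool <- function(size) {
  key <- paste0("pool", size)
  if (is.null(.mpff$pools)) .mpff$pools <- list()
  if (!is.null(.mpff$pools[[key]])) return(.mpff$pools[[key]])
  linked <- character()
  for (t in SYN_TEMPLATES) {
    for (l in SYN_LINKERS) {
      for (r in SYN_SUBRINGS) linked <- c(linked, sprintf(t, paste0(l, r)))
    }
  }
  cand <- c(SYN_BASE_RINGS, linked)
  scafs <- murcko_scaffold(cand)
  pool <- cand[!duplicated(scafs)]
  if (size > length(pool)) {
    stop("scaffold_pool_size ", size, " exceeds the grammar's ",
         length(pool), " distinct scaffolds")
  }
  pool <- pool[seq_len(size)]
  .mpff$pools[[key]] <- pool
  pool
}

# Truncated log-normal IC50 draw via inverse-CDF sampling: positives
# strictly below the threshold, negatives strictly above.
draw_ic50 <- function(labels, pars, threshold = 6.1) {
  lt <- log(threshold)
  mu <- ifelse(labels == 1, pars[["mu_pos"]], pars[["mu_neg"]])
  sg <- pars[["sigma"]]
  pcut <- stats::pnorm((lt - mu) / sg)
  u <- stats::runif(length(labels))
  q <- ifelse(labels == 1, u * pcut * 0.999999,
              pcut + (1 - pcut) * (1e-6 + u * 0.999998))
  exp(mu + sg * stats::qnorm(q))
}

#' Generate a synthetic molecule library
#'
#' Builds `n_molecules` valid SMILES by decorating ring scaffolds from a
#' deterministic pool. The first `scaffold_pool_size` rows cover every
#' pool scaffold once, so the library always reaches the requested
#' scaffold diversity; a fraction of later rows are heavy inhibitor-like
#' assemblies that fall inside the default screening filter windows.
#'
#' @param spec a [synthetic_spec()].
#' @param heavy_fraction fraction of rows drawn from the heavy
#'   (filter-window) family (default 0.1).
#' @return data.frame with `id` and `smiles`.
#' @export
generate_library <- function(spec = synthetic_spec(), heavy_fraction = 0.1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pool <- scaffold_pool(spec$scaffold_pool_size)
  set.seed(spec$seed)
  n <- spec$n_molecules
  prefixes <- c(SYN_NEG_PREFIXES, SYN_POS_PREFIXES)
  smiles <- character(n)
  for (k in seq_len(n)) {
    if (k > length(pool) && stats::runif(1) < heavy_fraction) {
      smiles[k] <- sprintf(SYN_HEAVY_CORE, sample(SYN_HEAVY_ARMS, 1L))
    } else {
      core <- pool[[((k - 1L) %% length(pool)) + 1L]]
      smiles[k] <- paste0(sample(prefixes, 1L), core)
    }
  }
  data.frame(id = sprintf("syn%05d", seq_len(n)), smiles = smiles,
             stringsAsFactors = FALSE)
}

#' Generate a labeled activity dataset
#'
#' Activity is assigned by construction: each record is active with
#' probability `positive_rate`; actives get an amide-bearing decoration
#' (so they contain the pharmacophore), inactives a carbonyl-free one.
#' IC50 values are drawn from the label's truncated log-normal, strictly
#' on the correct side of the 6.1 nM threshold, so threshold labeling
#' reproduces the generated labels exactly. Optional label noise flips a
#' fraction of labels (with IC50 redrawn accordingly), decoupling the
#' label from the pharmacophore.
#'
#' @param spec a [synthetic_spec()].
#' @param target_id target identifier attached to every record.
#' @return data.frame with `id`, `smiles`, `target_id`, `ic50_nM`,
#'   `label`.
#' @export
generate_activity_dataset <- function(spec = synthetic_spec(),
                                      target_id = "T1") {
  stopifnot(inherits(spec, "synthetic_spec"))
  pool <- scaffold_pool(spec$scaffold_pool_size)
  set.seed(spec$seed)
  n <- spec$n_molecules
  labels <- as.integer(stats::runif(n) < spec$positive_rate)
  smiles <- character(n)
  for (k in seq_len(n)) {
    core <- pool[[((k - 1L) %% length(pool)) + 1L]]
    pref <- if (labels[k] == 1) sample(SYN_POS_PREFIXES, 1L)
            else sample(SYN_NEG_PREFIXES, 1L)
    smiles[k] <- paste0(pref, core)
  }
  if (spec$label_flip_rate > 0) {
    flip <- stats::runif(n) < spec$label_flip_rate
    labels[flip] <- 1L - labels[flip]
  }
  ic50 <- draw_ic50(labels, spec$ic50_lognormal)
  data.frame(id = sprintf("syn%05d", seq_len(n)), smiles = smiles,
             target_id = target_id, ic50_nM = ic50, label = labels,
             stringsAsFactors = FALSE)
}

#' Generate a random protein sequence
#'
#' Uniform over the 20 standard residues, seeded. The default length
#' matches the catalytic-domain scale used in the package's fixtures.
#'
#' @param length sequence length (>= 1).
#' @param seed RNG seed.
#' @param id sequence identifier.
#' @return a `protein_sequence`.
#' @export
generate_protein <- function(length = 189L, seed = 1L, id = "synthetic") {
  stopifnot(length >= 1L)
  set.seed(seed)
  protein_sequence(id, paste(sample(AA_ALPHABET, length, replace = TRUE),
                             collapse = ""))
}

#' Generate a protein-conditional interaction dataset
#'
#' Two targets with opposite activity rules: against target A a compound
#' is active iff it carries the pharmacophore, against target B iff it
#' does not. Neither the compound representation nor the protein
#' representation alone predicts the label; only their interaction does,
#' which is the signal the cross-coupled fusion is built to carry.
#'
#' @param n number of records (split evenly over the two targets).
#' @param seed RNG seed.
#' @param scaffold_pool_size scaffold diversity of the compound set.
#' @param protein_length length of the two synthetic targets.
#' @return list with `records` (activity table with `target_id` in
#'   `{"TA","TB"}`) and `proteins` (named list of `protein_sequence`).
#' @export
generate_interaction_dataset <- function(n = 600L, seed = 1L,
                                         scaffold_pool_size = 60L,
                                         protein_length = 60L) {
  pool <- scaffold_pool(scaffold_pool_size)
  proteins <- list(TA = generate_protein(protein_length, seed = seed + 101L,
                                         id = "TA"),
                   TB = generate_protein(protein_length, seed = seed + 202L,
                                         id = "TB"))
  set.seed(seed)
  has_pharma <- as.integer(stats::runif(n) < 0.5)
  target <- rep(c("TA", "TB"), length.out = n)
  smiles <- character(n)
  for (k in seq_len(n)) {
    core <- pool[[((k - 1L) %% length(pool)) + 1L]]
    pref <- if (has_pharma[k] == 1) sample(SYN_POS_PREFIXES, 1L)
            else sample(SYN_NEG_PREFIXES, 1L)
    smiles[k] <- paste0(pref, core)
  }
  label <- ifelse(target == "TA", has_pharma, 1L - has_pharma)
  ic50 <- draw_ic50(label, c(mu_pos = 0, mu_neg = 5, sigma = 1))
  records <- data.frame(id = sprintf("int%05d", seq_len(n)),
                        smiles = smiles, target_id = target,
                        ic50_nM = ic50, label = as.integer(label),
                        stringsAsFactors = FALSE)
  list(records = records, proteins = proteins)
}

#' Write an activity table as CSV
#' @param records activity data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_activity_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
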
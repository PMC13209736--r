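# Dataset construction: activity labeling, canonical-SMILES
# deduplication, Bemis-Murcko scaffold splitting and physicochemical
# library filtering.

#' Label activity records by IC50 threshold
#'
#' Records with IC50 at or below the threshold are labeled active (1),
#' records above it inactive (0). The boundary value is labeled active:
#' positives are defined with "<=". Records with a missing or
#' non-positive IC50 are rejected and reported in the `rejected`
#' attribute of the result.
#'
#' @param records data.frame with an `ic50_nM` column.
#' @param threshold_nM activity threshold in nM (default 6.1, the
#'   potency of the reference inhibitor that anchors the active class).
#' @return the labeled data.frame (rejected rows removed); the removed
#'   rows with a `reason` column are attached as `attr(., "rejected")`.
#' @export
label_by_ic50 <- function(records, threshold_nM = 6.1) {
  stopifnot(is.data.frame(records), "ic50_nM" %in% names(records),
            threshold_nM > 0)
  ic50 <- records$ic50_nM
  bad <- is.na(ic50) | !is.finite(ic50) | ic50 <= 0
  rejected <- records[bad, , drop = FALSE]
  if (nrow(rejected) > 0L) {
    rejected$reason <- ifelse(is.na(ic50[bad]), "missing ic50",
                              "non-positive ic50")
  }
  out <- records[!bad, , drop = FALSE]
  out$label <- as.integer(out$ic50_nM <= threshold_nM)
  attr(out, "rejected") <- rejected
  out
}

#' Deduplicate activity records by canonical SMILES
#'
#' Collapses records sharing a (canonical SMILES, target) pair to a
#' single record whose IC50 is the median of the duplicates, then
#' relabels it with the threshold rule. In `strict` mode, groups whose
#' duplicate labels disagree are dropped instead of collapsed.
#'
#' @param records labeled data.frame with `canonical_smiles`, `ic50_nM`,
#'   `label` and (optionally) `target_id` columns.
#' @param threshold_nM threshold used for relabeling collapsed records.
#' @param strict drop label-conflicted duplicate groups instead of
#'   resolving them by median.
#' @return deduplicated data.frame; the number of collapsed records is
#'   attached as `attr(., "n_collapsed")`.
#' @export
deduplicate <- function(records, threshold_nM = 6.1, strict = FALSE) {
  stopifnot(is.data.frame(records), "canonical_smiles" %in% names(records))
  tid <- if ("target_id" %in% names(records)) records$target_id else ""
  key <- paste(records$canonical_smiles, tid, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  keep <- logical(nrow(records))
  for (idx in groups) {
    if (length(idx) == 1L) {
      keep[idx[1L]] <- TRUE
      next
    }
    if (strict && length(unique(records$label[idx])) > 1L) next
    first <- idx[1L]
    med <- stats::median(records$ic50_nM[idx])
    records$ic50_nM[first] <- med
    records$label[first] <- as.integer(med <= threshold_nM)
    keep[first] <- TRUE
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "n_collapsed") <- nrow(records) - nrow(out)
  out
}

#' Scaffold-grouped train/validation/test split
#'
#' Groups records by Bemis-Murcko scaffold and assigns entire groups to
#' subsets with a constrained greedy strategy: groups are visited in
#' decreasing size (ties broken by scaffold string) and each is placed in
#' the subset that minimizes
#' sum over subsets of (size fraction - target)^2 + lambda *
#' mass-weighted (positive rate - global rate)^2,
#' evaluated with the group tentatively added (the label term of subset s
#' is weighted by its size fraction). No scaffold ever straddles
#' two subsets, so there is no scaffold leakage by construction. All
#' acyclic molecules share the empty scaffold and move as one group
#' unless `acyclic_as_singletons` is set.
#'
#' @param records labeled, deduplicated data.frame with
#'   `canonical_smiles` and `label` columns (a `scaffold` column is used
#'   if present, otherwise scaffolds are computed).
#' @param fractions target subset fractions, summing to 1.
#' @param lambda weight of the label-balance term (default 1).
#' @param acyclic_as_singletons treat each acyclic molecule as its own
#'   group instead of pooling them under the empty scaffold.
#' @return a `split_assignment`: list with `assignment` (the records plus
#'   a `split` column), `report` (per-subset sizes, fractions, positive
#'   rates and deviations) and `scaffold_table` (scaffold to subset).
#'   The greedy pass is deterministic for fixed input.
#' @export
scaffold_split <- function(records, fractions = c(train = 0.8, val = 0.1,
                                                  test = 0.1),
                           lambda = 1, acyclic_as_singletons = FALSE) {
  stopifnot(is.data.frame(records), "label" %in% names(records),
            abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3L)
  subsets <- names(fractions) %||% c("train", "val", "test")
  if (is.null(names(fractions))) names(fractions) <- subsets
  scaf <- if ("scaffold" %in% names(records)) {
    records$scaffold
  } else {
    murcko_scaffold(records$canonical_smiles)
  }
  gkey <- scaf
  if (acyclic_as_singletons) {
    acy <- which(gkey == "")
    gkey[acy] <- paste0("\r", records$canonical_smiles[acy])
  }
  groups <- split(seq_len(nrow(records)), gkey)
  if (length(groups) < 3L) {
    warning("fewer than 3 scaffold groups; some subsets will be empty")
  }
  sizes <- lengths(groups)
  ord <- order(-sizes, names(groups))
  groups <- groups[ord]
  N <- nrow(records)
  global_pos <- mean(records$label)
  sub_n <- stats::setNames(numeric(3L), subsets)
  sub_pos <- stats::setNames(numeric(3L), subsets)
  assign_to <- character(length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    gn <- length(idx)
    gp <- sum(records$label[idx])
    costs <- vapply(subsets, function(s) {
      n2 <- sub_n
      p2 <- sub_pos
      n2[s] <- n2[s] + gn
      p2[s] <- p2[s] + gp
      rate_dev <- ifelse(n2 > 0, p2 / pmax(n2, 1) - global_pos, 0)
      # label deviations are weighted by subset mass so that a small
      # subset's noisy rate cannot veto every placement into it
      sum((n2 / N - fractions)^2) + lambda * sum((n2 / N) * rate_dev^2)
    }, numeric(1))
    pick <- subsets[which.min(costs)]  # ties: first of train, val, test
    assign_to[g] <- pick
    sub_n[pick] <- sub_n[pick] + gn
    sub_pos[pick] <- sub_pos[pick] + gp
  }
  split_col <- character(N)
  for (g in seq_along(groups)) split_col[groups[[g]]] <- assign_to[g]
  records$scaffold <- scaf
  records$split <- split_col
  report <- data.frame(
    subset = subsets,
    n = as.integer(sub_n[subsets]),
    fraction = as.numeric(sub_n[subsets] / N),
    target_fraction = as.numeric(fractions[subsets]),
    positive_rate = as.numeric(ifelse(sub_n[subsets] > 0,
                                      sub_pos[subsets] / pmax(sub_n[subsets], 1),
                                      NA_real_)),
    global_positive_rate = global_pos
  )
  report$size_deviation <- report$fraction - report$target_fraction
  report$rate_deviation <- report$positive_rate - global_pos
  scaffold_table <- data.frame(scaffold = names(groups),
                               n = as.integer(lengths(groups)),
                               subset = assign_to, stringsAsFactors = FALSE)
  structure(list(assignment = records, report = report,
                 scaffold_table = scaffold_table),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("<split_assignment>\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Physicochemical filter criteria
#'
#' Inclusive descriptor windows for library filtering. The defaults are
#' the property windows of known inhibitors of the screening target,
#' which sit well outside Lipinski space (high molecular weight, high
#' LogP).
#'
#' @param mw molecular-weight window in Da.
#' @param logp Crippen LogP window.
#' @param hbd hydrogen-bond donor window.
#' @param hba hydrogen-bond acceptor window.
#' @return a `filter_criteria` list.
#' @export
filter_criteria <- function(mw = c(550, 1500), logp = c(4, 8),
                            hbd = c(1, 4), hba = c(7, 13)) {
  for (w in list(mw, logp, hbd, hba)) stopifnot(length(w) == 2L, w[1] <= w[2])
  structure(list(mw = mw, logp = logp, hbd = hbd, hba = hba),
            class = "filter_criteria")
}

#' Filter a compound library by descriptor windows
#'
#' A molecule survives iff all four descriptors fall inside the inclusive
#' windows. The rejection log records the first failing criterion per
#' molecule (checked in the order mw, logp, hbd, hba). Unparsable SMILES
#' are logged with reason "parse" and excluded, not fatal. Survivors are
#' deduplicated by canonical SMILES after filtering.
#'
#' @param records data.frame with `smiles` (and optionally `id`).
#' @param criteria a [filter_criteria()].
#' @return list with `survivors` (records plus descriptor columns,
#'   deduplicated), `rejections` (data.frame id/smiles/reason) and
#'   `counts`.
#' @export
filter_library <- function(records, criteria = filter_criteria()) {
  stopifnot(is.data.frame(records), "smiles" %in% names(records),
            inherits(criteria, "filter_criteria"))
  if (!"id" %in% names(records)) {
    records$id <- sprintf("mol%05d", seq_len(nrow(records)))
  }
  prof <- chem_profile(records$smiles)
  reason <- rep(NA_character_, nrow(records))
  reason[!is.na(prof$error)] <- "parse"
  inside <- function(x, w) !is.na(x) & x >= w[1] & x <= w[2]
  ok <- is.na(reason)
  fail_mw <- ok & !inside(prof$mw, criteria$mw)
  reason[fail_mw] <- "mw"
  ok <- is.na(reason)
  fail_logp <- ok & !inside(prof$logp, criteria$logp)
  reason[fail_logp] <- "logp"
  ok <- is.na(reason)
  fail_hbd <- ok & !inside(prof$hbd, criteria$hbd)
  reason[fail_hbd] <- "hbd"
  ok <- is.na(reason)
  fail_hba <- ok & !inside(prof$hba, criteria$hba)
  reason[fail_hba] <- "hba"
  surv <- is.na(reason)
  survivors <- records[surv, , drop = FALSE]
  survivors$canonical_smiles <- prof$canonical_smiles[surv]
  survivors$mw <- prof$mw[surv]
  survivors$logp <- prof$logp[surv]
  survivors$hbd <- prof$hbd[surv]
  survivors$hba <- prof$hba[surv]
  dup <- duplicated(survivors$canonical_smiles)
  n_dup <- sum(dup)
  survivors <- survivors[!dup, , drop = FALSE]
  rejections <- data.frame(id = records$id[!surv],
                           smiles = records$smiles[!surv],
                           reason = reason[!surv], stringsAsFactors = FALSE)
  list(survivors = survivors, rejections = rejections,
       counts = list(input = nrow(records), survivors = nrow(survivors),
                     rejected = nrow(rejections), duplicates = n_dup,
                     unparsable = sum(reason == "parse", na.rm = TRUE)))
}

#' Write a rejection log as TSV
#' @param rejections data.frame with `id` and `reason`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_rejection_log <- function(rejections, path) {
  utils::write.table(rejections, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
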
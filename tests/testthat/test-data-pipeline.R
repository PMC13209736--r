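# Dataset construction: labeling, deduplication, scaffolds, splitting,
# filtering.

test_that("IC50 labeling uses <= at the threshold and rejects bad records", {
  df <- data.frame(id = as.character(1:5), smiles = "CCO",
                   ic50_nM = c(1.0, 100, 6.1, NA, -2))
  out <- label_by_ic50(df)
  expect_equal(out$label, c(1L, 0L, 1L))   # 6.1 itself is active
  rej <- attr(out, "rejected")
  expect_equal(nrow(rej), 2L)
  expect_setequal(rej$reason, c("missing ic50", "non-positive ic50"))
})

test_that("labeling is monotone in the threshold", {
  set.seed(41)
  df <- data.frame(ic50_nM = exp(rnorm(200, 2, 2)))
  lab_hi <- label_by_ic50(df, threshold_nM = 10)$label
  lab_lo <- label_by_ic50(df, threshold_nM = 2)$label
  expect_true(all(lab_lo <= lab_hi))  # lowering never creates positives
})

test_that("deduplication collapses by canonical SMILES with median IC50", {
  df <- data.frame(id = c("a", "b", "c"),
                   smiles = c("CCO", "OCC", "CCC"),
                   target_id = "T1",
                   ic50_nM = c(2, 10, 50))
  df$canonical_smiles <- canonicalize_smiles(df$smiles)
  df <- label_by_ic50(df)
  out <- deduplicate(df)
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "n_collapsed"), 1L)
  merged <- out[out$canonical_smiles == canonicalize_smiles("CCO"), ]
  expect_equal(merged$ic50_nM, 6.0)   # median of {2, 10}
  expect_equal(merged$label, 1L)      # 6.0 <= 6.1
  # strict mode drops the conflicted group instead
  strict <- deduplicate(df, strict = TRUE)
  expect_equal(nrow(strict), 1L)
  # distinct molecules are untouched
  solo <- deduplicate(df[df$smiles == "CCC", , drop = FALSE])
  expect_equal(nrow(solo), 1L)
  expect_equal(attr(solo, "n_collapsed"), 0L)
})

test_that("Murcko scaffolds strip side chains; acyclic molecules are empty", {
  expect_equal(murcko_scaffold("c1ccccc1"), "c1ccccc1")
  expect_equal(murcko_scaffold("Cc1ccccc1"), "c1ccccc1")
  expect_equal(murcko_scaffold("CCO"), "")
  expect_equal(murcko_scaffold("NC(=O)c1ccccc1"), "c1ccccc1")
})

test_that("ten singleton scaffold groups split exactly 8/1/1", {
  df <- data.frame(
    id = sprintf("m%02d", 1:10),
    canonical_smiles = sprintf("mol%02d", 1:10),
    scaffold = sprintf("scaf%02d", 1:10),  # ten distinct groups of one
    label = rep(1L, 10)
  )
  sp <- scaffold_split(df)
  counts <- table(sp$assignment$split)
  expect_equal(as.integer(counts[c("train", "val", "test")]), c(8L, 1L, 1L))

  # independent check: enumerate the greedy steps by brute force
  fracs <- c(train = 0.8, val = 0.1, test = 0.1)
  n <- c(train = 0, val = 0, test = 0)
  for (step in 1:10) {
    costs <- sapply(names(fracs), function(s) {
      n2 <- n
      n2[s] <- n2[s] + 1
      sum((n2 / 10 - fracs)^2)   # all labels equal: no rate term
    })
    pick <- names(fracs)[which.min(costs)]
    n[pick] <- n[pick] + 1
  }
  expect_equal(as.integer(counts[names(fracs)]), as.integer(n))
})

test_that("a single shared scaffold keeps every record in train", {
  df <- data.frame(id = as.character(1:6),
                   canonical_smiles = sprintf("m%d", 1:6),
                   scaffold = "only", label = c(1, 0, 1, 0, 1, 0))
  expect_warning(sp <- scaffold_split(df), "fewer than 3")
  expect_true(all(sp$assignment$split == "train"))
})

test_that("scaffold split on a 1000-molecule library is leak-free and balanced", {
  spec <- synthetic_spec(n_molecules = 1000, seed = 7,
                         scaffold_pool_size = 100, positive_rate = 0.4)
  ds <- generate_activity_dataset(spec)
  ds$canonical_smiles <- ds$smiles
  ds$scaffold <- murcko_scaffold(ds$smiles)
  expect_gte(length(unique(ds$scaffold)), 100L)
  sp <- scaffold_split(ds)
  a <- sp$assignment
  # hard invariant: partition with zero scaffold leakage
  expect_equal(sort(a$id), sort(ds$id))
  leak <- tapply(a$split, a$scaffold, function(s) length(unique(s)))
  expect_true(all(leak == 1L))
  # balance: sizes within +/-0.05 of 8:1:1; positive rates within 0.05
  fr <- prop.table(table(a$split))
  expect_lt(abs(fr[["train"]] - 0.8), 0.05)
  expect_lt(abs(fr[["val"]] - 0.1), 0.05)
  expect_lt(abs(fr[["test"]] - 0.1), 0.05)
  global <- mean(a$label)
  for (s in c("train", "val", "test")) {
    expect_lt(abs(mean(a$label[a$split == s]) - global), 0.05)
  }
  # determinism
  sp2 <- scaffold_split(ds)
  expect_identical(sp$assignment$split, sp2$assignment$split)
})

test_that("library filtering equals an independent bound-check loop", {
  spec <- synthetic_spec(n_molecules = 200, seed = 13,
                         scaffold_pool_size = 50)
  lib <- generate_library(spec, heavy_fraction = 0.3)
  res <- filter_library(lib)
  desc <- compute_descriptors(lib$smiles)
  keep <- logical(nrow(lib))
  for (i in seq_len(nrow(lib))) {
    keep[i] <- desc$mw[i] >= 550 && desc$mw[i] <= 1500 &&
      desc$logp[i] >= 4 && desc$logp[i] <= 8 &&
      desc$hbd[i] >= 1 && desc$hbd[i] <= 4 &&
      desc$hba[i] >= 7 && desc$hba[i] <= 13
  }
  oracle_ids <- lib$id[keep]
  oracle_ids <- oracle_ids[!duplicated(canonicalize_smiles(lib$smiles[keep]))]
  expect_setequal(res$survivors$id, oracle_ids)
  expect_gt(nrow(res$survivors), 0L)  # the heavy family is in-window
  expect_equal(res$counts$input, 200L)
})

test_that("filter rejections record the first failing criterion", {
  lib <- data.frame(id = c("small", "engineered", "broken"),
                    smiles = c("CCO",
                               "Oc1ccc(CN2CCN(Cc3ccc(Oc4ccc(CN5CCN(Cc6ccc(OC)cc6)CC5)cc4)cc3)CC2)cc1",
                               "C1CC"))
  res <- filter_library(lib)
  expect_equal(res$survivors$id, "engineered")
  expect_equal(res$rejections$reason[res$rejections$id == "small"], "mw")
  expect_equal(res$rejections$reason[res$rejections$id == "broken"], "parse")
  expect_equal(res$counts$unparsable, 1L)
})

test_that("filtering is order-independent", {
  spec <- synthetic_spec(n_molecules = 60, seed = 17, scaffold_pool_size = 20)
  lib <- generate_library(spec, heavy_fraction = 0.4)
  res1 <- filter_library(lib)
  set.seed(1)
  res2 <- filter_library(lib[sample(nrow(lib)), , drop = FALSE])
  expect_setequal(res1$survivors$canonical_smiles,
                  res2$survivors$canonical_smiles)
  expect_equal(res1$counts$survivors, res2$counts$survivors)
})
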
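# SMILES canonicalization, graph featurization, descriptors, batching.

test_that("canonicalization is idempotent and collapses equivalent writings", {
  s <- c("OCC", "CCO", "c1ccccc1", "C(C)O")
  canon <- canonicalize_smiles(s)
  expect_identical(canon[1], canon[2])
  expect_identical(canon[1], canon[4])
  expect_identical(canonicalize_smiles(canon), canon)
})

test_that("unparsable SMILES raise a parse error naming the input", {
  expect_error(canonicalize_smiles("C1CC"), "C1CC")
  expect_error(featurize_molecule("not_a_molecule"), "parse")
  expect_error(compute_descriptors("C1CC"), "parse")
})

test_that("featurization has the 74/12 layout and mirrored directed edges", {
  g1 <- featurize_molecule("C")          # methane: single heavy atom
  expect_equal(g1$num_atoms, 1L)
  expect_equal(dim(g1$atom_features), c(1L, 74L))
  expect_equal(nrow(g1$edges), 0L)

  g2 <- featurize_molecule("CC")         # ethane: one bond, two directed edges
  expect_equal(g2$num_atoms, 2L)
  expect_equal(nrow(g2$edges), 2L)
  expect_equal(dim(g2$bond_features), c(2L, 12L))
  expect_equal(g2$bond_features[1, ], g2$bond_features[2, ])

  gb <- featurize_molecule("c1ccccc1")   # benzene
  expect_equal(gb$num_atoms, 6L)
  expect_equal(nrow(gb$edges), 12L)
  # aromaticity flag: element(43) + degree(11) + valence(7) + charge(1) +
  # radicals(1) + hybridization(5) = position 68, aromatic bit at 69
  expect_equal(gb$atom_features[, 69L], rep(1, 6))
  # aromatic bond-type bit is the 4th of the bond-type one-hot
  expect_equal(gb$bond_features[, 4L], rep(1, 12))
})

test_that("adjacency matches the edge list: symmetric, zero diagonal", {
  lib <- generate_library(synthetic_spec(n_molecules = 100, seed = 21,
                                         scaffold_pool_size = 30))
  graphs <- featurize_molecules(lib$smiles)
  for (g in graphs) {
    adj <- matrix(0, g$num_atoms, g$num_atoms)
    if (nrow(g$edges) > 0) adj[g$edges] <- 1
    expect_identical(adj, g$adjacency)
    expect_identical(g$adjacency, t(g$adjacency))
    expect_true(all(diag(g$adjacency) == 0))
  }
})

test_that("featurization is invariant to the SMILES writing", {
  for (s in c("OCC", "C(C)(C)c1ccccc1", "n1ccccc1C")) {
    ga <- featurize_molecule(s)
    gb <- featurize_molecule(canonicalize_smiles(s))
    expect_equal(ga$num_atoms, gb$num_atoms)
    expect_equal(nrow(ga$edges), nrow(gb$edges))
    # equal as multisets of feature rows and degree sequences
    sort_rows <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]
    expect_equal(sort_rows(ga$atom_features), sort_rows(gb$atom_features))
    expect_equal(sort(rowSums(ga$adjacency)), sort(rowSums(gb$adjacency)))
  }
})

test_that("descriptors match frozen reference values", {
  d <- compute_descriptors(c("c1ccccc1", "CCO", "C"))
  expect_equal(d$hbd, c(0L, 1L, 0L))      # benzene has no donors
  expect_equal(d$hba[2], 1L)              # ethanol: one acceptor
  expect_equal(d$mw[3], 16.04, tolerance = 1e-3)  # 12.011 + 4 * 1.008
})

test_that("batching is block-diagonal with exact membership", {
  g1 <- featurize_molecule("CC")
  g2 <- featurize_molecule("CCO")
  b <- batch_graphs(list(g1, g2))
  expect_equal(b$num_atoms, 5L)
  expect_equal(b$membership, c(1L, 1L, 2L, 2L, 2L))
  # edges of graph 2 offset by 2; no cross-graph edges
  expect_true(all(b$edges[3:6, ] >= 3L))
  expect_equal(nrow(b$edges), 2L + 4L)
  m1 <- b$membership[b$edges[, 1]]
  m2 <- b$membership[b$edges[, 2]]
  expect_true(all(m1 == m2))
  # singleton batch keeps the graph intact
  b1 <- batch_graphs(list(g1))
  expect_equal(b1$atom_features, g1$atom_features)
  expect_equal(b1$edges, g1$edges)
  expect_error(batch_graphs(list()), "length")
})

test_that("the graph cache round-trips and flags stale featurizers", {
  path <- tempfile(fileext = ".rds")
  write_graph_cache(c("CCO", "OCC", "c1ccccc1"), path)
  cache <- read_graph_cache(path)
  expect_length(cache, 2L)  # CCO and OCC share one canonical key
  expect_setequal(names(cache), canonicalize_smiles(c("CCO", "c1ccccc1")))
  expect_equal(cache[["CCO"]]$num_atoms, 3L)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  meta$featurizer <- "other-version"
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  expect_warning(read_graph_cache(path), "other-version")
})
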
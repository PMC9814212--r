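# Featurization: layout, one-hot structure, symmetry, invariances.

test_that("single-atom and symmetric molecules featurize as expected", {
  f <- featurize("C")
  expect_identical(nrow(f$node_features), 1L)
  expect_identical(ncol(f$node_features), 27L)
  expect_identical(f$node_features[1, 11], 1)  # degree 0
  expect_identical(f$node_features[1, 21], 1)  # 4 hydrogens

  fb <- featurize("c1ccccc1")
  expect_identical(nrow(fb$node_features), 6L)
  # perfect symmetry: six identical rows
  expect_identical(unique(as.data.frame(fb$node_features)),
                   as.data.frame(fb$node_features)[1, ])
  expect_true(all(fb$node_features[, 23] == 1))  # aromatic
  expect_true(all(fb$node_features[, 24] == 1))  # in ring
})

test_that("one-hot blocks sum to one and all values are finite", {
  blocks <- list(1:10, 11:16, 17:21, 25:27)
  for (s in FIXTURE_SMILES) {
    X <- featurize(s)$node_features
    expect_true(all(is.finite(X)), info = s)
    for (bl in blocks)
      expect_true(all(abs(rowSums(X[, bl, drop = FALSE]) - 1) < 1e-12),
                  info = s)
  }
})

test_that("neighbor lists are symmetric", {
  for (s in FIXTURE_SMILES) {
    f <- featurize(s)
    for (v in seq_along(f$neighbors)) {
      for (u in f$neighbors[[v]])
        expect_true(v %in% f$neighbors[[u]], info = s)
    }
  }
})

test_that("featurization is permutation-equivariant over random reorderings", {
  set.seed(99)
  smis <- generate_molecules(100, seed = 55)
  for (s in smis) {
    mol <- parse_smiles(s)
    f0 <- featurize(mol)
    perm <- sample(mol$natoms)
    fp <- featurize(permute_molgraph(mol, perm))
    # row v of the original ends up at row perm[v] in the permuted version
    expect_equal(fp$node_features[perm, , drop = FALSE], f0$node_features,
                 info = s)
    expect_identical(as.integer(fp$degree_histogram),
                     as.integer(f0$degree_histogram), info = s)
  }
})

test_that("all SMILES dialects of one molecule collapse to one graph", {
  for (s in c("CCO", "CC(C)=O", "c1ccc2ccccc2c1", "CC(=O)Nc1ccc(O)cc1")) {
    mol <- parse_smiles(s)
    variants <- c(s, mol_to_smiles(mol), mol_to_smiles(mol, explicit_h = TRUE))
    mats <- lapply(variants, function(v) {
      m <- parse_smiles(v)
      rk <- logpnet:::.canon_ranks(m)
      featurize(m)$node_features[order(rk), , drop = FALSE]
    })
    expect_equal(mats[[2]], mats[[1]], info = s)
    expect_equal(mats[[3]], mats[[1]], info = s)
  }
})

test_that("unfamiliar elements fall into the other bucket with a warning", {
  expect_warning(f <- featurize("CC[Se]CC"), "other")
  expect_identical(f$node_features[3, 10], 1)
})
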
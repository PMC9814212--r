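# Curation: outlier flags, ensemble rule, duplicate groups, NHA bins.

test_that("single-model outlier flag uses a strict threshold", {
  # chlorpromazine-magnitude correction: |5.41 - 4.00| = 1.41 > 1
  fl <- flag_outliers(5.41, 4.00, ids = "chlorpromazine")
  expect_identical(nrow(fl), 1L)
  expect_identical(fl$flag_kind, "outlier_single")
  # exact agreement and exact-boundary cases are not flagged
  expect_identical(nrow(flag_outliers(c(2, 3), c(2, 3))), 0L)
  expect_identical(nrow(flag_outliers(3, 2)), 0L)          # |d| == 1.0
  expect_identical(nrow(flag_outliers(3, 1.9999)), 1L)
  # flag_outliers(x, x) empty for any x
  set.seed(2)
  x <- rnorm(100)
  expect_identical(nrow(flag_outliers(x, x)), 0L)
})

test_that("ensemble flag requires at least min_tools disagreeing tools", {
  exp_v <- rep(2, 3)
  tools <- matrix(2, nrow = 3, ncol = 7)
  tools[1, 1:4] <- 3.2   # 4 of 7 off by 1.2 -> flagged
  tools[2, 1:3] <- 3.2   # 3 of 7 off       -> not flagged
  fl <- ensemble_flag(exp_v, tools, ids = c("a", "b", "c"))
  expect_identical(fl$parent_id, "a")
  expect_match(fl$evidence, "\"n_disagreeing\":4")
  # NA predictions abstain
  tools[3, ] <- NA
  tools[3, 1:4] <- 3.5
  fl2 <- ensemble_flag(exp_v, tools, ids = c("a", "b", "c"))
  expect_setequal(fl2$parent_id, c("a", "c"))
})

test_that("ensemble with min_tools = 1 equals the union of per-tool flags", {
  set.seed(31)
  exp_v <- rnorm(60)
  tools <- sapply(1:5, function(k) exp_v + rnorm(60, sd = 0.8))
  union_ids <- sort(unique(unlist(lapply(1:5, function(k)
    flag_outliers(exp_v, tools[, k])$parent_id))))
  ens <- ensemble_flag(exp_v, tools, min_tools = 1L)
  expect_identical(sort(ens$parent_id), union_ids)
})

test_that("duplicate detection groups tautomer and salt pairs", {
  recs <- list(
    molecule_record("nitrosophenol", "O=Nc1ccc(O)cc1", 1.29),
    molecule_record("quinone_monoxime", "ON=C1C=CC(=O)C=C1", 1.08),
    molecule_record("octanoic_acid", "CCCCCCCC(=O)O", 3.05),
    molecule_record("sodium_octanoate", "CCCCCCCC(=O)[O-].[Na+]", -1.38),
    molecule_record("benzene", "c1ccccc1", 2.13),
    molecule_record("ethanol_a", "CCO", -0.31),
    molecule_record("ethanol_b", "OCC", -0.30))
  dup <- find_duplicates(recs)
  expect_identical(nrow(dup), 3L)
  taut <- dup[grepl("nitrosophenol", dup$ids), ]
  expect_identical(taut$kind, "duplicate_tautomer")
  expect_equal(taut$spread, 0.21, tolerance = 1e-12)
  salt <- dup[grepl("octanoate", dup$ids), ]
  expect_identical(salt$kind, "duplicate_salt_pair")
  expect_equal(salt$spread, 4.43, tolerance = 1e-12)
  ident <- dup[grepl("ethanol", dup$ids), ]
  expect_identical(ident$kind, "duplicate_structure")
  expect_false(any(grepl("benzene", dup$ids)))
  # unrelated molecules produce no groups
  expect_identical(nrow(find_duplicates(recs[c(5, 6)])), 0L)
})

test_that("rmse_by_nha bins correctly and satisfies the pooled identity", {
  mols <- c("C", "CCCCCCCCCCCC", "c1ccccc1")      # NHA 1, 12, 6
  out <- rmse_by_nha(c(1, 1, 1), c(1, 3, 1), mols)
  expect_identical(out$n, c(2L, 1L, 0L, 0L))
  expect_identical(out$rmse[1], 0)
  expect_identical(out$rmse[2], 2)
  expect_true(is.na(out$rmse[3]))

  # pooled identity on random fixtures: sum n_b rmse_b^2 = n rmse^2
  set.seed(77)
  smis <- generate_molecules(120, seed = 9)
  ex <- rnorm(120); pr <- ex + rnorm(120, sd = 0.7)
  tab <- rmse_by_nha(ex, pr, smis)
  lhs <- sum(tab$n * tab$rmse^2, na.rm = TRUE)
  expect_equal(lhs, 120 * rmse(pr, ex)^2, tolerance = 1e-9)
  # all items in one bin reproduces the global rmse
  one <- rmse_by_nha(ex, pr, smis, bin_edges = c(0, Inf))
  expect_equal(one$rmse, rmse(pr, ex), tolerance = 1e-12)
})
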
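# Dataset I/O, normalization, salt stripping, variant tables, splitting.

make_csv <- function(df) {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  p
}

test_that("read_dataset accepts parseable rows and logs rejections", {
  p <- make_csv(data.frame(id = c("a", "b", "c"),
                           smiles = c("CCO", "", "c1ccccc1"),
                           logp_exp = c(-0.2, 1, 1.8)))
  ds <- suppressWarnings(read_dataset(p))
  expect_identical(ds$n_accepted, 2L)
  expect_identical(ds$n_rejected, 1L)
  expect_identical(ds$rejected$row, 2L)

  # header-only file
  p2 <- make_csv(data.frame(id = character(0), smiles = character(0),
                            logp_exp = numeric(0)))
  ds2 <- read_dataset(p2)
  expect_identical(ds2$n_accepted, 0L)
  expect_identical(ds2$n_rejected, 0L)

  expect_error(read_dataset(tempfile()), "not found")
  p3 <- make_csv(data.frame(id = "a", structure = "CCO"))
  expect_error(read_dataset(p3), "mandatory column")
})

test_that("write(read(f)) round-trips id/smiles/logp byte-identically", {
  df <- data.frame(id = c("m1", "m2", "m3"),
                   smiles = c("CCO", "CC(C)=O", "Clc1ccc(Br)cc1"),
                   logp_exp = c("-0.31", "0.5", "3.05"))
  p <- make_csv(df)
  ds <- read_dataset(p)
  p2 <- tempfile(fileext = ".csv")
  write_dataset(ds$records, p2)
  back <- utils::read.csv(p2, colClasses = "character")
  expect_identical(back$id, df$id)
  expect_identical(back$smiles, df$smiles)
  expect_identical(back$logp_exp, df$logp_exp)
})

test_that("labels outside the typical range warn but are kept", {
  p <- make_csv(data.frame(id = "x", smiles = "CCO", logp_exp = 15))
  expect_warning(ds <- read_dataset(p), "outside typical range")
  expect_identical(ds$n_accepted, 1L)
})

test_that("normalize_structure rewrites hypervalent nitro groups", {
  expect_identical(canonical_smiles(normalize_structure("CN(=O)=O")),
                   canonical_smiles("C[N+](=O)[O-]"))
  # idempotence and identity cases
  for (s in c("C[N+](=O)[O-]", "CCO", "c1ccccc1", "CC(N)=O")) {
    m1 <- normalize_structure(s)
    expect_identical(mol_to_smiles(normalize_structure(m1)), mol_to_smiles(m1),
                     info = s)
    if (!grepl("N\\(=O\\)=O", s))
      expect_identical(mol_to_smiles(m1), canonical_smiles(s), info = s)
  }
  # azide dative form
  expect_identical(canonical_smiles(normalize_structure("CN=N#N")),
                   canonical_smiles("CN=[N+]=[N-]"))
})

test_that("strip_salt returns the neutralized parent and counterions", {
  s <- strip_salt("CCCCCCCC(=O)[O-].[Na+]")
  expect_identical(mol_to_smiles(s$mol), canonical_smiles("CCCCCCCC(=O)O"))
  expect_identical(s$counterions, "[Na+]")
  expect_false(s$ambiguous)

  single <- strip_salt("c1ccccc1")
  expect_identical(mol_to_smiles(single$mol), canonical_smiles("c1ccccc1"))
  expect_length(single$counterions, 0L)

  dimer <- strip_salt("CC(=O)O.CC(=O)O")
  expect_true(dimer$ambiguous)

  # idempotence on all fixtures
  for (s2 in c("CCCCCCCC(=O)[O-].[Na+]", "C[NH3+].[Cl-]", "CCO")) {
    once <- strip_salt(s2)$mol
    twice <- strip_salt(once)$mol
    expect_identical(mol_to_smiles(twice), mol_to_smiles(once), info = s2)
  }
})

test_that("build_variant_table merges duplicate canonical graphs", {
  # no tautomers, original == canonical graph -> single row
  r1 <- molecule_record("x", "CCO", 0.5)
  t1 <- build_variant_table(r1)
  expect_identical(nrow(t1), 1L)
  expect_identical(t1$variant_kind, "original")

  # keto compound with two distinct enols -> >= 3 unique-graph rows
  r2 <- molecule_record("y", "CC(=O)CCC", 1.0)
  t2 <- build_variant_table(r2)
  expect_gte(nrow(t2), 3L)
  expect_true(all(t2$label == 1.0))
  # duplicate-merge invariant: one row per canonical graph
  canon <- vapply(t2$variant_smiles, canonical_smiles, "")
  expect_identical(length(unique(canon)), nrow(t2))
})

test_that("split_dataset reproduces the published size arithmetic", {
  ids <- sprintf("id%05d", seq_len(13889))
  sp <- split_dataset(ids, seed = 11)
  expect_identical(sum(sp$partition == "test"), 1389L)
  expect_identical(sum(sp$partition != "test"), 12500L)
  expect_identical(sum(sp$partition == "valid"), 2500L)
  expect_identical(sum(sp$partition == "train"), 10000L)

  sp10 <- split_dataset(sprintf("x%d", 1:10), seed = 1)
  expect_identical(sum(sp10$partition == "test"), 1L)
  expect_identical(sum(sp10$partition == "valid"), 2L)
  expect_identical(sum(sp10$partition == "train"), 7L)
})

test_that("splitting is deterministic and leakage-free", {
  ids <- sprintf("p%04d", seq_len(1000))
  a <- split_dataset(ids, seed = 7)
  b <- split_dataset(ids, seed = 7)
  expect_identical(a, b)
  d <- split_dataset(ids, seed = 8)
  expect_false(identical(a$partition, d$partition))
  expect_identical(sort(table(d$partition)), sort(table(a$partition)))
  # every parent in exactly one partition
  expect_identical(sort(a$parent_id), sort(ids))
  expect_true(all(table(a$parent_id) == 1L))
  # variants inherit the parent partition (no leakage)
  vr <- data.frame(parent_id = rep(ids, each = 3),
                   variant_smiles = "CCO", variant_kind = "tautomer",
                   label = 0)
  for (part in c("train", "valid", "test")) {
    sel <- variants_in_partition(vr, a, part)
    want <- a$parent_id[a$partition == part]
    expect_setequal(unique(sel$parent_id), want)
    expect_identical(nrow(sel), 3L * length(want))
  }
  expect_error(split_dataset(ids, test_frac = 1.2), "fractions")
  expect_error(split_dataset(ids[1:2]), "at least 3")
})

test_that("SDF reader recovers structures, charges and the log P field", {
  sdf <- c("benzoate", "", "",
           " 9  9  0  0  0  0  0  0  0  0999 V2000",
           sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   c("C", "C", "C", "C", "C", "C", "C", "O", "O")),
           "  1  2  4  0", "  2  3  4  0", "  3  4  4  0", "  4  5  4  0",
           "  5  6  4  0", "  6  1  4  0", "  1  7  1  0", "  7  8  2  0",
           "  7  9  1  0",
           "M  CHG  1   9  -1",
           "M  END",
           "> <LOGP>", "1.87", "", "$$$$")
  p <- tempfile(fileext = ".sdf")
  writeLines(sdf, p)
  recs <- read_sdf(p)
  expect_length(recs, 1L)
  expect_identical(recs[[1]]$logp_exp, 1.87)
  expect_identical(canonical_smiles(recs[[1]]$smiles),
                   canonical_smiles("[O-]C(=O)c1ccccc1"))
})
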
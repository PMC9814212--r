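# Synthetic world: oracle arithmetic, generator statistics, dataset labels.

test_that("oracle_logp matches hand sums", {
  expect_equal(oracle_logp("C"), 0.40)
  expect_equal(oracle_logp("CCO"), 2 * 0.40 - 1.00)
  expect_equal(oracle_logp("c1ccccc1"), 6 * 0.30)
  # ketone vs its enol: carbonyl O swaps to enol hydroxyl (delta +0.35)
  expect_equal(oracle_logp("CC(C)=O"), 3 * 0.40 - 0.70)
  expect_equal(oracle_logp("CC(O)=C"), 3 * 0.40 - 1.00 + 0.35)
})

test_that("oracle is additive over disconnected unions", {
  for (pair in list(c("CCO", "c1ccccc1"), c("CC(C)=O", "CSC"),
                    c("ClCC", "CCN"))) {
    u <- oracle_logp(paste(pair, collapse = "."))
    expect_equal(u, oracle_logp(pair[1]) + oracle_logp(pair[2]),
                 info = paste(pair, collapse = "."))
  }
})

test_that("macro_oracle mixes micro values with the stated fractions rule", {
  # no-tautomer molecule: macro equals micro
  m <- macro_oracle("CCO")
  expect_identical(m$macro, oracle_logp("CCO"))
  # acetone: keto micro k, enol micro k + delta; fractions (0.8, 0.2)
  k <- oracle_logp("CC(C)=O")
  delta <- (-1.00 + 0.35) - (-0.70)
  ma <- macro_oracle("CC(C)=O")
  expect_equal(sort(ma$micro_logps), sort(c(k, k + delta)))
  expect_equal(ma$fractions[match(canonical_smiles("CC(C)=O"), ma$members)], 0.8)
  expect_equal(ma$macro, log10(0.8 * 10^k + 0.2 * 10^(k + delta)),
               tolerance = 1e-12)
  # convexity: macro within the micro range
  for (s in c("CC(=O)CCC", "O=Nc1ccc(O)cc1", "CCC(=O)N")) {
    mm <- macro_oracle(s)
    expect_gte(mm$macro, min(mm$micro_logps) - 1e-12)
    expect_lte(mm$macro, max(mm$micro_logps) + 1e-12)
  }
})

test_that("generator is deterministic, valence-legal and size-bounded", {
  a <- generate_molecules(200, seed = 31)
  b <- generate_molecules(200, seed = 31)
  expect_identical(a, b)
  d <- generate_molecules(200, seed = 32)
  expect_false(identical(a, d))
  expect_identical(generate_molecules(0), character(0))
  nha <- vapply(a, count_nha, 0L)
  expect_true(all(nha >= 3L & nha <= 20L))
  for (s in a) expect_silent(parse_smiles(s))
})

test_that("motif frequencies land inside binomial 99 percent bounds", {
  n <- 500L
  smis <- generate_molecules(n, seed = 71)
  has_ketone <- vapply(smis, function(s) {
    m <- parse_smiles(s)
    any(vapply(seq_len(nrow(m$bonds)), function(k) {
      a <- m$bonds$a1[k]; b <- m$bonds$a2[k]
      if (m$bonds$order[k] != 2L) return(FALSE)
      oc <- if (m$elem[a] == "O") c(a, b) else if (m$elem[b] == "O") c(b, a)
            else return(FALSE)
      # carbonyl C with only carbon heavy neighbours -> ketone, not amide
      cn <- setdiff(c(m$bonds$a1[m$bonds$a1 == oc[2] | m$bonds$a2 == oc[2]],
                      m$bonds$a2[m$bonds$a1 == oc[2] | m$bonds$a2 == oc[2]]),
                    oc)
      length(cn) && all(m$elem[cn] == "C")
    }, TRUE))
  }, TRUE)
  has_nitroso <- grepl("N=O", smis, fixed = TRUE)
  has_amide <- grepl("C(=O)N", smis, fixed = TRUE)
  bounds <- function(p) n * p + c(-1, 1) * qnorm(0.995) * sqrt(n * p * (1 - p))
  for (probe in list(list(mean(has_ketone) * n, 0.30),
                     list(sum(has_nitroso), 0.05),
                     list(sum(has_amide), 0.15))) {
    b <- bounds(probe[[2]])
    expect_gte(probe[[1]], b[1])
    expect_lte(probe[[1]], b[2])
  }
})

test_that("dataset labels carry the configured measurement noise", {
  # noise-free labels equal the macro oracle exactly
  recs0 <- generate_dataset(30, seed = 5, spec = oracle_spec(noise_sigma = 0))
  for (r in recs0)
    expect_equal(r$logp_exp, macro_oracle(r$smiles)$macro, tolerance = 1e-12)
  # residual standard deviation at sigma = 0.1 within the chi-square band;
  # n = 400 keeps this test fast -- the 99% chi-square band for n = 400 is
  # (0.0882, 0.1118)
  recs <- memo_get("dataset_noise_400", function() generate_dataset(400, seed = 5))
  resid <- vapply(recs, function(r) r$logp_exp - macro_oracle(r$smiles)$macro, 0)
  n <- length(resid)
  lo <- 0.1 * sqrt(qchisq(0.005, n - 1) / (n - 1))
  hi <- 0.1 * sqrt(qchisq(0.995, n - 1) / (n - 1))
  expect_gte(sd(resid), lo)
  expect_lte(sd(resid), hi)
  # round-trip through dataset I/O
  p <- tempfile(fileext = ".csv")
  write_dataset(recs[1:10], p)
  back <- read_dataset(p)
  expect_identical(vapply(back$records, function(r) r$smiles, ""),
                   vapply(recs[1:10], function(r) r$smiles, ""))
  expect_equal(vapply(back$records, function(r) r$logp_exp, 0),
               vapply(recs[1:10], function(r) r$logp_exp, 0), tolerance = 1e-12)
})

test_that("about 30% of molecules carry two or more extra tautomers", {
  # internal ketones contribute two distinct enols; the binomial 99% band
  # around p = 0.3 at n = 1000 is approximately (255, 345)
  smis <- generate_molecules(1000, seed = 2)
  n_extra <- vapply(smis, function(s)
    length(enumerate_tautomers(s)$members) - 1L, 0L)
  cnt <- sum(n_extra >= 2L)
  expect_gt(cnt, 255L)
  expect_lt(cnt, 345L)
})
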
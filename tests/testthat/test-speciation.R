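# Speciation arithmetic: microstates, fractions, log D, macro log P,
# ionization classes.

test_that("microstate enumeration counts and charges are exact", {
  m0 <- enumerate_microstates(0, 0)
  expect_identical(nrow(m0), 1L)
  expect_identical(m0$charge, 0L)

  m11 <- enumerate_microstates(1, 1)
  expect_identical(nrow(m11), 4L)
  expect_setequal(m11$charge, c(1, 0, 0, -1))

  m20 <- enumerate_microstates(2, 0)
  expect_identical(nrow(m20), 4L)
  expect_identical(sort(m20$charge), c(-2L, -1L, -1L, 0L))
})

test_that("species fractions match closed forms", {
  # Henderson-Hasselbalch midpoint
  f <- species_fractions(pka_acidic = 7, pH = 7)
  expect_identical(f, c(0.5, 0.5))
  # one acidic site, pKa 7, pH 3
  f2 <- species_fractions(pka_acidic = 7, pH = 3)
  expect_equal(f2[1], 1 / (1 + 10^-4), tolerance = 1e-12)
  # extremes put all mass on fully (de)protonated states
  f3 <- species_fractions(pka_acidic = c(4, 9), pka_basic = 6, pH = -100)
  expect_equal(max(f3), 1, tolerance = 1e-12)
  ms <- enumerate_microstates(2, 1)
  expect_identical(ms$charge[which.max(f3)], 1L)  # fully protonated: cation
  f4 <- species_fractions(pka_acidic = c(4, 9), pka_basic = 6, pH = 100)
  expect_identical(ms$charge[which.max(f4)], -2L) # fully deprotonated
})

test_that("fractions normalize over 10,000 random site sets", {
  set.seed(123)
  for (i in seq_len(10000)) {
    na <- sample(0:2, 1); nb <- sample(0:2, 1)
    f <- species_fractions(runif(na, -2, 14), runif(nb, -2, 14),
                           pH = runif(1, -2, 16))
    expect_true(abs(sum(f) - 1) < 1e-9)
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("log_d matches hand arithmetic and convexity bounds", {
  expect_equal(log_d(2.7, 1), 2.7)
  expect_equal(log_d(c(2, -2), c(0.5, 0.5)), log10(50.005), tolerance = 1e-12)
  expect_equal(log_d(c(2, -2), c(0.5, 0.5)), 1.6990, tolerance = 1e-4)
  set.seed(5)
  for (i in 1:50) {
    lp <- runif(4, -6, 8)
    fr <- runif(4); fr <- fr / sum(fr)
    d <- log_d(lp, fr)
    expect_true(d >= min(lp) - 1e-12 && d <= max(lp) + 1e-12)
    # permutation invariance
    p <- sample(4)
    expect_equal(log_d(lp[p], fr[p]), d, tolerance = 1e-12)
  }
  # all-equal species collapse exactly
  expect_identical(log_d(c(1.3, 1.3), c(0.25, 0.75)), 1.3)
  expect_error(log_d(numeric(0), numeric(0)), "empty")
  expect_error(log_d(c(1, 2), c(0.7, 0.7)), "sum to 1")
})

test_that("log-space accumulation survives extreme magnitudes", {
  expect_equal(log_d(c(350, 300), c(0.5, 0.5)), 350 + log10(0.5),
               tolerance = 1e-9)
  expect_equal(log_d(c(-320, -320), c(0.5, 0.5)), -320, tolerance = 1e-9)
})

test_that("macro_logp shares the log_d kernel", {
  expect_equal(macro_logp(tautomer_mixture(1.7, 1)), 1.7)
  mix <- tautomer_mixture(c(1.29, 1.08), c(0.8, 0.2))
  expect_equal(macro_logp(mix), log10(0.8 * 10^1.29 + 0.2 * 10^1.08),
               tolerance = 1e-12)
  expect_equal(macro_logp(mix), 1.25535, tolerance = 1e-4)
  # dominance limit
  expect_equal(macro_logp(tautomer_mixture(c(3, 0), c(1 - 1e-12, 1e-12))), 3,
               tolerance = 1e-9)
  # agreement with log_d on identical inputs
  expect_identical(macro_logp(mix), log_d(c(1.29, 1.08), c(0.8, 0.2)))
})

test_that("ionization classification follows the stated rules", {
  # o-phthalic acid: acidic pKas 2.5 and 5.5 -> anion
  expect_identical(classify_ionization(c(2.5, 5.5)), "anion")
  expect_identical(classify_ionization(7), "neutral")
  # literal zwitterion rule: pKa greater than pKb
  expect_identical(classify_ionization(5, 4), "zwitterion")
  # conventional direction available as a switch
  expect_identical(classify_ionization(5, 4, convention = "chemical"), "neutral")
  expect_identical(classify_ionization(4, 9.5, convention = "chemical"),
                   "zwitterion")
  expect_identical(classify_ionization(NULL, 10), "cation")
  expect_identical(classify_ionization(NULL, NULL), "unknown")
  # both window violations with both site types
  expect_identical(classify_ionization(2, 10), "zwitterion")
})

test_that("speciation_table rows sum to 1 and behave monotonically", {
  grid <- seq(0, 14, by = 0.5)
  tab <- speciation_table(pka_acidic = 5, ph_grid = grid)
  expect_true(all(abs(rowSums(tab[, -1]) - 1) < 1e-9))
  # monoprotic acid: neutral fraction decreases with pH
  expect_true(all(diff(tab[["a1=H"]]) < 0))
  # single-point grid equals species_fractions
  one <- speciation_table(pka_acidic = 5, ph_grid = 3)
  expect_equal(as.numeric(one[1, -1]), species_fractions(5, pH = 3))
  # one acidic + one basic site: cation dominates at pH 0
  tab2 <- speciation_table(pka_acidic = 5, pka_basic = 2, ph_grid = 0)
  ms <- enumerate_microstates(1, 1)
  expect_gt(tab2[1, 1 + which(ms$charge == 1)], 0.98)
})
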
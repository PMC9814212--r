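# Network primitives, evaluation statistics, and small-scale training
# behaviour. The full oracle-recovery and augmentation benchmarks live in
# test-acceptance.R.

test_that("graph_conv_layer handles empty neighborhoods and identity params", {
  f <- 4L
  X <- matrix(rnorm(3 * f), 3, f)
  W_nbr <- matrix(rnorm(f * f), f, f)
  # edgeless graph: output independent of W_nbr
  out1 <- graph_conv_layer(X, list(integer(0), integer(0), integer(0)),
                           diag(f), W_nbr, numeric(f))
  out2 <- graph_conv_layer(X, list(integer(0), integer(0), integer(0)),
                           diag(f), W_nbr * 0, numeric(f))
  expect_equal(out1, out2)
  # identity-like params with BN bypassed: ReLU(X)
  expect_equal(out1, pmax(X, 0))
})

test_that("graph_conv_layer is permutation-equivariant on isomorphic graphs", {
  set.seed(12)
  mol <- parse_smiles("CC(=O)Nc1ccc(O)cc1")
  fe <- featurize(mol)
  W_self <- matrix(rnorm(27 * 8), 27, 8)
  W_nbr <- matrix(rnorm(27 * 8), 27, 8)
  b <- rnorm(8)
  out <- graph_conv_layer(fe$node_features, fe$neighbors, W_self, W_nbr, b)
  perm <- sample(mol$natoms)
  fp <- featurize(permute_molgraph(mol, perm))
  outp <- graph_conv_layer(fp$node_features, fp$neighbors, W_self, W_nbr, b)
  expect_equal(outp[perm, , drop = FALSE], out)
})

test_that("graph_pool takes neighborhood maxima", {
  X <- matrix(c(1, 5, 3,
                2, 1, 9), nrow = 3)
  # isolated node: identity; pooling idempotent on edgeless graphs
  nb0 <- list(integer(0), integer(0), integer(0))
  expect_equal(graph_pool(X, nb0), X)
  # complete graph: every row becomes the column max
  nbK <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  pooled <- graph_pool(X, nbK)
  expect_true(all(pooled[, 1] == 5) && all(pooled[, 2] == 9))
})

test_that("rmse matches hand arithmetic", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3) + 1, c(1, 2, 3)), 1.0)
  expect_equal(rmse(c(1, 2), c(2, 4)), sqrt(5 / 2), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:2), "mismatch")
  # symmetry and linear scaling of residuals
  set.seed(4)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(rmse(a, b), rmse(b, a))
  expect_equal(rmse(3 * a, 3 * a + 3 * (b - a)), 3 * rmse(a, b))
})

test_that("bootstrap_rmse agrees with the exhaustive two-point oracle", {
  # residual set (0, 2): the four equiprobable resamples give rmse values
  # {0, sqrt(2), sqrt(2), 2}; enumerate rather than trust the formula
  preds <- c(1, 1); labels <- c(1, 3)
  combos <- expand.grid(i = 1:2, j = 1:2)
  vals <- apply(combos, 1, function(ix)
    rmse(preds[c(ix[1], ix[2])], labels[c(ix[1], ix[2])]))
  exact_mean <- mean(vals)
  expect_equal(exact_mean, (0 + sqrt(2) + sqrt(2) + 2) / 4, tolerance = 1e-12)
  bs <- bootstrap_rmse(preds, labels, n_resamples = 1000, seed = 42)
  se_exact <- stats::sd(vals) / sqrt(1000)
  expect_lt(abs(bs$mean_rmse - exact_mean), 3 * se_exact)
  # degenerate cases
  z <- bootstrap_rmse(c(1, 2, 3), c(1, 2, 3), seed = 1)
  expect_identical(z$mean_rmse, 0)
  expect_identical(z$sdev, 0)
  cst <- bootstrap_rmse(c(2, 3, 4), c(1, 2, 3), seed = 1)
  expect_equal(cst$mean_rmse, 1)
  expect_equal(cst$sdev, 0)
})

test_that("training on constant labels converges to the constant", {
  smis <- c("CCO", "CC(C)=O", "c1ccccc1", "CCC(=O)CC", "ClCCN", "CCOC")
  rows <- data.frame(variant_smiles = rep(smis, 4), label = 2.0)
  model <- train_gcn(rows, rows, epochs = 10, batch_size = 12, lr = 0.01,
                     dropout = 0, seed = 3)
  preds <- predict_batch(model, smis)
  expect_true(all(abs(preds - 2.0) < 0.05))
})

test_that("training reduces error on learnable data and is seed-deterministic", {
  set.seed(8)
  smis <- generate_molecules(120, seed = 21)
  labels <- vapply(smis, oracle_logp, 0)
  rows <- data.frame(variant_smiles = smis, label = labels)
  m1 <- train_gcn(rows[1:100, ], rows[101:120, ], epochs = 5, lr = 0.005,
                  seed = 17)
  expect_lt(m1$history$train_rmse[5], m1$history$train_rmse[1])
  m2 <- train_gcn(rows[1:100, ], rows[101:120, ], epochs = 5, lr = 0.005,
                  seed = 17)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("predictions are bounded, dialect-invariant and order-preserving", {
  smis <- c("CCO", "OCC", "CC(C)=O", "c1ccccc1")
  rows <- data.frame(variant_smiles = smis,
                     label = c(-0.3, -0.3, 0.5, 2.1))
  model <- train_gcn(rows, rows, epochs = 3, seed = 5)
  # tanh head bound
  lo <- model$label_scale$c - model$label_scale$s
  hi <- model$label_scale$c + model$label_scale$s
  p <- predict_batch(model, c(smis, "CCCCCCCCCCCCCCCCCCCC"))
  expect_true(all(p >= lo & p <= hi))
  # identical graphs give identical predictions
  expect_identical(p[1], p[2])
  # empty input, order preservation, per-item failure markers
  expect_identical(predict_batch(model, character(0)), numeric(0))
  shuf <- c(3, 1, 4, 2)
  expect_equal(predict_batch(model, smis[shuf]), p[shuf], tolerance = 1e-12)
  mixed <- predict_batch(model, c("CCO", "definitely(((bad", "c1ccccc1"))
  expect_true(is.na(mixed[2]) && !anyNA(mixed[c(1, 3)]))
  # batch and one-by-one agree
  solo <- vapply(smis, function(s) predict_batch(model, s), 0)
  expect_equal(unname(solo), p[1:4], tolerance = 1e-6)
})

test_that("models round-trip through the JSON archive", {
  rows <- data.frame(variant_smiles = c("CCO", "CC(C)=O", "c1ccccc1"),
                     label = c(-0.3, 0.5, 2.1))
  model <- train_gcn(rows, rows, epochs = 2, seed = 9)
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(predict_batch(back, rows$variant_smiles),
               predict_batch(model, rows$variant_smiles), tolerance = 1e-12)
  expect_identical(back$layout, model$layout)
})
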
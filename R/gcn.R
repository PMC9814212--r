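# Graph-convolutional regression network, implemented directly on matrices
# (Matrix-package sparse adjacency for neighbor sums; manual backprop; Adam).
#
# Architecture: conv(27->64) -> BN -> ReLU -> max-pool -> conv(64->128) ->
# BN -> ReLU -> max-pool -> per-molecule atom sum -> dense(128, ReLU) -> BN ->
# dropout(0.1, training only) -> scalar head y = c + s * tanh(z), where
# (c, s) re-scale the tanh range to the training-label range (midrange,
# 1.05 * half-range). Loss is mean squared error.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9

# ---------------------------------------------------------------------------
# batch assembly

.featurize_cache <- function(smiles_vec) {
  cache <- new.env(hash = TRUE, size = length(smiles_vec))
  for (s in unique(smiles_vec)) {
    f <- tryCatch(featurize(s), error = function(e) NULL)
    assign(s, f, envir = cache)
  }
  cache
}

.assemble_batch <- function(feats) {
  # feats: list of graph_features
  natoms <- vapply(feats, function(f) nrow(f$node_features), 0L)
  N <- sum(natoms)
  offs <- cumsum(c(0L, natoms[-length(natoms)]))
  X <- do.call(rbind, lapply(feats, function(f) f$node_features))
  seg <- rep(seq_along(feats), natoms)
  ii <- integer(0); jj <- integer(0)
  nb_all <- vector("list", N)
  pos <- 0L
  for (g in seq_along(feats)) {
    nb <- feats[[g]]$neighbors
    for (a in seq_along(nb)) {
      pos <- pos + 1L
      if (length(nb[[a]])) {
        nb_all[[pos]] <- nb[[a]] + offs[g]
        ii <- c(ii, rep(pos, length(nb[[a]])))
        jj <- c(jj, nb[[a]] + offs[g])
      }
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(N, N))
  maxdeg <- max(1L, max(vapply(nb_all, length, 0L)))
  NB <- matrix(0L, nrow = N, ncol = maxdeg)
  for (a in seq_len(N)) {
    d <- length(nb_all[[a]])
    if (d) NB[a, seq_len(d)] <- nb_all[[a]]
  }
  list(X = X, A = A, NB = NB, seg = seg, n_mol = length(feats))
}

# ---------------------------------------------------------------------------
# layer forward/backward primitives

.bn_forward <- function(Z, gamma, beta, training, rm, rv) {
  if (training && nrow(Z) > 1L) {
    mu <- colMeans(Z)
    va <- colMeans(Z^2) - mu^2
  } else {
    mu <- rm; va <- rv
  }
  xhat <- sweep(sweep(Z, 2L, mu, "-"), 2L, sqrt(va + .BN_EPS), "/")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out, xhat = xhat, mu = mu, va = va)
}

.bn_backward <- function(dout, cache, gamma) {
  xhat <- cache$xhat
  inv_sd <- 1 / sqrt(cache$va + .BN_EPS)
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  m <- nrow(dout)
  dx <- sweep(dout, 2L, gamma * inv_sd, "*") -
    sweep(matrix(1, m, 1) %*% rbind(colMeans(dout)), 2L, gamma * inv_sd, "*") -
    xhat * (matrix(1, m, 1) %*% rbind(colMeans(dout * xhat) * gamma * inv_sd))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.maxpool_forward <- function(H, NB) {
  P <- H
  Wn <- matrix(0L, nrow(H), ncol(H))
  if (ncol(NB)) {
    Hpad <- rbind(H, matrix(-Inf, 1L, ncol(H)))
    padrow <- nrow(H) + 1L
    for (k in seq_len(ncol(NB))) {
      idx <- NB[, k]
      idx[idx == 0L] <- padrow
      Hk <- Hpad[idx, , drop = FALSE]
      upd <- Hk > P
      P[upd] <- Hk[upd]
      Wn[upd] <- k
    }
  }
  list(P = P, winner = Wn)
}

.scatter_add <- function(target, idx, values) {
  if (!length(idx)) return(target)
  ru <- rowsum(values, group = idx, reorder = TRUE)
  rows <- as.integer(rownames(ru))
  target[rows, ] <- target[rows, , drop = FALSE] + ru
  target
}

.maxpool_backward <- function(dP, NB, winner) {
  dH <- dP * (winner == 0L)
  if (ncol(NB)) {
    for (k in seq_len(ncol(NB))) {
      mask <- winner == k
      if (!any(mask)) next
      G <- dP * mask
      sel <- NB[, k] > 0L & rowSums(mask) > 0L
      # aggregate gradient rows onto their source atoms
      srcs <- NB[sel, k]
      dH <- .scatter_add(dH, srcs, G[sel, , drop = FALSE])
    }
  }
  dH
}

# ---------------------------------------------------------------------------
# parameter initialization & Adam

.glorot <- function(nin, nout) {
  matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
}

.init_params <- function(n_in = .N_FEATURES, w1 = 64L, w2 = 128L, wd = 128L) {
  list(
    W1s = .glorot(n_in, w1), W1n = .glorot(n_in, w1), b1 = numeric(w1),
    g1 = rep(1, w1), be1 = numeric(w1), rm1 = numeric(w1), rv1 = rep(1, w1),
    W2s = .glorot(w1, w2), W2n = .glorot(w1, w2), b2 = numeric(w2),
    g2 = rep(1, w2), be2 = numeric(w2), rm2 = numeric(w2), rv2 = rep(1, w2),
    Wd = .glorot(w2, wd), bd = numeric(wd),
    gd = rep(1, wd), bed = numeric(wd), rmd = numeric(wd), rvd = rep(1, wd),
    wo = .glorot(wd, 1L), bo = 0)
}

.TRAINABLE <- c("W1s", "W1n", "b1", "g1", "be1", "W2s", "W2n", "b2", "g2",
                "be2", "Wd", "bd", "gd", "bed", "wo", "bo")

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in .TRAINABLE) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---------------------------------------------------------------------------
# forward pass (optionally retaining caches for backprop)

.forward_batch <- function(batch, params, label_scale, training = FALSE,
                           dropout = 0.1, keep_cache = FALSE) {
  X <- batch$X; A <- batch$A; NB <- batch$NB; seg <- batch$seg
  Z1 <- X %*% params$W1s + as.matrix(A %*% (X %*% params$W1n))
  Z1 <- sweep(Z1, 2L, params$b1, "+")
  bn1 <- .bn_forward(Z1, params$g1, params$be1, training, params$rm1, params$rv1)
  H1 <- pmax(bn1$out, 0)
  mp1 <- .maxpool_forward(H1, NB)
  Z2 <- mp1$P %*% params$W2s + as.matrix(A %*% (mp1$P %*% params$W2n))
  Z2 <- sweep(Z2, 2L, params$b2, "+")
  bn2 <- .bn_forward(Z2, params$g2, params$be2, training, params$rm2, params$rv2)
  H2 <- pmax(bn2$out, 0)
  mp2 <- .maxpool_forward(H2, NB)
  S <- rowsum(mp2$P, group = seg, reorder = TRUE)
  Zd <- sweep(S %*% params$Wd, 2L, params$bd, "+")
  bnd <- .bn_forward(Zd, params$gd, params$bed, training, params$rmd, params$rvd)
  Dr <- pmax(bnd$out, 0)
  if (training && dropout > 0) {
    mask <- (matrix(stats::runif(length(Dr)), nrow(Dr)) >= dropout) / (1 - dropout)
    Dd <- Dr * mask
  } else {
    mask <- NULL
    Dd <- Dr
  }
  z <- as.numeric(Dd %*% params$wo) + params$bo
  th <- tanh(z)
  y <- label_scale$c + label_scale$s * th
  res <- list(y = y)
  if (keep_cache)
    res$cache <- list(X = X, A = A, NB = NB, seg = seg, Z1 = Z1, bn1 = bn1,
                      H1 = H1, mp1 = mp1, bn2 = bn2, H2 = H2, mp2 = mp2,
                      S = S, bnd = bnd, Dr = Dr, mask = mask, Dd = Dd,
                      z = z, th = th)
  res
}

.backward_batch <- function(fw, params, label_scale, labels) {
  cc <- fw$cache
  B <- length(labels)
  grads <- list()
  dy <- 2 * (fw$y - labels) / B
  dz <- dy * label_scale$s * (1 - cc$th^2)
  grads$wo <- crossprod(cc$Dd, dz)
  grads$bo <- sum(dz)
  dDd <- dz %*% t(params$wo)
  dDr <- if (is.null(cc$mask)) dDd else dDd * cc$mask
  dbnd_out <- dDr * (cc$bnd$out > 0)
  bnd_b <- .bn_backward(dbnd_out, cc$bnd, params$gd)
  grads$gd <- bnd_b$dgamma; grads$bed <- bnd_b$dbeta
  dZd <- bnd_b$dx
  grads$Wd <- crossprod(cc$S, dZd)
  grads$bd <- colSums(dZd)
  dS <- dZd %*% t(params$Wd)
  dP2 <- dS[cc$seg, , drop = FALSE]
  dH2 <- .maxpool_backward(dP2, cc$NB, cc$mp2$winner)
  dbn2_out <- dH2 * (cc$bn2$out > 0)
  bn2_b <- .bn_backward(dbn2_out, cc$bn2, params$g2)
  grads$g2 <- bn2_b$dgamma; grads$be2 <- bn2_b$dbeta
  dZ2 <- bn2_b$dx
  grads$W2s <- crossprod(cc$mp1$P, dZ2)
  AtdZ2 <- as.matrix(Matrix::crossprod(cc$A, dZ2))
  grads$W2n <- crossprod(cc$mp1$P, AtdZ2)
  grads$b2 <- colSums(dZ2)
  dP1 <- dZ2 %*% t(params$W2s) + AtdZ2 %*% t(params$W2n)
  dH1 <- .maxpool_backward(dP1, cc$NB, cc$mp1$winner)
  dbn1_out <- dH1 * (cc$bn1$out > 0)
  bn1_b <- .bn_backward(dbn1_out, cc$bn1, params$g1)
  grads$g1 <- bn1_b$dgamma; grads$be1 <- bn1_b$dbeta
  dZ1 <- bn1_b$dx
  grads$W1s <- crossprod(cc$X, dZ1)
  AtdZ1 <- as.matrix(Matrix::crossprod(cc$A, dZ1))
  grads$W1n <- crossprod(cc$X, AtdZ1)
  grads$b1 <- colSums(dZ1)
  grads
}

.update_running <- function(params, fw) {
  cc <- fw$cache
  for (pair in list(c("rm1", "bn1"), c("rm2", "bn2"), c("rmd", "bnd"))) {
    rm_nm <- pair[1L]; bn <- cc[[pair[2L]]]
    rv_nm <- sub("rm", "rv", rm_nm)
    params[[rm_nm]] <- .BN_MOMENTUM * params[[rm_nm]] + (1 - .BN_MOMENTUM) * bn$mu
    params[[rv_nm]] <- .BN_MOMENTUM * params[[rv_nm]] + (1 - .BN_MOMENTUM) * bn$va
  }
  params
}

# ---------------------------------------------------------------------------
# public API

#' Graph convolution layer (single application)
#'
#' \code{h'_v = ReLU(BN(W_self h_v + sum_u W_nbr h_u + b))}. Exposed mainly
#' for testing; training uses the fused batch path. BN can be bypassed.
#'
#' @param features node feature matrix (n x f_in).
#' @param neighbors list of per-atom neighbor index vectors.
#' @param W_self,W_nbr weight matrices (f_in x f_out); \code{b} bias.
#' @param bn_bypass if TRUE skip batch normalization.
#' @param gamma,beta,mu,va BN parameters when not bypassed.
#' @return node matrix (n x f_out).
#' @export
graph_conv_layer <- function(features, neighbors, W_self, W_nbr, b,
                             bn_bypass = TRUE, gamma = NULL, beta = NULL,
                             mu = NULL, va = NULL) {
  stopifnot(ncol(features) == nrow(W_self), ncol(features) == nrow(W_nbr))
  n <- nrow(features)
  nb_sum <- matrix(0, n, ncol(W_nbr))
  for (v in seq_len(n)) {
    if (length(neighbors[[v]]))
      nb_sum[v, ] <- colSums(features[neighbors[[v]], , drop = FALSE] %*% W_nbr)
  }
  Z <- features %*% W_self + nb_sum
  Z <- sweep(Z, 2L, b, "+")
  if (!bn_bypass) {
    xhat <- sweep(sweep(Z, 2L, mu, "-"), 2L, sqrt(va + .BN_EPS), "/")
    Z <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  }
  pmax(Z, 0)
}

#' Graph max-pool layer
#'
#' \code{h'_v = elementwise max over \{v\} union N(v)}.
#'
#' @param features node matrix.
#' @param neighbors list of per-atom neighbor index vectors.
#' @return node matrix of the same shape.
#' @export
graph_pool <- function(features, neighbors) {
  out <- features
  for (v in seq_len(nrow(features))) {
    if (length(neighbors[[v]]))
      out[v, ] <- do.call(pmax, c(list(features[v, ]),
        lapply(neighbors[[v]], function(u) features[u, ])))
  }
  out
}

#' Root mean square error
#' @param preds,labels aligned numeric vectors (length >= 1).
#' @return sqrt of the mean squared residual.
#' @export
rmse <- function(preds, labels) {
  if (length(preds) != length(labels)) stop("rmse: length mismatch")
  if (!length(preds)) stop("rmse: empty input")
  sqrt(mean((preds - labels)^2))
}

#' Bootstrap mean rmse and its standard mean error
#'
#' rmse is recomputed on each of \code{n_resamples} with-replacement resamples
#' of the (prediction, label) pairs; the mean of the rmse distribution (which
#' replaces the point rmse, symmetrizing the confidence interval) and its
#' standard mean error are returned.
#'
#' @param preds,labels aligned numeric vectors (n >= 2).
#' @param n_resamples number of bootstrap datasets (default 1000).
#' @param seed integer seed.
#' @return list with \code{mean_rmse}, \code{sdev} (standard mean error),
#'   \code{point_rmse}.
#' @export
bootstrap_rmse <- function(preds, labels, n_resamples = 1000L, seed = 1L) {
  stopifnot(length(preds) == length(labels), length(preds) >= 2L)
  n <- length(preds)
  vals <- .with_seed(seed, {
    vapply(seq_len(n_resamples), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      rmse(preds[idx], labels[idx])
    }, 0)
  })
  list(mean_rmse = mean(vals), sdev = stats::sd(vals) / sqrt(n_resamples),
       point_rmse = rmse(preds, labels))
}

#' Train the graph-convolutional log P regressor
#'
#' Minimizes mean squared error with Adam; label scaling (c = midrange,
#' s = 1.05 * half-range of training labels) maps the tanh head onto the label
#' range. Per-epoch train/validation rmse are recorded and the parameters of
#' the best-validation epoch are returned. Fully deterministic given the seed
#' (initialization, batch order, dropout masks).
#'
#' @param train_rows data.frame with \code{variant_smiles} and \code{label}
#'   columns (e.g. a stacked variant table).
#' @param valid_rows like \code{train_rows}; used for model selection.
#' @param epochs number of training epochs.
#' @param batch_size molecules per batch (default 50).
#' @param lr Adam learning rate (default 0.002; the desk-scale setting --
#'   large-scale runs of this architecture family use 5e-5..1e-4).
#' @param dropout dropout rate after the dense layer (default 0.1).
#' @param seed integer seed.
#' @param verbose print per-epoch progress.
#' @return object of class \code{gcn_model}: \code{params},
#'   \code{label_scale}, \code{history} (per-epoch rmse), \code{best_epoch},
#'   \code{config}, \code{layout}.
#' @export
train_gcn <- function(train_rows, valid_rows = NULL, epochs = 30L,
                      batch_size = 50L, lr = 0.002, dropout = 0.1, seed = 1L,
                      verbose = FALSE) {
  stopifnot(nrow(train_rows) >= 1L)
  labels <- train_rows$label
  stopifnot(all(is.finite(labels)))
  lo <- min(labels); hi <- max(labels)
  label_scale <- list(c = (lo + hi) / 2,
                      s = max(1.05 * (hi - lo) / 2, 1e-3))
  cache <- .featurize_cache(c(train_rows$variant_smiles,
                              if (!is.null(valid_rows)) valid_rows$variant_smiles))
  featable <- function(smi) !is.null(get(smi, envir = cache))
  keep <- vapply(train_rows$variant_smiles, featable, TRUE)
  if (!all(keep)) {
    warning(sprintf("dropping %d unfeaturizable training rows", sum(!keep)))
    train_rows <- train_rows[keep, , drop = FALSE]
  }
  tr_feats <- lapply(train_rows$variant_smiles, function(s) get(s, envir = cache))
  tr_labels <- train_rows$label
  va_feats <- NULL; va_labels <- NULL
  if (!is.null(valid_rows) && nrow(valid_rows)) {
    vkeep <- vapply(valid_rows$variant_smiles, featable, TRUE)
    valid_rows <- valid_rows[vkeep, , drop = FALSE]
    va_feats <- lapply(valid_rows$variant_smiles, function(s) get(s, envir = cache))
    va_labels <- valid_rows$label
  }
  n <- length(tr_feats)
  .with_seed(seed, {
    params <- .init_params()
    state <- list(t = 0L,
                  m = lapply(params[.TRAINABLE], function(p) p * 0),
                  v = lapply(params[.TRAINABLE], function(p) p * 0))
    history <- data.frame(epoch = integer(0), train_rmse = numeric(0),
                          valid_rmse = numeric(0))
    best <- list(rmse = Inf, params = params, epoch = 0L)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      nb <- ceiling(n / batch_size)
      sse <- 0
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, n)]
        batch <- .assemble_batch(tr_feats[idx])
        fw <- .forward_batch(batch, params, label_scale, training = TRUE,
                             dropout = dropout, keep_cache = TRUE)
        if (any(!is.finite(fw$y)))
          stop("non-finite predictions during training; aborting")
        sse <- sse + sum((fw$y - tr_labels[idx])^2)
        grads <- .backward_batch(fw, params, label_scale, tr_labels[idx])
        params <- .update_running(params, fw)
        st <- .adam_step(params, grads, state, lr)
        params <- st$params; state <- st$state
        if (any(vapply(params[.TRAINABLE],
                       function(p) any(!is.finite(p)), TRUE)))
          stop("non-finite parameters after update; aborting")
      }
      tr_rmse <- sqrt(sse / n)
      va_rmse <- NA_real_
      if (!is.null(va_feats)) {
        vp <- .predict_feats(va_feats, params, label_scale)
        va_rmse <- rmse(vp, va_labels)
        if (va_rmse < best$rmse)
          best <- list(rmse = va_rmse, params = params, epoch = ep)
      }
      history <- rbind(history, data.frame(epoch = ep, train_rmse = tr_rmse,
                                           valid_rmse = va_rmse))
      if (verbose)
        message(sprintf("epoch %3d  train rmse %.4f  valid rmse %.4f",
                        ep, tr_rmse, va_rmse))
    }
    final <- if (is.finite(best$rmse)) best$params else params
    structure(list(params = final, label_scale = label_scale,
                   history = history,
                   best_epoch = if (is.finite(best$rmse)) best$epoch else epochs,
                   config = list(epochs = epochs, batch_size = batch_size,
                                 lr = lr, dropout = dropout, seed = seed),
                   layout = .FEATURE_LAYOUT_ID),
              class = "gcn_model")
  })
}

.predict_feats <- function(feats, params, label_scale, chunk = 256L) {
  out <- numeric(length(feats))
  i <- 1L
  while (i <= length(feats)) {
    j <- min(i + chunk - 1L, length(feats))
    batch <- .assemble_batch(feats[i:j])
    out[i:j] <- .forward_batch(batch, params, label_scale,
                               training = FALSE)$y
    i <- j + 1L
  }
  out
}

#' @export
print.gcn_model <- function(x, ...) {
  cat(sprintf("<gcn_model: %d epochs trained, best epoch %d (valid rmse %.4f), layout %s>\n",
              nrow(x$history), x$best_epoch,
              x$history$valid_rmse[x$best_epoch], x$layout))
  invisible(x)
}

#' Predict log P for a batch of molecules
#'
#' Vectorized inference (dropout inactive, running BN statistics), order
#' preserving. Unfeaturizable inputs yield NA rather than failing the batch.
#'
#' @param model a \code{gcn_model}.
#' @param molecules character vector of SMILES (or list of molgraphs).
#' @return numeric vector of predictions (NA marks per-item failures).
#' @export
predict_batch <- function(model, molecules) {
  stopifnot(inherits(model, "gcn_model"))
  if (!length(molecules)) return(numeric(0))
  feats <- lapply(molecules, function(m)
    tryCatch(featurize(m), error = function(e) NULL))
  ok <- !vapply(feats, is.null, TRUE)
  for (f in feats[ok]) {
    if (f$layout != model$layout)
      stop("featurizer layout mismatch between model and inputs")
  }
  out <- rep(NA_real_, length(molecules))
  if (any(ok))
    out[ok] <- .predict_feats(feats[ok], model$params, model$label_scale)
  out
}

#' Save / load a trained model as a versioned JSON archive
#' @param model a \code{gcn_model}.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  obj <- list(format = "logpnet-gcn-json-v1", layout = model$layout,
              label_scale = model$label_scale, config = model$config,
              best_epoch = model$best_epoch,
              params = lapply(model$params, function(p) {
                if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
                else list(dim = NULL, data = as.numeric(p))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @return \code{load_model} returns the restored \code{gcn_model}.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "logpnet-gcn-json-v1"))
    stop("unrecognized model archive format")
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  structure(list(params = params,
                 label_scale = as.list(obj$label_scale),
                 history = NULL, best_epoch = obj$best_epoch,
                 config = as.list(obj$config), layout = obj$layout),
            class = "gcn_model")
}
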
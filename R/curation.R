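# Dataset curation: outlier flags (single-model and ensemble), duplicate
# detection (identical structure, tautomer groups, salt/parent pairs), and
# error stratification by molecule size.

.new_flags <- function(parent_id, flag_kind, evidence) {
  data.frame(parent_id = as.character(parent_id),
             flag_kind = as.character(flag_kind),
             evidence = as.character(evidence),
             stringsAsFactors = FALSE)
}

#' Flag single-model outliers
#'
#' A record is flagged when the absolute difference between experimental and
#' predicted log P strictly exceeds the threshold (boundary values are not
#' flagged).
#'
#' @param experimental,predicted aligned numeric vectors.
#' @param threshold flag when |exp - pred| > threshold (default 1).
#' @param ids optional record identifiers (default positional).
#' @return data.frame of flags: \code{parent_id}, \code{flag_kind}
#'   (\code{"outlier_single"}), \code{evidence} (JSON with the residual).
#' @export
flag_outliers <- function(experimental, predicted, threshold = 1.0, ids = NULL) {
  stopifnot(length(experimental) == length(predicted))
  if (is.null(ids)) ids <- as.character(seq_along(experimental))
  resid <- experimental - predicted
  hit <- which(abs(resid) > threshold & !is.na(resid))
  if (!length(hit)) return(.new_flags(character(0), character(0), character(0)))
  ev <- vapply(hit, function(i) jsonlite::toJSON(
    list(residual = resid[i], experimental = experimental[i],
         predicted = predicted[i]), auto_unbox = TRUE, digits = NA), "")
  .new_flags(ids[hit], "outlier_single", ev)
}

#' Flag ensemble outliers
#'
#' A record is flagged when at least \code{min_tools} prediction tools each
#' disagree with the experimental value by more than \code{threshold}.
#' Missing per-tool predictions (NA) abstain for that record.
#'
#' @param experimental numeric vector of labels.
#' @param tool_predictions numeric matrix, one column per tool.
#' @param min_tools minimum number of disagreeing tools (default 4).
#' @param threshold per-tool disagreement threshold (default 1).
#' @param ids optional record identifiers.
#' @return data.frame of flags (\code{flag_kind = "outlier_ensemble"}) with the
#'   disagreement count in the evidence payload.
#' @export
ensemble_flag <- function(experimental, tool_predictions, min_tools = 4L,
                          threshold = 1.0, ids = NULL) {
  tool_predictions <- as.matrix(tool_predictions)
  stopifnot(nrow(tool_predictions) == length(experimental),
            ncol(tool_predictions) >= min_tools)
  if (is.null(ids)) ids <- as.character(seq_along(experimental))
  off <- abs(tool_predictions - experimental) > threshold
  n_off <- rowSums(off, na.rm = TRUE)
  hit <- which(n_off >= min_tools)
  if (!length(hit)) return(.new_flags(character(0), character(0), character(0)))
  ev <- vapply(hit, function(i) jsonlite::toJSON(
    list(n_disagreeing = unname(n_off[i]), n_tools = ncol(tool_predictions),
         experimental = experimental[i]), auto_unbox = TRUE, digits = NA), "")
  .new_flags(ids[hit], "outlier_ensemble", ev)
}

# union-find over record indices
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Find duplicate records arising from different structure representations
#'
#' Groups records that are (a) the identical canonical graph
#' (\code{duplicate_structure}), (b) members of the same tautomer group
#' (\code{duplicate_tautomer}), or (c) identical after salt stripping
#' (\code{duplicate_salt_pair}). Kinds may chain; the union-find closure over
#' all three relations is returned. Each group reports the spread
#' (max - min) of experimental labels; resolution is left to the caller.
#'
#' @param records list of molecule records (see \code{\link{read_dataset}}):
#'   each a list with at least \code{id}, \code{smiles}, \code{logp_exp}.
#' @return data.frame with one row per group: \code{group}, \code{kind}
#'   (comma-joined kinds observed inside the group), \code{ids},
#'   \code{spread}.
#' @export
find_duplicates <- function(records) {
  n <- length(records)
  if (n < 2L)
    return(data.frame(group = integer(0), kind = character(0),
                      ids = character(0), spread = numeric(0)))
  mols <- lapply(records, function(r) tryCatch(parse_smiles(r$smiles),
                                               error = function(e) NULL))
  ok <- !vapply(mols, is.null, TRUE)
  canon <- rep(NA_character_, n)
  canon[ok] <- vapply(mols[ok], mol_to_smiles, "")
  stripped <- rep(NA_character_, n)
  stripped[ok] <- vapply(which(ok), function(i)
    mol_to_smiles(strip_salt(mols[[i]])$mol), "")
  tauts <- vector("list", n)
  for (i in which(ok)) tauts[[i]] <- enumerate_tautomers(mols[[i]])$smiles

  parent <- seq_len(n)
  kinds <- vector("list", n)  # per-root accumulated kinds
  link <- function(i, j, kind) {
    ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
    if (ri != rj) parent[rj] <<- ri
    r <- .uf_find(parent, i)
    kinds[[r]] <<- union(c(kinds[[ri]], kinds[[rj]]), kind)
  }
  for (i in seq_len(n - 1L)) {
    if (!ok[i]) next
    for (j in (i + 1L):n) {
      if (!ok[j]) next
      if (canon[i] == canon[j]) link(i, j, "duplicate_structure")
      else if (length(intersect(tauts[[i]], tauts[[j]]))) link(i, j, "duplicate_tautomer")
      else if (stripped[i] == stripped[j]) link(i, j, "duplicate_salt_pair")
    }
  }
  roots <- vapply(seq_len(n), function(i) .uf_find(parent, i), 0L)
  groups <- split(seq_len(n), roots)
  groups <- Filter(function(g) length(g) > 1L, groups)
  if (!length(groups))
    return(data.frame(group = integer(0), kind = character(0),
                      ids = character(0), spread = numeric(0)))
  out <- lapply(seq_along(groups), function(gi) {
    g <- groups[[gi]]
    labs <- vapply(records[g], function(r)
      if (is.null(r$logp_exp)) NA_real_ else r$logp_exp, 0)
    data.frame(
      group = gi,
      kind = paste(sort(kinds[[.uf_find(parent, g[1L])]]), collapse = ","),
      ids = paste(vapply(records[g], function(r) r$id, ""), collapse = ","),
      spread = if (all(is.na(labs))) NA_real_ else
        max(labs, na.rm = TRUE) - min(labs, na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Root-mean-square error stratified by molecule size
#'
#' Bins records by heavy-atom count (NHA) and reports per-bin n and rmse.
#' Bins are half-open \code{[low, high)}; empty bins keep \code{n = 0} and an
#' NA rmse.
#'
#' @param experimental,predicted aligned numeric vectors.
#' @param molecules list of \code{molgraph}s or character vector of SMILES.
#' @param bin_edges monotone numeric vector of edges; default
#'   \code{c(0, 10, 20, 30, Inf)}.
#' @return data.frame: \code{bin}, \code{nha_low}, \code{nha_high}, \code{n},
#'   \code{rmse}.
#' @export
rmse_by_nha <- function(experimental, predicted, molecules,
                        bin_edges = c(0, 10, 20, 30, Inf)) {
  stopifnot(length(experimental) == length(predicted),
            length(molecules) == length(experimental),
            !is.unsorted(bin_edges, strictly = TRUE))
  nha <- vapply(molecules, count_nha, 0L)
  resid <- experimental - predicted
  nb <- length(bin_edges) - 1L
  out <- data.frame(
    bin = sprintf("[%g,%g)", bin_edges[-length(bin_edges)], bin_edges[-1L]),
    nha_low = bin_edges[-length(bin_edges)], nha_high = bin_edges[-1L],
    n = 0L, rmse = NA_real_)
  for (b in seq_len(nb)) {
    sel <- nha >= bin_edges[b] & nha < bin_edges[b + 1L]
    out$n[b] <- sum(sel)
    if (any(sel)) out$rmse[b] <- sqrt(mean(resid[sel]^2))
  }
  out
}
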
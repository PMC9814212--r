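# Dataset I/O, variant-table construction, group-aware splitting.
#
# CSV dialect: UTF-8, comma-separated, mandatory header, '.' decimal
# separator. Multi-valued pKa columns pack values with ';'.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.parse_num_list <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(NULL)
  v <- suppressWarnings(as.numeric(strsplit(as.character(x), ";")[[1]]))
  v <- v[is.finite(v)]
  if (!length(v)) NULL else v
}

.fmt_num_list <- function(v) {
  if (is.null(v) || !length(v)) return("")
  paste(vapply(v, function(x) as.character(x), ""), collapse = ";")
}

#' Construct a molecule record
#'
#' @param id identifier string.
#' @param smiles SMILES string (the original representation is retained).
#' @param logp_exp experimental macro log P (log10 units), or NA.
#' @param pka_acidic,pka_basic optional numeric vectors of site constants.
#' @param ion_class one of neutral/anion/cation/zwitterion/unknown; computed
#'   from the pKa values when missing.
#' @return object of class \code{molecule_record}.
#' @export
molecule_record <- function(id, smiles, logp_exp = NA_real_,
                            pka_acidic = NULL, pka_basic = NULL,
                            ion_class = NULL) {
  if (is.null(ion_class))
    ion_class <- classify_ionization(pka_acidic, pka_basic)
  structure(list(id = as.character(id), smiles = as.character(smiles),
                 logp_exp = as.numeric(logp_exp),
                 pka_acidic = pka_acidic, pka_basic = pka_basic,
                 ion_class = ion_class),
            class = "molecule_record")
}

#' Read a molecular dataset from delimited text
#'
#' One record per parseable row. Rows whose SMILES does not parse are skipped
#' with a warning and counted; a finite-label sanity window (default -5..12)
#' produces warnings only.
#'
#' @param path CSV file path.
#' @param column_map named list mapping roles to column names; defaults
#'   \code{list(id = "id", smiles = "smiles", logp = "logp_exp",
#'   pka_acidic = "pka_acidic", pka_basic = "pka_basic")}. \code{id},
#'   \code{smiles} and \code{logp} are mandatory roles (the pKa columns are
#'   used only when present in the file).
#' @return list with \code{records} (list of \code{molecule_record}),
#'   \code{n_accepted}, \code{n_rejected}, \code{rejected} (data.frame of row
#'   numbers and reasons).
#' @export
read_dataset <- function(path, column_map = list()) {
  if (!file.exists(path)) stop(sprintf("dataset file not found: %s", path))
  cm <- utils::modifyList(list(id = "id", smiles = "smiles", logp = "logp_exp",
                               pka_acidic = "pka_acidic",
                               pka_basic = "pka_basic"), column_map)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  for (role in c("id", "smiles", "logp")) {
    if (!(cm[[role]] %in% names(df)))
      stop(sprintf("mandatory column '%s' (role %s) missing in %s",
                   cm[[role]], role, path))
  }
  has_pka <- cm$pka_acidic %in% names(df)
  has_pkb <- cm$pka_basic %in% names(df)
  records <- list()
  rej_row <- integer(0); rej_reason <- character(0)
  for (r in seq_len(nrow(df))) {
    smi <- df[[cm$smiles]][r]
    err <- NULL
    if (is.na(smi) || !nzchar(trimws(smi))) err <- "empty SMILES"
    else {
      err <- tryCatch({ parse_smiles(smi); NULL },
                      error = function(e) conditionMessage(e))
    }
    if (!is.null(err)) {
      warning(sprintf("row %d rejected: %s", r, err))
      rej_row <- c(rej_row, r); rej_reason <- c(rej_reason, err)
      next
    }
    lp <- suppressWarnings(as.numeric(df[[cm$logp]][r]))
    if (is.finite(lp) && (lp < -5 || lp > 12))
      warning(sprintf("row %d: log P %.2f outside typical range -5..12", r, lp))
    records[[length(records) + 1L]] <- molecule_record(
      id = df[[cm$id]][r], smiles = smi, logp_exp = lp,
      pka_acidic = if (has_pka) .parse_num_list(df[[cm$pka_acidic]][r]) else NULL,
      pka_basic = if (has_pkb) .parse_num_list(df[[cm$pka_basic]][r]) else NULL)
  }
  list(records = records, n_accepted = length(records),
       n_rejected = length(rej_row),
       rejected = data.frame(row = rej_row, reason = rej_reason,
                             stringsAsFactors = FALSE))
}

#' Write molecule records as CSV
#'
#' Inverse of \code{\link{read_dataset}}: id, SMILES and log P fields
#' round-trip unchanged.
#'
#' @param records list of \code{molecule_record}.
#' @param path output CSV path.
#' @export
write_dataset <- function(records, path) {
  df <- data.frame(
    id = vapply(records, function(r) r$id, ""),
    smiles = vapply(records, function(r) r$smiles, ""),
    logp_exp = vapply(records, function(r)
      if (is.na(r$logp_exp)) "" else as.character(r$logp_exp), ""),
    pka_acidic = vapply(records, function(r) .fmt_num_list(r$pka_acidic), ""),
    pka_basic = vapply(records, function(r) .fmt_num_list(r$pka_basic), ""),
    ion_class = vapply(records, function(r) r$ion_class, ""),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read molecules from an SDF (V2000) file
#'
#' Minimal molfile reader: atom block elements, bond block orders (4 =
#' aromatic), \code{M  CHG} charge lines, and one named data field mapped to
#' the experimental log P.
#'
#' @param path SDF path.
#' @param logp_field name of the property block entry holding log P
#'   (default \code{"LOGP"}).
#' @return list of \code{molecule_record} (SMILES regenerated canonically).
#' @export
read_sdf <- function(path, logp_field = "LOGP") {
  if (!file.exists(path)) stop(sprintf("SDF file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  i <- 1L
  entry <- 0L
  while (i <= length(lines)) {
    if (i + 3L > length(lines)) break
    entry <- entry + 1L
    name <- trimws(lines[i])
    counts <- lines[i + 3L]
    na <- as.integer(substr(counts, 1, 3)); nb <- as.integer(substr(counts, 4, 6))
    ai <- i + 4L
    elem <- character(na); charge <- integer(na)
    for (a in seq_len(na))
      elem[a] <- trimws(substr(lines[ai + a - 1L], 32, 34))
    bi <- ai + na
    b1 <- integer(nb); b2 <- integer(nb); bo <- integer(nb); ba <- logical(nb)
    for (b in seq_len(nb)) {
      ln <- lines[bi + b - 1L]
      b1[b] <- as.integer(substr(ln, 1, 3)); b2[b] <- as.integer(substr(ln, 4, 6))
      o <- as.integer(substr(ln, 7, 9))
      if (o == 4L) { bo[b] <- 1L; ba[b] <- TRUE } else { bo[b] <- o; ba[b] <- FALSE }
    }
    j <- bi + nb
    props <- list()
    while (j <= length(lines) && !startsWith(lines[j], "$$$$")) {
      ln <- lines[j]
      if (startsWith(ln, "M  CHG")) {
        toks <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
        nch <- toks[1L]
        for (c2 in seq_len(nch))
          charge[toks[2L * c2]] <- toks[2L * c2 + 1L]
      }
      m <- regmatches(ln, regexec("^> *<(.+)>", ln))[[1]]
      if (length(m) == 2L && j < length(lines)) props[[m[2L]]] <- trimws(lines[j + 1L])
      j <- j + 1L
    }
    # aromatic-flag bonds: mark atoms aromatic for kekulization
    arom_atom <- rep(FALSE, na)
    arom_atom[unique(c(b1[ba], b2[ba]))] <- TRUE
    bonds <- data.frame(a1 = b1, a2 = b2, order = bo, arom = ba)
    deg <- tabulate(c(b1, b2), nbins = na)
    h <- rep(NA_integer_, na)
    for (a in which(arom_atom)) h[a] <- if (elem[a] == "C") max(0L, 3L - deg[a]) else 0L
    if (any(ba)) bonds <- .kekulize(elem, charge, h, arom_atom, bonds, deg)
    bs <- numeric(na)
    for (k in seq_len(nrow(bonds))) {
      bs[bonds$a1[k]] <- bs[bonds$a1[k]] + bonds$order[k]
      bs[bonds$a2[k]] <- bs[bonds$a2[k]] + bonds$order[k]
    }
    for (a in which(is.na(h))) {
      av <- .allowed_valence(elem[a], charge[a])
      fit <- av[av >= bs[a] - charge[a] * 0]
      h[a] <- if (length(fit)) as.integer(min(fit) - bs[a]) else 0L
    }
    mol <- .perceive_aromaticity(
      .new_molgraph(elem, charge, h, arom_atom, bonds))
    lp <- if (!is.null(props[[logp_field]]))
      suppressWarnings(as.numeric(props[[logp_field]])) else NA_real_
    recs[[length(recs) + 1L]] <- molecule_record(
      id = if (nzchar(name)) name else sprintf("sdf_%d", entry),
      smiles = mol_to_smiles(mol), logp_exp = lp)
    while (j <= length(lines) && !startsWith(lines[j], "$$$$")) j <- j + 1L
    i <- j + 1L
  }
  recs
}

#' Build the augmented variant table for one record
#'
#' Emits one row per distinct canonical graph among the requested
#' representations: the original SMILES, its canonical form, the explicit-H
#' dialect, and every enumerated tautomer. Rows whose canonical graphs
#' coincide are merged, keeping the first-seen kind in the fixed order
#' original, canonical, explicit_h, tautomer. Every row carries the parent's
#' macro log P label.
#'
#' @param record a \code{molecule_record}.
#' @param tautomers optional pre-computed \code{tautomer_set} for the record
#'   (enumerated on demand when NULL).
#' @param include character vector of representation kinds to include.
#' @return data.frame: \code{parent_id}, \code{variant_smiles},
#'   \code{variant_kind}, \code{label}.
#' @export
build_variant_table <- function(record, tautomers = NULL,
                                include = c("original", "canonical",
                                            "explicit_h", "tautomer")) {
  mol <- parse_smiles(record$smiles)
  canon <- mol_to_smiles(mol)
  cand_smiles <- character(0); cand_kind <- character(0); cand_canon <- character(0)
  add <- function(s, kind, cs) {
    cand_smiles[length(cand_smiles) + 1L] <<- s
    cand_kind[length(cand_kind) + 1L] <<- kind
    cand_canon[length(cand_canon) + 1L] <<- cs
  }
  if ("original" %in% include) add(record$smiles, "original", canon)
  if ("canonical" %in% include) add(canon, "canonical", canon)
  if ("explicit_h" %in% include)
    add(mol_to_smiles(mol, explicit_h = TRUE), "explicit_h", canon)
  if ("tautomer" %in% include) {
    if (is.null(tautomers)) tautomers <- enumerate_tautomers(mol)
    for (s in tautomers$smiles) add(s, "tautomer", s)
  }
  keep <- !duplicated(cand_canon)
  data.frame(parent_id = record$id,
             variant_smiles = cand_smiles[keep],
             variant_kind = cand_kind[keep],
             label = record$logp_exp,
             stringsAsFactors = FALSE)
}

#' Group-aware random train/validation/test split
#'
#' The test fraction is drawn first (round-half-up on the count), the
#' remainder is split into train and validation by the same rounding.
#' Augmentation variants always inherit the parent's partition, so no
#' structure leaks across partitions.
#'
#' @param records list of \code{molecule_record} (n >= 3), or a character
#'   vector of parent ids.
#' @param test_frac fraction for the test partition (default 0.10).
#' @param valid_frac_of_rest validation fraction of the non-test remainder
#'   (default 0.20).
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return data.frame \code{parent_id}, \code{partition} (train/valid/test).
#' @export
split_dataset <- function(records, test_frac = 0.10, valid_frac_of_rest = 0.20,
                          seed = 1L) {
  ids <- if (is.character(records)) records
         else vapply(records, function(r) r$id, "")
  n <- length(ids)
  if (n < 3L) stop("need at least 3 records to split")
  if (anyDuplicated(ids)) stop("parent ids must be unique")
  if (test_frac <= 0 || test_frac >= 1 || valid_frac_of_rest <= 0 ||
      valid_frac_of_rest >= 1)
    stop("fractions must lie strictly inside (0, 1)")
  n_test <- as.integer(floor(n * test_frac + 0.5))
  n_rest <- n - n_test
  n_valid <- as.integer(floor(n_rest * valid_frac_of_rest + 0.5))
  n_train <- n_rest - n_valid
  perm <- .with_seed(seed, sample.int(n))
  part <- character(n)
  part[perm[seq_len(n_test)]] <- "test"
  part[perm[n_test + seq_len(n_valid)]] <- "valid"
  part[perm[n_test + n_valid + seq_len(n_train)]] <- "train"
  data.frame(parent_id = ids, partition = part, stringsAsFactors = FALSE)
}
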
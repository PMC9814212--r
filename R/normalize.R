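# Structure normalization (hypervalent nitrogen rewrites) and salt stripping.

#' Rewrite hypervalent nitrogen depictions to charge-separated form
#'
#' Pentavalent depictions of nitro groups (\code{CN(=O)=O}), N-oxides and
#' azides -- "dative bond" forms that some sources emit -- are rewritten to the
#' standard charge-separated form (\code{C[N+](=O)[O-]}). All other atoms are
#' untouched; the function is idempotent.
#'
#' @param mol a \code{molgraph} (or SMILES string, which is parsed first).
#' @return a valence-legal \code{molgraph}.
#' @export
normalize_structure <- function(mol) {
  if (!inherits(mol, "molgraph")) mol <- parse_smiles(mol)
  repeat {
    bs <- .bondsum(mol)
    deg <- tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = mol$natoms)
    over <- which(mol$elem == "N" & mol$charge == 0L & (bs + mol$h) > 3L)
    if (!length(over)) break
    fixed_one <- FALSE
    for (i in over) {
      ks <- which((mol$bonds$a1 == i | mol$bonds$a2 == i) & mol$bonds$order >= 2L)
      if (!length(ks)) next
      partner <- ifelse(mol$bonds$a1[ks] == i, mol$bonds$a2[ks], mol$bonds$a1[ks])
      term <- deg[partner] == 1L & mol$charge[partner] == 0L
      cand <- ks[term & mol$elem[partner] == "O"]
      if (!length(cand)) cand <- ks[term & mol$elem[partner] == "N"]
      if (!length(cand)) next
      # deterministic pick: highest bond order, then highest partner index
      p2 <- ifelse(mol$bonds$a1[cand] == i, mol$bonds$a2[cand], mol$bonds$a1[cand])
      sel <- cand[order(-mol$bonds$order[cand], -p2)][1L]
      psel <- if (mol$bonds$a1[sel] == i) mol$bonds$a2[sel] else mol$bonds$a1[sel]
      mol$bonds$order[sel] <- mol$bonds$order[sel] - 1L
      mol$charge[i] <- mol$charge[i] + 1L
      mol$charge[psel] <- mol$charge[psel] - 1L
      fixed_one <- TRUE
      break
    }
    if (!fixed_one)
      stop("normalize_structure: unfixable valence violation at a nitrogen atom")
  }
  .check_valence(mol, "normalized structure")
  .perceive_aromaticity(mol)
}

# counterion whitelist: canonical SMILES of fragments treated as counterions
.COUNTERION_SMILES <- c(
  "[Li+]", "[Na+]", "[K+]", "[Rb+]", "[Cs+]", "[Ca+2]", "[Mg+2]", "[Ba+2]",
  "[Sr+2]", "[Zn+2]", "[F-]", "[Cl-]", "[Br-]", "[I-]", "[NH4+]", "[OH-]",
  "O", "[O-]S([O-])(=O)=O", "[O-]S(O)(=O)=O", "[O-][N+]([O-])=O", "[O-]Cl(=O)(=O)=O",
  "[O-]C(O)=O", "[O-]C([O-])=O", "[O-]P(O)(O)=O", "[O-]P([O-])(O)=O",
  "[O-]P([O-])([O-])=O"
)

.is_counterion <- function(frag_canon, frag) {
  if (frag_canon %in% .COUNTERION_SMILES) return(TRUE)
  # single atoms that are not organic-subset elements (metals) count as well
  if (frag$natoms == 1L && !(frag$elem[1L] %in% c("C"))) {
    if (frag$charge[1L] != 0L) return(TRUE)
  }
  FALSE
}

.neutralize_fragment <- function(mol, target_delta) {
  # shift the fragment's net charge by target_delta via (de)protonation of
  # O/S/N centers; returns the molecule (possibly partially neutralized)
  while (target_delta > 0L) { # need charge increase: protonate anions
    i <- which(mol$charge == -1L & mol$elem %in% c("O", "S", "N"))
    if (!length(i)) break
    i <- i[1L]
    mol$charge[i] <- 0L
    mol$h[i] <- mol$h[i] + 1L
    target_delta <- target_delta - 1L
  }
  while (target_delta < 0L) { # need charge decrease: deprotonate cations
    i <- which(mol$charge == 1L & mol$elem == "N" & mol$h > 0L)
    if (!length(i)) break
    i <- i[1L]
    mol$charge[i] <- 0L
    mol$h[i] <- mol$h[i] - 1L
    target_delta <- target_delta + 1L
  }
  mol
}

#' Strip counterions from a multi-fragment molecule
#'
#' Returns the largest organic fragment; whitelisted counterions (alkali and
#' alkaline-earth cations, halides, ammonium, common small inorganics) are
#' listed separately. When the removed counterions balanced the parent's
#' charge, the parent is neutralized by (de)protonation. Two organic fragments
#' of equal heavy-atom count are returned together with an ambiguity flag.
#'
#' @param mol a \code{molgraph} or SMILES string.
#' @return list with elements \code{mol} (the stripped parent),
#'   \code{counterions} (character vector of canonical SMILES) and
#'   \code{ambiguous} (logical).
#' @export
strip_salt <- function(mol) {
  if (!inherits(mol, "molgraph")) mol <- parse_smiles(mol)
  frags <- mol_fragments(mol)
  if (length(frags) == 1L)
    return(list(mol = mol, counterions = character(0), ambiguous = FALSE))
  canon <- vapply(frags, function(f) mol_to_smiles(f), "")
  is_ci <- mapply(.is_counterion, canon, frags)
  main <- frags[!is_ci]
  ions <- canon[is_ci]
  if (!length(main)) {
    # everything whitelisted (e.g. pure inorganic salt): keep the largest
    sizes <- vapply(frags, function(f) f$natoms, 0L)
    main <- frags[which.max(sizes)]
    ions <- canon[-which.max(sizes)]
  }
  sizes <- vapply(main, function(f) f$natoms, 0L)
  top <- which(sizes == max(sizes))
  ambiguous <- length(top) > 1L
  if (ambiguous) {
    # distinct structures of equal size -> genuinely ambiguous; identical
    # structures (true dimer) are also flagged but a single copy is returned
    parent <- main[[top[1L]]]
    others <- main[setdiff(seq_along(main), top[1L])]
    if (length(unique(vapply(main[top], mol_to_smiles, ""))) > 1L) {
      # keep both organic fragments: rebuild a multi-fragment molecule
      parent <- .combine_fragments(main[top])
      others <- main[setdiff(seq_along(main), top)]
    }
    ions <- c(ions, vapply(others, mol_to_smiles, ""))
  } else {
    parent <- main[[top]]
    others <- main[setdiff(seq_along(main), top)]
    ions <- c(ions, vapply(others, mol_to_smiles, ""))
  }
  ion_charge <- vapply(ions, function(s) sum(parse_smiles(s)$charge), 0)
  parent_charge <- sum(parent$charge)
  if (parent_charge != 0L && sum(ion_charge) == -parent_charge) {
    parent <- .neutralize_fragment(parent, -parent_charge)
  }
  list(mol = parent, counterions = unname(ions), ambiguous = ambiguous)
}

.combine_fragments <- function(frags) {
  elem <- character(0); charge <- integer(0); h <- integer(0); arom <- logical(0)
  b1 <- integer(0); b2 <- integer(0); bo <- integer(0); ba <- logical(0)
  off <- 0L
  for (f in frags) {
    elem <- c(elem, f$elem); charge <- c(charge, f$charge)
    h <- c(h, f$h); arom <- c(arom, f$arom)
    if (nrow(f$bonds)) {
      b1 <- c(b1, f$bonds$a1 + off); b2 <- c(b2, f$bonds$a2 + off)
      bo <- c(bo, f$bonds$order); ba <- c(ba, f$bonds$arom)
    }
    off <- off + f$natoms
  }
  .new_molgraph(elem, charge, h, arom,
                data.frame(a1 = b1, a2 = b2, order = bo, arom = ba))
}
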
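# Rule-based tautomer enumeration.
#
# Six transform rules, applied as breadth-first closure over the molecular
# graph, deduplicated by canonical SMILES:
#   1 keto_enol       C=O with alpha C-H  <->  C-OH with C=C
#   2 amide_imidic    N(H)-C=O  <->  N=C-OH   (acyclic)
#   3 lactam_lactim   ring variant of rule 2
#   4 imine_enamine   C=N with alpha C-H  <->  C(H)=C-N(H)
#   5 nitroso_oxime   o/p-nitrosophenol  <->  quinone monoxime (through-ring)
#   6 ring_nh_shift   1H/3H shifts between ring nitrogens of N-heteroaromatics
#
# Rules 1-4 act on localized (non-aromatic) bonds only; ring-disrupting shifts
# are the business of rules 5-6, which re-kekulize the ring they touch.
# Hydrogen bookkeeping is explicit, so molecular formula is conserved by
# construction; every candidate is valence-checked before acceptance.

.bond_rows_at <- function(mol, i) which(mol$bonds$a1 == i | mol$bonds$a2 == i)

.all_single_bonds <- function(mol, i) {
  ks <- .bond_rows_at(mol, i)
  !length(ks) || all(mol$bonds$order[ks] == 1L)
}

.bond_partner <- function(mol, k, i) {
  ifelse(mol$bonds$a1[k] == i, mol$bonds$a2[k], mol$bonds$a1[k])
}

.bond_between <- function(mol, a, b) {
  which((mol$bonds$a1 == a & mol$bonds$a2 == b) |
        (mol$bonds$a1 == b & mol$bonds$a2 == a))
}

.finish_candidate <- function(mol) {
  ok <- tryCatch({ .check_valence(mol); TRUE }, error = function(e) FALSE)
  if (!ok) return(NULL)
  .perceive_aromaticity(mol)
}

# assign orders on a set of ring bonds so that `needy` atoms get exactly one
# double bond within the set; all listed bonds default to single
.rematch_bonds <- function(mol, bond_idx, needy) {
  mol$bonds$order[bond_idx] <- 1L
  mol$bonds$arom[bond_idx] <- FALSE
  matched <- rep(FALSE, mol$natoms)
  chosen <- integer(0)
  needy_v <- which(needy)
  solve <- function(idx) {
    while (idx <= length(needy_v) && matched[needy_v[idx]]) idx <- idx + 1L
    if (idx > length(needy_v)) return(TRUE)
    v <- needy_v[idx]
    ks <- bond_idx[mol$bonds$a1[bond_idx] == v | mol$bonds$a2[bond_idx] == v]
    for (k in ks) {
      u <- .bond_partner(mol, k, v)
      if (!needy[u] || matched[u]) next
      matched[v] <<- TRUE; matched[u] <<- TRUE; chosen <<- c(chosen, k)
      if (solve(idx + 1L)) return(TRUE)
      matched[v] <<- FALSE; matched[u] <<- FALSE
      chosen <<- chosen[-length(chosen)]
    }
    FALSE
  }
  if (!solve(1L)) return(NULL)
  mol$bonds$order[chosen] <- 2L
  mol
}

# --- rules 1-4: localized 1,3 H shifts -------------------------------------

.shift_13 <- function(mol, het, c1, c2, direction) {
  # direction "to_enol": het=C1 double -> single, C1-C2 single -> double,
  #   H moves C2 -> het.  "to_keto": the reverse.
  kb1 <- .bond_between(mol, het, c1)
  kb2 <- .bond_between(mol, c1, c2)
  if (direction == "to_enol") {
    mol$bonds$order[kb1] <- 1L
    mol$bonds$order[kb2] <- 2L
    mol$h[het] <- mol$h[het] + 1L
    mol$h[c2] <- mol$h[c2] - 1L
  } else {
    mol$bonds$order[kb1] <- 2L
    mol$bonds$order[kb2] <- 1L
    mol$h[het] <- mol$h[het] - 1L
    mol$h[c2] <- mol$h[c2] + 1L
  }
  .finish_candidate(mol)
}

.single_c_neighbors_only <- function(mol, c1, excluding) {
  ks <- .bond_rows_at(mol, c1)
  for (k in ks) {
    p <- .bond_partner(mol, k, c1)
    if (p %in% excluding) next
    if (mol$bonds$order[k] == 1L && mol$elem[p] %in% c("N", "O", "S")) return(FALSE)
  }
  TRUE
}

.apply_keto_enol <- function(mol) {
  out <- list()
  for (k in which(mol$bonds$order == 2L & !mol$bonds$arom)) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    for (pair in list(c(a, b), c(b, a))) {
      o <- pair[1L]; c1 <- pair[2L]
      if (mol$elem[o] != "O" || mol$elem[c1] != "C") next
      if (mol$charge[o] != 0L || length(.bond_rows_at(mol, o)) != 1L) next
      if (!.single_c_neighbors_only(mol, c1, excluding = o)) next # ketone/aldehyde only
      for (k2 in .bond_rows_at(mol, c1)) {
        if (mol$bonds$order[k2] != 1L || mol$bonds$arom[k2]) next
        c2 <- .bond_partner(mol, k2, c1)
        if (mol$elem[c2] != "C" || mol$arom[c2] || mol$h[c2] < 1L) next
        if (!.all_single_bonds(mol, c2)) next
        cand <- .shift_13(mol, o, c1, c2, "to_enol")
        if (!is.null(cand)) out[[length(out) + 1L]] <- list(mol = cand, rule = "keto_enol")
      }
    }
  }
  # reverse: enol -> keto
  for (o in which(mol$elem == "O" & mol$charge == 0L & mol$h >= 1L)) {
    ks <- .bond_rows_at(mol, o)
    if (length(ks) != 1L || mol$bonds$order[ks] != 1L || mol$bonds$arom[ks]) next
    c1 <- .bond_partner(mol, ks, o)
    if (mol$elem[c1] != "C" || mol$arom[c1]) next
    if (!.single_c_neighbors_only(mol, c1, excluding = o)) next
    for (k2 in .bond_rows_at(mol, c1)) {
      if (mol$bonds$order[k2] != 2L || mol$bonds$arom[k2]) next
      c2 <- .bond_partner(mol, k2, c1)
      if (mol$elem[c2] != "C") next
      cand <- .shift_13(mol, o, c1, c2, "to_keto")
      if (!is.null(cand)) out[[length(out) + 1L]] <- list(mol = cand, rule = "keto_enol")
    }
  }
  out
}

.apply_amide_imidic <- function(mol) {
  out <- list()
  inring <- .ring_membership(mol)
  # forward: N(H)-C(=O) -> N=C-OH
  for (k in which(mol$bonds$order == 2L & !mol$bonds$arom)) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    for (pair in list(c(a, b), c(b, a))) {
      o <- pair[1L]; c1 <- pair[2L]
      if (mol$elem[o] != "O" || mol$elem[c1] != "C") next
      if (mol$charge[o] != 0L || length(.bond_rows_at(mol, o)) != 1L) next
      for (k2 in .bond_rows_at(mol, c1)) {
        if (mol$bonds$order[k2] != 1L || mol$bonds$arom[k2]) next
        nn <- .bond_partner(mol, k2, c1)
        if (mol$elem[nn] != "N" || mol$arom[nn] || mol$h[nn] < 1L ||
            mol$charge[nn] != 0L) next
        if (!.all_single_bonds(mol, nn)) next
        rule <- if (inring[c1] && inring[nn]) "lactam_lactim" else "amide_imidic"
        cand <- .shift_13(mol, o, c1, nn, "to_enol")
        if (!is.null(cand)) out[[length(out) + 1L]] <- list(mol = cand, rule = rule)
      }
    }
  }
  # reverse: N=C-OH -> N(H)-C=O
  for (o in which(mol$elem == "O" & mol$charge == 0L & mol$h >= 1L)) {
    ks <- .bond_rows_at(mol, o)
    if (length(ks) != 1L || mol$bonds$order[ks] != 1L || mol$bonds$arom[ks]) next
    c1 <- .bond_partner(mol, ks, o)
    if (mol$elem[c1] != "C" || mol$arom[c1]) next
    for (k2 in .bond_rows_at(mol, c1)) {
      if (mol$bonds$order[k2] != 2L || mol$bonds$arom[k2]) next
      nn <- .bond_partner(mol, k2, c1)
      if (mol$elem[nn] != "N" || mol$charge[nn] != 0L) next
      rule <- if (inring[c1] && inring[nn]) "lactam_lactim" else "amide_imidic"
      cand <- .shift_13(mol, o, c1, nn, "to_keto")
      if (!is.null(cand)) out[[length(out) + 1L]] <- list(mol = cand, rule = rule)
    }
  }
  out
}

.apply_imine_enamine <- function(mol) {
  out <- list()
  only_c <- function(c1, n) {
    for (k in .bond_rows_at(mol, c1)) {
      p <- .bond_partner(mol, k, c1)
      if (p != n && mol$elem[p] != "C") return(FALSE)
    }
    TRUE
  }
  # imine -> enamine: N=C1, alpha C2-H
  for (k in which(mol$bonds$order == 2L & !mol$bonds$arom)) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    for (pair in list(c(a, b), c(b, a))) {
      nn <- pair[1L]; c1 <- pair[2L]
      if (mol$elem[nn] != "N" || mol$elem[c1] != "C") next
      if (mol$charge[nn] != 0L || mol$arom[nn]) next
      if (!only_c(c1, nn)) next
      for (k2 in .bond_rows_at(mol, c1)) {
        if (mol$bonds$order[k2] != 1L || mol$bonds$arom[k2]) next
        c2 <- .bond_partner(mol, k2, c1)
        if (mol$elem[c2] != "C" || mol$arom[c2] || mol$h[c2] < 1L) next
        if (!.all_single_bonds(mol, c2)) next
        cand <- .shift_13(mol, nn, c1, c2, "to_enol")
        if (!is.null(cand)) out[[length(out) + 1L]] <- list(mol = cand, rule = "imine_enamine")
      }
    }
  }
  # enamine -> imine: N(H)-C1=C2
  for (nn in which(mol$elem == "N" & mol$charge == 0L & mol$h >= 1L & !mol$arom)) {
    for (ks in .bond_rows_at(mol, nn)) {
      if (mol$bonds$order[ks] != 1L || mol$bonds$arom[ks]) next
      c1 <- .bond_partner(mol, ks, nn)
      if (mol$elem[c1] != "C" || mol$arom[c1]) next
      if (!only_c(c1, nn)) next
      for (k2 in .bond_rows_at(mol, c1)) {
        if (mol$bonds$order[k2] != 2L || mol$bonds$arom[k2]) next
        c2 <- .bond_partner(mol, k2, c1)
        if (mol$elem[c2] != "C") next
        cand <- .shift_13(mol, nn, c1, c2, "to_keto")
        if (!is.null(cand)) out[[length(out) + 1L]] <- list(mol = cand, rule = "imine_enamine")
      }
    }
  }
  out
}

# --- rule 5: nitrosophenol <-> quinone monoxime ----------------------------

.aromatic_carbocycles6 <- function(mol) {
  adj <- .adjlist(mol)
  cys <- .find_cycles(adj, mol$natoms, maxlen = 6L)
  Filter(function(cy) length(cy) == 6L && all(mol$arom[cy]) &&
           all(mol$elem[cy] == "C"), cys)
}

.apply_nitroso_oxime <- function(mol) {
  out <- list()
  # forward: aromatic ring, C_a-OH and C_b-N=O at ortho/para
  for (cy in .aromatic_carbocycles6(mol)) {
    oh_at <- list(); no_at <- list()
    for (j in seq_along(cy)) {
      a <- cy[j]
      for (k in .bond_rows_at(mol, a)) {
        p <- .bond_partner(mol, k, a)
        if (p %in% cy || mol$bonds$order[k] != 1L) next
        if (mol$elem[p] == "O" && mol$h[p] >= 1L && mol$charge[p] == 0L &&
            length(.bond_rows_at(mol, p)) == 1L)
          oh_at[[length(oh_at) + 1L]] <- c(j, p)
        if (mol$elem[p] == "N" && mol$charge[p] == 0L) {
          kk <- .bond_rows_at(mol, p)
          if (length(kk) == 2L) {
            oo <- setdiff(.bond_partner(mol, kk, p), a)
            kno <- .bond_between(mol, p, oo)
            if (mol$elem[oo] == "O" && mol$bonds$order[kno] == 2L &&
                length(.bond_rows_at(mol, oo)) == 1L)
              no_at[[length(no_at) + 1L]] <- c(j, p, oo)
          }
        }
      }
    }
    for (oh in oh_at) for (no in no_at) {
      dj <- abs(oh[1L] - no[1L]); dj <- min(dj, 6L - dj)
      if (!(dj %in% c(1L, 3L))) next  # ortho or para only
      ca <- cy[oh[1L]]; cb <- cy[no[1L]]; op <- oh[2L]; nn <- no[2L]; on <- no[3L]
      m2 <- mol
      m2$h[op] <- m2$h[op] - 1L
      m2$bonds$order[.bond_between(m2, ca, op)] <- 2L
      m2$h[on] <- m2$h[on] + 1L
      m2$bonds$order[.bond_between(m2, nn, on)] <- 1L
      m2$bonds$order[.bond_between(m2, cb, nn)] <- 2L
      ring_bonds <- vapply(seq_along(cy), function(j)
        .bond_between(m2, cy[j], cy[if (j == 6L) 1L else j + 1L]), 0L)
      needy <- rep(FALSE, m2$natoms)
      needy[setdiff(cy, c(ca, cb))] <- TRUE
      m2 <- .rematch_bonds(m2, ring_bonds, needy)
      if (!is.null(m2)) {
        cand <- .finish_candidate(m2)
        if (!is.null(cand)) out[[length(out) + 1L]] <- list(mol = cand, rule = "nitroso_oxime")
      }
    }
  }
  # reverse: quinoid ring with exocyclic C_a=O and C_b=N-OH
  adj <- .adjlist(mol)
  for (cy in Filter(function(cy) length(cy) == 6L && all(mol$elem[cy] == "C") &&
                      !any(mol$arom[cy]), .find_cycles(adj, mol$natoms, maxlen = 6L))) {
    co <- list(); cnoh <- list()
    for (j in seq_along(cy)) {
      a <- cy[j]
      for (k in .bond_rows_at(mol, a)) {
        p <- .bond_partner(mol, k, a)
        if (p %in% cy || mol$bonds$order[k] != 2L) next
        if (mol$elem[p] == "O" && length(.bond_rows_at(mol, p)) == 1L)
          co[[length(co) + 1L]] <- c(j, p)
        if (mol$elem[p] == "N") {
          kk <- .bond_rows_at(mol, p)
          oo <- setdiff(.bond_partner(mol, kk, p), a)
          if (length(oo) == 1L && mol$elem[oo] == "O" && mol$h[oo] >= 1L &&
              mol$bonds$order[.bond_between(mol, p, oo)] == 1L)
            cnoh[[length(cnoh) + 1L]] <- c(j, p, oo)
        }
      }
    }
    for (a1 in co) for (a2 in cnoh) {
      ca <- cy[a1[1L]]; op <- a1[2L]; cb <- cy[a2[1L]]; nn <- a2[2L]; on <- a2[3L]
      m2 <- mol
      m2$h[op] <- m2$h[op] + 1L
      m2$bonds$order[.bond_between(m2, ca, op)] <- 1L
      m2$h[on] <- m2$h[on] - 1L
      m2$bonds$order[.bond_between(m2, nn, on)] <- 2L
      m2$bonds$order[.bond_between(m2, cb, nn)] <- 1L
      ring_bonds <- vapply(seq_along(cy), function(j)
        .bond_between(m2, cy[j], cy[if (j == 6L) 1L else j + 1L]), 0L)
      needy <- rep(FALSE, m2$natoms)
      needy[cy] <- TRUE
      m2 <- .rematch_bonds(m2, ring_bonds, needy)
      if (!is.null(m2)) {
        cand <- .finish_candidate(m2)
        if (!is.null(cand)) out[[length(out) + 1L]] <- list(mol = cand, rule = "nitroso_oxime")
      }
    }
  }
  out
}

# --- rule 6: 1H/3H shifts between ring nitrogens ---------------------------

.apply_ring_nh_shift <- function(mol) {
  out <- list()
  adj <- .adjlist(mol)
  cys <- .find_cycles(adj, mol$natoms, maxlen = 6L)
  cys <- Filter(function(cy) all(mol$arom[cy]), cys)
  seen_pairs <- character(0)
  for (cy in cys) {
    ns <- cy[mol$elem[cy] == "N"]
    if (length(ns) < 2L) next
    donors <- ns[mol$h[ns] >= 1L & mol$charge[ns] == 0L]
    acceptors <- ns[mol$h[ns] == 0L & mol$charge[ns] == 0L]
    for (d in donors) for (a in acceptors) {
      key <- paste(d, a)
      if (key %in% seen_pairs) next
      seen_pairs <- c(seen_pairs, key)
      m2 <- mol
      m2$h[d] <- m2$h[d] - 1L
      m2$h[a] <- m2$h[a] + 1L
      ring_bonds <- vapply(seq_along(cy), function(j)
        .bond_between(m2, cy[j], cy[if (j == length(cy)) 1L else j + 1L]), 0L)
      # atoms needing one in-ring double bond after the shift: those whose
      # fixed valence (exocyclic bonds + H) is one short
      exo <- .bondsum(m2)
      for (rb in ring_bonds) {
        exo[m2$bonds$a1[rb]] <- exo[m2$bonds$a1[rb]] - m2$bonds$order[rb]
        exo[m2$bonds$a2[rb]] <- exo[m2$bonds$a2[rb]] - m2$bonds$order[rb]
      }
      needy <- rep(FALSE, m2$natoms)
      for (v in cy) {
        base <- exo[v] + 2L + m2$h[v]  # two in-ring single bonds assumed
        val <- min(.allowed_valence(m2$elem[v], m2$charge[v]))
        needy[v] <- base < val
      }
      m2 <- .rematch_bonds(m2, ring_bonds, needy)
      if (is.null(m2)) next
      cand <- .finish_candidate(m2)
      # only keep if the ring stayed aromatic (an NH shift that de-aromatizes
      # the ring is not a 1H/3H tautomer)
      if (!is.null(cand) && all(cand$arom[cy]))
        out[[length(out) + 1L]] <- list(mol = cand, rule = "ring_nh_shift")
    }
  }
  out
}

.apply_all_rules <- function(mol) {
  c(.apply_keto_enol(mol), .apply_amide_imidic(mol), .apply_imine_enamine(mol),
    .apply_nitroso_oxime(mol), .apply_ring_nh_shift(mol))
}

#' Enumerate tautomers of a molecule
#'
#' Breadth-first closure of the six-rule tautomer transform set, deduplicated
#' by canonical SMILES, up to \code{max_depth} rule applications per member and
#' at most \code{max_members} members. Member order is the canonical-string
#' sort, so enumeration is deterministic.
#'
#' @param mol a \code{molgraph} or SMILES string (valid, normalized molecule).
#' @param max_members cap on the member count (cap hit sets \code{truncated}).
#' @param max_depth cap on chained rule applications.
#' @return an object of class \code{tautomer_set}: \code{parent} (molgraph),
#'   \code{members} (list of molgraph ordered by canonical SMILES),
#'   \code{smiles} (their canonical SMILES), \code{rule_trace} (list of rule
#'   name chains, one per member), \code{truncated} (logical).
#' @export
enumerate_tautomers <- function(mol, max_members = 32L, max_depth = 4L) {
  if (!inherits(mol, "molgraph")) mol <- parse_smiles(mol)
  parent_canon <- mol_to_smiles(mol)
  seen <- new.env(hash = TRUE)
  assign(parent_canon, list(mol = mol, trace = character(0)), envir = seen)
  frontier <- list(list(mol = mol, trace = character(0)))
  truncated <- FALSE
  depth <- 0L
  while (length(frontier) && depth < max_depth) {
    depth <- depth + 1L
    nxt <- list()
    for (node in frontier) {
      for (cand in .apply_all_rules(node$mol)) {
        cs <- mol_to_smiles(cand$mol)
        if (exists(cs, envir = seen, inherits = FALSE)) next
        if (length(ls(seen)) >= max_members) { truncated <- TRUE; next }
        rec <- list(mol = cand$mol, trace = c(node$trace, cand$rule))
        assign(cs, rec, envir = seen)
        nxt[[length(nxt) + 1L]] <- rec
      }
    }
    frontier <- nxt
  }
  if (length(frontier) && depth == max_depth) {
    # check whether anything new was still reachable
    for (node in frontier) {
      for (cand in .apply_all_rules(node$mol)) {
        if (!exists(mol_to_smiles(cand$mol), envir = seen, inherits = FALSE)) {
          truncated <- TRUE; break
        }
      }
      if (truncated) break
    }
  }
  keys <- sort(ls(seen))
  members <- lapply(keys, function(k) get(k, envir = seen)$mol)
  traces <- lapply(keys, function(k) get(k, envir = seen)$trace)
  structure(list(parent = mol, parent_smiles = parent_canon, members = members,
                 smiles = keys, rule_trace = traces, truncated = truncated),
            class = "tautomer_set")
}

#' @export
print.tautomer_set <- function(x, ...) {
  cat(sprintf("<tautomer_set: %d member(s)%s>\n", length(x$members),
              if (x$truncated) ", truncated" else ""))
  for (i in seq_along(x$smiles)) {
    cat(sprintf("  %s%s\n", x$smiles[i],
                if (length(x$rule_trace[[i]]))
                  paste0("  [", paste(x$rule_trace[[i]], collapse = " > "), "]")
                else "  [parent]"))
  }
  invisible(x)
}

#' Remove duplicate molecular representations from a SMILES list
#'
#' Keeps one entry per distinct canonical form, preserving input order of
#' first occurrences. Unparseable entries are skipped with a warning.
#'
#' @param smiles_list character vector of SMILES.
#' @return character vector (the surviving original strings).
#' @export
dedupe_variants <- function(smiles_list) {
  if (!length(smiles_list)) return(character(0))
  keep <- character(0)
  seen <- character(0)
  for (s in smiles_list) {
    cs <- tryCatch(canonical_smiles(s), error = function(e) {
      warning(sprintf("skipping unparseable SMILES '%s': %s", s, conditionMessage(e)))
      NA_character_
    })
    if (is.na(cs) || cs %in% seen) next
    seen <- c(seen, cs)
    keep <- c(keep, s)
  }
  keep
}

#' Do two molecules belong to the same tautomer group?
#'
#' True iff the enumerated tautomer sets of the two inputs intersect (so the
#' relation is symmetric and reflexive). Used by dataset curation to find
#' tautomer-duplicate entries.
#'
#' @param a,b \code{molgraph}s or SMILES strings.
#' @param max_members,max_depth enumeration caps, see
#'   \code{\link{enumerate_tautomers}}.
#' @return logical.
#' @export
same_tautomer_group <- function(a, b, max_members = 32L, max_depth = 4L) {
  ta <- enumerate_tautomers(a, max_members, max_depth)
  tb <- enumerate_tautomers(b, max_members, max_depth)
  length(intersect(ta$smiles, tb$smiles)) > 0L
}
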
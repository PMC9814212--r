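# Molecular graph engine: SMILES parsing, kekulization, aromaticity perception,
# canonical SMILES generation. Heavy-atom graphs only; hydrogens are stored as
# per-atom counts. Scope: organic subset + bracket atoms, ring closures,
# branches, charges, aromatic lowercase forms. Stereo markers are parsed and
# dropped (graphs are constitution-only).

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_ELEMS <- c("b", "c", "n", "o", "p", "s")

# Allowed valences (sum of bond orders + H count) per element/charge.
.allowed_valence <- function(elem, charge) {
  if (elem == "C") {
    if (charge == 0) return(4L)
    return(3L)
  }
  if (elem == "N") {
    if (charge == 1) return(4L)
    if (charge == -1) return(2L)
    return(c(3L, 5L))
  }
  if (elem == "O") {
    if (charge == 1) return(3L)
    if (charge == -1) return(1L)
    return(2L)
  }
  if (elem == "S") {
    if (charge == -1) return(1L)
    if (charge == 1) return(3L)
    return(c(2L, 4L, 6L))
  }
  if (elem == "P") return(c(3L, 5L))
  if (elem %in% c("F", "Cl", "Br", "I")) {
    if (charge == -1) return(0L)
    return(1L)
  }
  if (elem == "B") return(3L)
  if (elem == "H") return(1L)
  # metals / anything else: free valence (salts are single atoms in practice)
  0:8
}

.new_molgraph <- function(elem, charge, h, arom, bonds) {
  structure(list(
    elem = as.character(elem),
    charge = as.integer(charge),
    h = as.integer(h),
    arom = as.logical(arom),
    bonds = bonds, # data.frame(a1, a2, order, arom)
    natoms = length(elem)
  ), class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph: %d heavy atoms, %d bonds, formula %s>\n",
              x$natoms, nrow(x$bonds), mol_formula(x)))
  invisible(x)
}

.adjlist <- function(mol) {
  adj <- vector("list", mol$natoms)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

.bondsum <- function(mol) {
  bs <- numeric(mol$natoms)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[k]
      bs[mol$bonds$a1[k]] <- bs[mol$bonds$a1[k]] + o
      bs[mol$bonds$a2[k]] <- bs[mol$bonds$a2[k]] + o
    }
  }
  bs
}

.check_valence <- function(mol, where = "molecule") {
  bs <- .bondsum(mol)
  for (i in seq_len(mol$natoms)) {
    tot <- bs[i] + mol$h[i]
    if (!(tot %in% .allowed_valence(mol$elem[i], mol$charge[i]))) {
      stop(sprintf("valence violation in %s: atom %d (%s, charge %+d) has valence %g",
                   where, i, mol$elem[i], mol$charge[i], tot))
    }
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# SMILES tokenizer/parser

.parse_bracket <- function(tok) {
  # tok excludes the square brackets, e.g. "NH3+", "nH", "13CH4", "O-", "Ca+2"
  s <- tok
  # isotope (ignored)
  s <- sub("^[0-9]+", "", s)
  m <- regmatches(s, regexpr("^([A-Z][a-z]?|[bcnops])", s))
  if (!length(m)) stop(sprintf("cannot parse bracket atom [%s]", tok))
  sym <- m
  s <- substring(s, nchar(sym) + 1L)
  arom <- sym %in% .AROMATIC_ELEMS
  elem <- if (arom) toupper(sym) else sym
  # chirality markers (ignored)
  s <- sub("^@{1,2}(TH[12]|AL[12])?", "", s)
  h <- 0L
  if (grepl("^H", s)) {
    s <- substring(s, 2L)
    hm <- regmatches(s, regexpr("^[0-9]+", s))
    if (length(hm)) { h <- as.integer(hm); s <- substring(s, nchar(hm) + 1L) } else h <- 1L
  }
  charge <- 0L
  if (grepl("^\\+", s)) {
    plus <- regmatches(s, regexpr("^\\++", s))
    s2 <- substring(s, nchar(plus) + 1L)
    num <- regmatches(s2, regexpr("^[0-9]+", s2))
    charge <- if (length(num)) as.integer(num) else nchar(plus)
    s <- if (length(num)) substring(s2, nchar(num) + 1L) else s2
  } else if (grepl("^-", s)) {
    minus <- regmatches(s, regexpr("^-+", s))
    s2 <- substring(s, nchar(minus) + 1L)
    num <- regmatches(s2, regexpr("^[0-9]+", s2))
    charge <- -(if (length(num)) as.integer(num) else nchar(minus))
    s <- if (length(num)) substring(s2, nchar(num) + 1L) else s2
  }
  if (nzchar(s)) stop(sprintf("trailing characters in bracket atom [%s]", tok))
  list(elem = elem, arom = arom, h = h, charge = charge)
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset, bracket atoms with charges and explicit
#' hydrogen counts, branches, ring closures (including \code{\%nn}), aromatic
#' lowercase notation (kekulized on input), multi-fragment dot notation, and
#' stereo markers (parsed, then dropped). Explicit \code{[H]} atoms are folded
#' into the heavy-atom hydrogen counts.
#'
#' @param smiles a single SMILES string.
#' @return an object of class \code{molgraph}: heavy atoms (element, formal
#'   charge, hydrogen count, aromaticity flag) plus a bond table.
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  s <- trimws(smiles)
  if (!nzchar(s)) stop("empty SMILES")
  chars <- strsplit(s, "")[[1]]
  n <- 0L
  elem <- character(); arom <- logical(); charge <- integer(); hnum <- integer()
  bracket <- logical()
  b_a1 <- integer(); b_a2 <- integer(); b_ord <- integer(); b_arom <- logical()
  prev <- 0L            # previous atom index (0 = none)
  pend_ord <- NA_integer_  # pending bond order from explicit bond symbol
  pend_arom <- FALSE
  stack <- integer(0)
  ring <- list()        # ring closure id -> c(atom, order, arom)
  i <- 1L
  len <- length(chars)

  add_atom <- function(e, ar, ch, hh, br) {
    n <<- n + 1L
    elem[n] <<- e; arom[n] <<- ar; charge[n] <<- ch; hnum[n] <<- hh; bracket[n] <<- br
    if (prev > 0L) {
      ord <- pend_ord; aro <- pend_arom
      if (is.na(ord)) {
        if (arom[prev] && ar) { ord <- 1L; aro <- TRUE } else ord <- 1L
      }
      b_a1[length(b_a1) + 1L] <<- prev
      b_a2[length(b_a2) + 1L] <<- n
      b_ord[length(b_ord) + 1L] <<- ord
      b_arom[length(b_arom) + 1L] <<- aro
    }
    prev <<- n
    pend_ord <<- NA_integer_; pend_arom <<- FALSE
  }

  close_ring <- function(id) {
    key <- as.character(id)
    if (is.null(ring[[key]])) {
      ring[[key]] <<- list(atom = prev, ord = pend_ord, arom = pend_arom)
    } else {
      other <- ring[[key]]
      ord <- pend_ord; aro <- pend_arom
      if (is.na(ord)) { ord <- other$ord; aro <- aro || isTRUE(other$arom) }
      if (is.na(ord)) {
        if (arom[prev] && arom[other$atom]) { ord <- 1L; aro <- TRUE } else ord <- 1L
      }
      b_a1[length(b_a1) + 1L] <<- other$atom
      b_a2[length(b_a2) + 1L] <<- prev
      b_ord[length(b_ord) + 1L] <<- ord
      b_arom[length(b_arom) + 1L] <<- aro
      ring[[key]] <<- NULL
    }
    pend_ord <<- NA_integer_; pend_arom <<- FALSE
  }

  while (i <= len) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= len && chars[j] != "]") j <- j + 1L
      if (j > len) stop("unbalanced '[' in SMILES")
      at <- .parse_bracket(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      add_atom(at$elem, at$arom, at$charge, at$h, TRUE)
      i <- j + 1L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      two <- if (i < len) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, 0L, NA_integer_, FALSE); i <- i + 2L
      } else {
        add_atom(ch, FALSE, 0L, NA_integer_, FALSE); i <- i + 1L
      }
    } else if (ch %in% .AROMATIC_ELEMS) {
      add_atom(toupper(ch), TRUE, 0L, NA_integer_, FALSE); i <- i + 1L
    } else if (ch == "-") { pend_ord <- 1L; i <- i + 1L
    } else if (ch == "=") { pend_ord <- 2L; i <- i + 1L
    } else if (ch == "#") { pend_ord <- 3L; i <- i + 1L
    } else if (ch == ":") { pend_ord <- 1L; pend_arom <- TRUE; i <- i + 1L
    } else if (ch %in% c("/", "\\")) { pend_ord <- 1L; i <- i + 1L # stereo dropped
    } else if (ch == "(") { stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch)); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > len) stop("bad '%' ring closure")
      close_ring(as.integer(paste(chars[(i + 1L):(i + 2L)], collapse = "")))
      i <- i + 3L
    } else if (ch == ".") {
      prev <- 0L; pend_ord <- NA_integer_; pend_arom <- FALSE; i <- i + 1L
    } else {
      stop(sprintf("unexpected character '%s' in SMILES '%s'", ch, smiles))
    }
  }
  if (length(ring)) stop("unclosed ring bond in SMILES")
  if (length(stack)) stop("unbalanced '(' in SMILES")
  if (n == 0L) stop("no atoms in SMILES")

  bonds <- data.frame(a1 = b_a1, a2 = b_a2, order = b_ord, arom = b_arom)

  # fold explicit [H] atoms into neighbor H counts
  hidx <- which(elem == "H")
  if (length(hidx)) {
    if (any(charge[hidx] != 0L)) stop("charged explicit hydrogens unsupported")
    for (hi in hidx) {
      kb <- which(bonds$a1 == hi | bonds$a2 == hi)
      if (length(kb) != 1L || bonds$order[kb] != 1L)
        stop("explicit [H] must have exactly one single bond")
      nb <- if (bonds$a1[kb] == hi) bonds$a2[kb] else bonds$a1[kb]
      if (is.na(hnum[nb])) hnum[nb] <- 0L  # attachment makes H explicit
      hnum[nb] <- hnum[nb] + 1L + hnum[hi]
    }
    keep <- setdiff(seq_len(n), hidx)
    remap <- integer(n); remap[keep] <- seq_along(keep)
    bonds <- bonds[!(bonds$a1 %in% hidx | bonds$a2 %in% hidx), , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    elem <- elem[keep]; arom <- arom[keep]; charge <- charge[keep]
    hnum <- hnum[keep]; bracket <- bracket[keep]
    n <- length(keep)
    rownames(bonds) <- NULL
  }

  deg <- tabulate(c(bonds$a1, bonds$a2), nbins = n)

  # pre-kekulization implicit H for organic-subset aromatic atoms
  need_h <- which(is.na(hnum))
  for (i2 in need_h) {
    if (arom[i2]) {
      hnum[i2] <- if (elem[i2] == "C") max(0L, 3L - deg[i2]) else 0L
    }
  }

  # kekulize aromatic bonds
  if (any(bonds$arom)) {
    bonds <- .kekulize(elem, charge, hnum, arom, bonds, deg)
  }

  # implicit H for remaining organic-subset atoms from final bond orders
  bs <- numeric(n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      bs[bonds$a1[k]] <- bs[bonds$a1[k]] + bonds$order[k]
      bs[bonds$a2[k]] <- bs[bonds$a2[k]] + bonds$order[k]
    }
  }
  for (i2 in which(is.na(hnum))) {
    av <- .allowed_valence(elem[i2], 0L)
    fit <- av[av >= bs[i2]]
    hnum[i2] <- if (length(fit)) as.integer(min(fit) - bs[i2]) else 0L
  }

  mol <- .new_molgraph(elem, charge, hnum, arom, bonds)
  .check_valence(mol, sprintf("'%s'", smiles))
  .perceive_aromaticity(mol)
}

# ---------------------------------------------------------------------------
# Kekulization: assign alternating double bonds over the aromatic bond set so
# that every aromatic atom short of its valence gets exactly one double bond.

.kekulize <- function(elem, charge, hnum, arom, bonds, deg) {
  bs1 <- numeric(length(elem)) # bond sum with aromatic bonds counted as 1
  for (k in seq_len(nrow(bonds))) {
    bs1[bonds$a1[k]] <- bs1[bonds$a1[k]] + bonds$order[k]
    bs1[bonds$a2[k]] <- bs1[bonds$a2[k]] + bonds$order[k]
  }
  needy <- rep(FALSE, length(elem))
  for (i in which(arom)) {
    tot <- bs1[i] + hnum[i]
    needy[i] <- tot < min(.allowed_valence(elem[i], charge[i]))
  }
  ab <- which(bonds$arom)
  if (!length(ab)) return(bonds)
  # backtracking perfect matching on the needy atoms over aromatic bonds
  nb_of <- lapply(seq_along(elem), function(v) {
    ks <- ab[bonds$a1[ab] == v | bonds$a2[ab] == v]
    ks
  })
  matched <- rep(FALSE, length(elem))
  chosen <- logical(nrow(bonds))
  order_v <- which(needy)
  solve <- function(idx) {
    while (idx <= length(order_v) && matched[order_v[idx]]) idx <- idx + 1L
    if (idx > length(order_v)) return(TRUE)
    v <- order_v[idx]
    for (k in nb_of[[v]]) {
      u <- if (bonds$a1[k] == v) bonds$a2[k] else bonds$a1[k]
      if (!needy[u] || matched[u]) next
      matched[v] <<- TRUE; matched[u] <<- TRUE; chosen[k] <<- TRUE
      if (solve(idx + 1L)) return(TRUE)
      matched[v] <<- FALSE; matched[u] <<- FALSE; chosen[k] <<- FALSE
    }
    FALSE
  }
  if (!solve(1L)) stop("kekulization failed: no valid alternating bond assignment")
  bonds$order[chosen] <- 2L
  bonds$arom <- FALSE
  bonds
}

# ---------------------------------------------------------------------------
# Ring perception & aromaticity (Hueckel-style on simple cycles up to size 7)

.find_cycles <- function(adj, n, maxlen = 7L) {
  cycles <- list()
  path <- integer(maxlen + 1L)
  dfs <- function(start, v, depth, onpath) {
    for (u in adj[[v]]) {
      if (u == start && depth >= 3L) {
        if (path[2L] < v) cycles[[length(cycles) + 1L]] <<- path[seq_len(depth)]
      } else if (u > start && !onpath[u] && depth < maxlen) {
        path[depth + 1L] <<- u
        onpath[u] <- TRUE
        dfs(start, u, depth + 1L, onpath)
        onpath[u] <- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    if (length(adj[[s]]) < 2L) next
    path[1L] <- s
    onpath <- rep(FALSE, n)
    onpath[s] <- TRUE
    dfs(s, s, 1L, onpath)
  }
  cycles
}

.bond_index_map <- function(mol) {
  # environment mapping "a-b" (a<b) -> bond row
  e <- new.env(hash = TRUE, size = max(16L, nrow(mol$bonds)))
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
      assign(paste(min(a, b), max(a, b)), k, envir = e)
    }
  }
  e
}

.perceive_aromaticity <- function(mol) {
  n <- mol$natoms
  mol$arom <- rep(FALSE, n)
  if (nrow(mol$bonds)) mol$bonds$arom <- FALSE
  if (n < 3L || nrow(mol$bonds) < 3L) return(mol)
  adj <- .adjlist(mol)
  cycles <- .find_cycles(adj, n)
  if (!length(cycles)) return(mol)
  bmap <- .bond_index_map(mol)
  deg <- tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = n)
  in_any_ring <- rep(FALSE, n)
  for (cy in cycles) in_any_ring[cy] <- TRUE
  # multi-bond partners per atom
  hi <- which(mol$bonds$order >= 2L)
  dbl <- vector("list", n)
  for (k in hi) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    dbl[[a]] <- c(dbl[[a]], b); dbl[[b]] <- c(dbl[[b]], a)
  }
  for (cy in cycles) {
    pi_sum <- 0L
    ok <- TRUE
    for (a in cy) {
      if (deg[a] + mol$h[a] > 3L) { ok <- FALSE; break }
      partners <- dbl[[a]]
      if (length(partners) && any(partners %in% cy)) {
        pi_sum <- pi_sum + 1L
      } else if (length(partners)) {
        p <- partners[1L]
        if (mol$elem[p] %in% c("C", "N") && in_any_ring[p]) pi_sum <- pi_sum + 1L
        else { pi_sum <- pi_sum + 0L }  # exocyclic C=O etc: empty contribution
      } else if (mol$elem[a] %in% c("N", "P") &&
                 (mol$h[a] > 0L || deg[a] == 3L || mol$charge[a] < 0L)) {
        pi_sum <- pi_sum + 2L
      } else if (mol$elem[a] %in% c("O", "S")) {
        pi_sum <- pi_sum + 2L
      } else if (mol$elem[a] == "C" && mol$charge[a] == -1L) {
        pi_sum <- pi_sum + 2L
      } else { ok <- FALSE; break }
    }
    if (ok && pi_sum %% 4L == 2L) {
      mol$arom[cy] <- TRUE
      m <- length(cy)
      for (j in seq_len(m)) {
        a <- cy[j]; b <- cy[if (j == m) 1L else j + 1L]
        k <- get(paste(min(a, b), max(a, b)), envir = bmap)
        mol$bonds$arom[k] <- TRUE
      }
    }
  }
  mol
}

.ring_membership <- function(mol) {
  n <- mol$natoms
  inring <- rep(FALSE, n)
  if (nrow(mol$bonds) < 3L) return(inring)
  adj <- .adjlist(mol)
  for (cy in .find_cycles(adj, n, maxlen = 12L)) inring[cy] <- TRUE
  inring
}

# ---------------------------------------------------------------------------
# Formula, fragments

#' Molecular formula (Hill order) of a molecular graph
#' @param mol a \code{molgraph}.
#' @return a single string, e.g. \code{"C3H6O"}.
#' @export
mol_formula <- function(mol) {
  cnt <- table(mol$elem)
  htot <- sum(mol$h)
  elems <- names(cnt)
  rest <- sort(setdiff(elems, "C"))
  out <- character(0)
  fmt <- function(e, k) if (k == 1L) e else paste0(e, k)
  if ("C" %in% elems) out <- c(out, fmt("C", cnt[["C"]]))
  if (htot > 0L && "C" %in% elems) out <- c(out, fmt("H", htot))
  for (e in rest) out <- c(out, fmt(e, cnt[[e]]))
  if (!("C" %in% elems) && htot > 0L) out <- c(sort(c(out, fmt("H", htot))))
  paste(out, collapse = "")
}

.fragments <- function(mol) {
  n <- mol$natoms
  comp <- integer(n)
  adj <- .adjlist(mol)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in adj[[v]]) if (comp[u] == 0L) { comp[u] <- cid; queue <- c(queue, u) }
    }
  }
  comp
}

.subgraph <- function(mol, keep) {
  keep <- sort(keep)
  remap <- integer(mol$natoms); remap[keep] <- seq_along(keep)
  b <- mol$bonds[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep, , drop = FALSE]
  b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
  rownames(b) <- NULL
  .new_molgraph(mol$elem[keep], mol$charge[keep], mol$h[keep], mol$arom[keep], b)
}

#' Split a multi-fragment molecule into connected components
#' @param mol a \code{molgraph}.
#' @return list of \code{molgraph}, in order of first atom appearance.
#' @export
mol_fragments <- function(mol) {
  comp <- .fragments(mol)
  lapply(seq_len(max(comp)), function(ci) .subgraph(mol, which(comp == ci)))
}

# ---------------------------------------------------------------------------
# Canonical ranking (iterative refinement + deterministic tie-break)

.canon_ranks <- function(mol) {
  n <- mol$natoms
  if (n == 1L) return(1L)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    lab <- if (mol$bonds$arom[k]) 9L else mol$bonds$order[k]
    adj[[a]] <- rbind(adj[[a]], c(b, lab))
    adj[[b]] <- rbind(adj[[b]], c(a, lab))
  }
  deg <- vapply(adj, function(x) if (is.null(x)) 0L else nrow(x), 0L)
  inring <- .ring_membership(mol)
  key <- paste(mol$elem, mol$charge, mol$h, as.integer(mol$arom), deg,
               as.integer(inring))
  rank <- match(key, sort(unique(key)))
  refine <- function(rank) {
    repeat {
      nclass <- length(unique(rank))
      nk <- vapply(seq_len(n), function(v) {
        if (is.null(adj[[v]])) return(sprintf("%04d|", rank[v]))
        nb <- sprintf("%02d.%04d", adj[[v]][, 2L], rank[adj[[v]][, 1L]])
        sprintf("%04d|%s", rank[v], paste(sort(nb), collapse = ","))
      }, "")
      newrank <- match(nk, sort(unique(nk)))
      if (length(unique(newrank)) == nclass) return(newrank)
      rank <- newrank
    }
  }
  rank <- refine(rank)
  while (length(unique(rank)) < n) {
    tab <- table(rank)
    dup <- as.integer(names(tab)[tab > 1L])
    r0 <- min(dup)
    v <- min(which(rank == r0))
    rank <- rank * 2L
    rank[v] <- rank[v] - 1L
    rank <- match(rank, sort(unique(rank)))
    rank <- refine(rank)
  }
  rank
}

# ---------------------------------------------------------------------------
# SMILES writer

.default_implicit_h <- function(elem, charge, arom, bondsum_written, deg) {
  # H count a reader of an unbracketed atom would infer
  if (charge != 0L) return(NA_integer_)
  if (!(elem %in% .ORGANIC_SUBSET)) return(NA_integer_)
  if (arom) {
    if (elem == "C") return(max(0L, 3L - deg))
    return(0L)
  }
  av <- .allowed_valence(elem, 0L)
  fit <- av[av >= bondsum_written]
  if (!length(fit)) return(NA_integer_)
  as.integer(min(fit) - bondsum_written)
}

.atom_token <- function(mol, i, deg, bsum) {
  e <- mol$elem[i]
  sym <- if (mol$arom[i]) tolower(e) else e
  dflt <- .default_implicit_h(e, mol$charge[i], mol$arom[i], bsum, deg)
  if (!is.na(dflt) && dflt == mol$h[i] && mol$charge[i] == 0L) return(sym)
  hpart <- if (mol$h[i] == 0L) "" else if (mol$h[i] == 1L) "H" else paste0("H", mol$h[i])
  ch <- mol$charge[i]
  cpart <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
           else if (ch > 0L) paste0("+", ch) else paste0("-", abs(ch))
  paste0("[", sym, hpart, cpart, "]")
}

.write_fragment <- function(mol, rank, explicit_h = FALSE) {
  n <- mol$natoms
  adj <- vector("list", n)
  nb_rows <- nrow(mol$bonds)
  if (nb_rows) {
    for (k in seq_len(nb_rows)) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
      adj[[a]] <- rbind(adj[[a]], c(b, k))
      adj[[b]] <- rbind(adj[[b]], c(a, k))
    }
  }
  deg <- vapply(adj, function(x) if (is.null(x)) 0L else nrow(x), 0L)
  bsum <- .bondsum(mol)
  root <- which.min(rank)

  # pass 1: DFS in canonical neighbor order; classify tree vs ring-closure
  # bonds and assign closure digits in discovery order
  visited <- rep(FALSE, n)
  used_bond <- rep(FALSE, max(1L, nb_rows))
  children <- vector("list", n)   # ordered matrix: child, bond
  closures <- vector("list", n)   # ordered matrix: digit, bond
  digit_next <- 0L
  walk <- function(v) {
    visited[v] <<- TRUE
    nb <- adj[[v]]
    if (is.null(nb)) return(invisible())
    nb <- nb[order(rank[nb[, 1L]]), , drop = FALSE]
    for (r in seq_len(nrow(nb))) {
      u <- nb[r, 1L]; k <- nb[r, 2L]
      if (used_bond[k]) next
      if (visited[u]) {
        used_bond[k] <<- TRUE
        digit_next <<- digit_next + 1L
        closures[[u]] <<- rbind(closures[[u]], c(digit_next, k))
        closures[[v]] <<- rbind(closures[[v]], c(digit_next, k))
      } else {
        used_bond[k] <<- TRUE
        children[[v]] <<- rbind(children[[v]], c(u, k))
        walk(u)
      }
    }
  }
  walk(root)

  bond_sym <- function(k) {
    if (mol$bonds$arom[k]) return("")
    o <- mol$bonds$order[k]
    if (o == 2L) return("=")
    if (o == 3L) return("#")
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    if (mol$arom[a] && mol$arom[b]) return("-") # single bond joining aromatic atoms
    ""
  }
  atom_str <- function(i) {
    if (explicit_h) {
      e <- mol$elem[i]
      sym <- if (mol$arom[i]) tolower(e) else e
      hpart <- if (mol$h[i] == 0L) "" else if (mol$h[i] == 1L) "H"
               else paste0("H", mol$h[i])
      ch <- mol$charge[i]
      cpart <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
               else if (ch > 0L) paste0("+", ch) else paste0("-", abs(ch))
      paste0("[", sym, hpart, cpart, "]")
    } else {
      .atom_token(mol, i, deg[i], bsum[i])
    }
  }

  out <- character(0)
  emit <- function(v, incoming_bond) {
    if (!is.na(incoming_bond)) out[length(out) + 1L] <<- bond_sym(incoming_bond)
    out[length(out) + 1L] <<- atom_str(v)
    if (!is.null(closures[[v]])) {
      cl <- closures[[v]]
      cl <- cl[order(cl[, 1L]), , drop = FALSE]
      for (r in seq_len(nrow(cl))) {
        d <- cl[r, 1L]; k <- cl[r, 2L]
        out[length(out) + 1L] <<- paste0(bond_sym(k),
                                         if (d > 9L) paste0("%", sprintf("%02d", d)) else d)
      }
    }
    kids <- children[[v]]
    if (is.null(kids)) return(invisible())
    for (r in seq_len(nrow(kids))) {
      last <- r == nrow(kids)
      if (!last) out[length(out) + 1L] <<- "("
      emit(kids[r, 1L], kids[r, 2L])
      if (!last) out[length(out) + 1L] <<- ")"
    }
  }
  emit(root, NA_integer_)
  paste(out, collapse = "")
}

#' Write a molecular graph as a SMILES string
#'
#' @param mol a \code{molgraph}.
#' @param canonical use canonical atom ordering (default TRUE).
#' @param explicit_h write every atom in brackets with its full hydrogen count
#'   (the "explicit-H" SMILES dialect).
#' @return a SMILES string; multi-fragment molecules are dot-joined with
#'   fragments in sorted order when canonical.
#' @export
mol_to_smiles <- function(mol, canonical = TRUE, explicit_h = FALSE) {
  frags <- mol_fragments(mol)
  parts <- vapply(frags, function(fr) {
    rk <- if (canonical) .canon_ranks(fr) else seq_len(fr$natoms)
    .write_fragment(fr, rk, explicit_h = explicit_h)
  }, "")
  if (canonical) parts <- sort(parts)
  paste(parts, collapse = ".")
}

#' Canonical SMILES of a SMILES string or molecular graph
#'
#' Two inputs describe the same constitution (after aromaticity perception,
#' ignoring stereochemistry) if and only if their canonical SMILES agree.
#'
#' @param x a SMILES string or a \code{molgraph}.
#' @return canonical SMILES string.
#' @export
canonical_smiles <- function(x) {
  mol <- if (inherits(x, "molgraph")) x else parse_smiles(x)
  mol_to_smiles(mol, canonical = TRUE)
}

#' Number of non-hydrogen (heavy) atoms
#'
#' NHA is the molecule-size proxy used when stratifying prediction error.
#'
#' @param mol a \code{molgraph} or SMILES string.
#' @return integer heavy-atom count.
#' @export
count_nha <- function(mol) {
  if (!inherits(mol, "molgraph")) mol <- parse_smiles(mol)
  mol$natoms
}
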
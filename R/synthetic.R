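# Seeded synthetic molecule/label generator.
#
# Ground truth is an atom-additive log P oracle over a fixed, versioned
# contribution table. Tautomer-sensitive macro labels mix per-tautomer micro
# log P values (dominant form f = 0.8, remainder uniform), emulating the
# structure of experimental macro log P for tautomerizing compounds. The
# fragment grammar (alkyl chains, benzene rings, keto / amide / nitrosophenol
# motifs, halogen and polar decorations) keeps every atom classifiable by the
# oracle while exercising the full contribution table.

.ORACLE_CONTRIBUTIONS <- c(
  aliphatic_c = 0.40, aromatic_c = 0.30, hydroxyl_o = -1.00, carbonyl_o = -0.70,
  ether_o = -0.60, n = -0.90, s = 0.25, f = 0.20, cl = 0.70, br = 0.90, i = 1.10)

#' Atom-additive oracle specification
#'
#' @param contributions named per-atom-class log P increments; the default
#'   table is fixed and versioned so acceptance thresholds stay stable.
#' @param enol_hydroxyl_delta increment added to a hydroxyl oxygen sitting on
#'   a non-aromatic C=C carbon (an enol hydroxyl).
#' @param noise_sigma measurement-noise standard deviation in log units.
#' @param dominant_fraction fraction assigned to the dominant (input) tautomer;
#'   the remainder is spread uniformly over the other tautomers.
#' @return object of class \code{oracle_spec}.
#' @export
oracle_spec <- function(contributions = .ORACLE_CONTRIBUTIONS,
                        enol_hydroxyl_delta = 0.35,
                        noise_sigma = 0.1,
                        dominant_fraction = 0.8) {
  stopifnot(all(is.finite(contributions)), noise_sigma >= 0,
            dominant_fraction > 0, dominant_fraction <= 1)
  structure(list(contributions = contributions,
                 enol_hydroxyl_delta = enol_hydroxyl_delta,
                 noise_sigma = noise_sigma,
                 dominant_fraction = dominant_fraction),
            class = "oracle_spec")
}

.classify_atom <- function(mol, i) {
  e <- mol$elem[i]
  if (e == "C") return(if (mol$arom[i]) "aromatic_c" else "aliphatic_c")
  if (e == "O") {
    if (mol$h[i] >= 1L) return("hydroxyl_o")
    ks <- .bond_rows_at(mol, i)
    if (any(mol$bonds$order[ks] >= 2L)) return("carbonyl_o")
    return("ether_o")
  }
  if (e == "N") return("n")
  if (e == "S") return("s")
  if (e == "F") return("f")
  if (e == "Cl") return("cl")
  if (e == "Br") return("br")
  if (e == "I") return("i")
  stop(sprintf("oracle cannot classify element '%s'", e))
}

.is_enol_hydroxyl <- function(mol, i) {
  # hydroxyl O attached to a carbon that carries a localized C=C double bond
  if (mol$elem[i] != "O" || mol$h[i] < 1L) return(FALSE)
  ks <- .bond_rows_at(mol, i)
  if (length(ks) != 1L || mol$bonds$order[ks] != 1L) return(FALSE)
  x <- .bond_partner(mol, ks, i)
  if (mol$elem[x] != "C" || mol$arom[x]) return(FALSE)
  for (k in .bond_rows_at(mol, x)) {
    if (mol$bonds$order[k] == 2L && !mol$bonds$arom[k]) {
      p <- .bond_partner(mol, k, x)
      if (mol$elem[p] == "C") return(TRUE)
    }
  }
  FALSE
}

#' Deterministic atom-additive log P oracle
#'
#' Sum of per-atom contributions from the oracle table; a hydroxyl on an
#' enol carbon additionally receives \code{enol_hydroxyl_delta}. No noise.
#'
#' @param mol \code{molgraph} or SMILES.
#' @param spec an \code{\link{oracle_spec}}.
#' @return micro log P of this exact structure.
#' @export
oracle_logp <- function(mol, spec = oracle_spec()) {
  if (!inherits(mol, "molgraph")) mol <- parse_smiles(mol)
  total <- 0
  for (i in seq_len(mol$natoms)) {
    cls <- .classify_atom(mol, i)
    total <- total + spec$contributions[[cls]]
    if (cls == "hydroxyl_o" && .is_enol_hydroxyl(mol, i))
      total <- total + spec$enol_hydroxyl_delta
  }
  total
}

#' Macro log P oracle over the tautomer ensemble
#'
#' Enumerates tautomers, evaluates the micro oracle on each, assigns the
#' dominant fraction to the input form and spreads the remainder uniformly,
#' and mixes on the linear scale via \code{\link{macro_logp}}.
#'
#' @param mol \code{molgraph} or SMILES.
#' @param spec an \code{\link{oracle_spec}}.
#' @return list: \code{members} (canonical SMILES), \code{micro_logps},
#'   \code{fractions}, \code{macro}.
#' @export
macro_oracle <- function(mol, spec = oracle_spec()) {
  if (!inherits(mol, "molgraph")) mol <- parse_smiles(mol)
  ts <- enumerate_tautomers(mol)
  micro <- vapply(ts$members, oracle_logp, 0, spec = spec)
  k <- length(micro)
  fr <- if (k == 1L) 1 else {
    f <- rep((1 - spec$dominant_fraction) / (k - 1L), k)
    f[match(ts$parent_smiles, ts$smiles)] <- spec$dominant_fraction
    f
  }
  list(members = ts$smiles, micro_logps = micro, fractions = fr,
       macro = macro_logp(tautomer_mixture(micro, fr)))
}

.halogens <- c("F", "Cl", "Br", "I")

.assemble_molecule <- function(keto, nitroso, amide) {
  # chain lengths are trimmed/extended so 3 <= NHA <= 20 holds by
  # construction: acceptance must not depend on the motif draws, or the
  # emitted motif frequencies would drift from their stated probabilities
  l1 <- sample(1:3, 1L)
  l2 <- if (keto) l1 + sample(1:2, 1L) else 0L  # two inequivalent alpha carbons
  hal <- stats::runif(1) < 0.30
  hal_sym <- if (hal) sample(.halogens, 1L) else ""
  u_ring <- stats::runif(1)
  u_dec <- stats::runif(1)
  term <- if (nitroso) "nitroso"                 # para-nitrosophenol ring
          else if (u_ring < 0.35) "ring"         # plain benzene terminus
          else if (!amide) {
            if (u_dec < 0.20) "O"                # primary alcohol
            else if (u_dec < 0.35) "N"           # primary amine
            else if (u_dec < 0.45) "OC"          # methyl ether
            else if (u_dec < 0.52) "SC"          # thioether
            else ""
          } else ""
  term_atoms <- switch(term, nitroso = 9L, ring = 6L, O = 1L, N = 1L,
                       OC = 2L, SC = 2L, 0L)
  size <- function(a, b) as.integer(hal) + a + (if (keto) 2L + b else 0L) +
    (if (amide) 3L else 0L) + term_atoms
  while (size(l1, l2) > 20L && l2 > 2L) l2 <- l2 - 1L
  while (size(l1, l2) > 20L && l1 > 1L) l1 <- l1 - 1L
  if (size(l1, l2) < 3L) l1 <- l1 + 3L - size(l1, l2)
  parts <- c(if (hal) hal_sym, strrep("C", l1),
             if (keto) c("C(=O)", strrep("C", l2)),
             if (amide) "C(=O)N",
             switch(term, nitroso = "c1cc(N=O)ccc1O", ring = "c1ccccc1",
                    O = "O", N = "N", OC = "OC", SC = "SC", NULL))
  paste(parts, collapse = "")
}

#' Generate seeded synthetic molecules
#'
#' Valence-legal molecules of 3-20 heavy atoms assembled from a fragment
#' grammar. Motifs are drawn independently per molecule: an internal ketone
#' with two inequivalent alpha carbons (two distinct enol tautomers), a
#' primary/anilide amide, and a para-nitrosophenol ring (quinone-monoxime
#' tautomer). Deterministic given the seed.
#'
#' @param n number of molecules.
#' @param seed integer seed.
#' @param motif_probs named list/vector of motif probabilities
#'   (\code{carbonyl_alpha_h}, \code{nitrosophenol}, \code{amide}).
#' @return character vector of SMILES.
#' @export
generate_molecules <- function(n, seed = 1L,
                               motif_probs = c(carbonyl_alpha_h = 0.3,
                                               nitrosophenol = 0.05,
                                               amide = 0.15)) {
  stopifnot(n >= 0)
  if (n == 0L) return(character(0))
  .with_seed(seed, {
    out <- character(n)
    for (i in seq_len(n)) {
      keto <- stats::runif(1) < motif_probs[["carbonyl_alpha_h"]]
      nitroso <- stats::runif(1) < motif_probs[["nitrosophenol"]]
      amide <- stats::runif(1) < motif_probs[["amide"]]
      smi <- .assemble_molecule(keto, nitroso, amide)
      mol <- parse_smiles(smi)  # grammar guarantees validity and size bounds
      stopifnot(mol$natoms >= 3L, mol$natoms <= 20L)
      out[i] <- smi
    }
    out
  })
}

#' Generate a labelled synthetic dataset
#'
#' Molecules from \code{\link{generate_molecules}} with macro-oracle labels
#' plus Gaussian measurement noise, and optional synthetic pKa columns for
#' speciation/curation testing.
#'
#' @param n number of records.
#' @param seed integer seed (controls molecules, noise and pKa draws).
#' @param spec an \code{\link{oracle_spec}} (its \code{noise_sigma} is used).
#' @param pka_prob probability that a record receives one synthetic acidic and
#'   (independently) one basic site constant, each uniform on 1..11.
#' @param motif_probs forwarded to \code{\link{generate_molecules}}.
#' @return list of \code{molecule_record}.
#' @export
generate_dataset <- function(n, seed = 1L, spec = oracle_spec(),
                             pka_prob = 0.2,
                             motif_probs = c(carbonyl_alpha_h = 0.3,
                                             nitrosophenol = 0.05,
                                             amide = 0.15)) {
  smis <- generate_molecules(n, seed = seed, motif_probs = motif_probs)
  .with_seed(seed + 1000003L, {
    lapply(seq_len(n), function(i) {
      macro <- macro_oracle(smis[i], spec)$macro
      noise <- if (spec$noise_sigma > 0) stats::rnorm(1, 0, spec$noise_sigma) else 0
      pka_a <- if (stats::runif(1) < pka_prob) stats::runif(1, 1, 11) else NULL
      pka_b <- if (stats::runif(1) < pka_prob) stats::runif(1, 1, 11) else NULL
      molecule_record(id = sprintf("SYN%05d", i), smiles = smis[i],
                      logp_exp = macro + noise,
                      pka_acidic = pka_a, pka_basic = pka_b)
    })
  })
}
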
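# pH-dependent ionization arithmetic: microstate enumeration under an
# independent-site model, species fractions, log D, macro log P from tautomer
# mixtures, and the ionization-class rules used for dataset annotation.
#
# Conventions: "pKa" values describe acidic sites (HA <-> A- + H+); "pKb"
# values are the pKa of the conjugate acid of a basic site (BH+ <-> B + H+),
# the scale on which "pKb > 9" means protonated throughout the pH 3-9 window.

#' Enumerate protonation microstates
#'
#' All \code{2^(n_acidic + n_basic)} site-occupancy patterns of a molecule
#' with the given numbers of acidic and basic sites, with net charges.
#' Deterministic order: binary counting, acidic sites varying fastest.
#'
#' @param n_acidic,n_basic site counts (non-negative integers).
#' @return data.frame with columns \code{state} (string like \code{"a1=H a2=- b1=H+"}),
#'   \code{deprot_acidic}, \code{deprot_basic} (index vectors packed as
#'   comma strings), and \code{charge}.
#' @export
enumerate_microstates <- function(n_acidic, n_basic) {
  stopifnot(n_acidic >= 0, n_basic >= 0)
  na <- as.integer(n_acidic); nb <- as.integer(n_basic)
  nsite <- na + nb
  nstate <- 2L^nsite
  out <- vector("list", nstate)
  for (s in seq_len(nstate) - 1L) {
    bits <- as.integer(intToBits(s))[seq_len(max(1L, nsite))][seq_len(nsite)]
    abits <- if (na) bits[seq_len(na)] else integer(0)      # 1 = deprotonated
    bbits <- if (nb) bits[na + seq_len(nb)] else integer(0) # 1 = deprotonated
    charge <- sum(bbits == 0L) * (nb > 0) - sum(abits == 1L)
    lab <- c(if (na) paste0("a", seq_len(na), "=", ifelse(abits == 1L, "-", "H")),
             if (nb) paste0("b", seq_len(nb), "=", ifelse(bbits == 1L, "0", "H+")))
    out[[s + 1L]] <- data.frame(
      state = paste(lab, collapse = " "),
      deprot_acidic = paste(which(abits == 1L), collapse = ","),
      deprot_basic = paste(which(bbits == 1L), collapse = ","),
      charge = charge,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  if (nsite == 0L) df$state <- "neutral"
  df
}

#' Fractions of all protonation microstates at a given pH
#'
#' Independent-site model: each microstate's unnormalized weight is the
#' product over its deprotonated sites of \code{10^(pH - pKa_site)};
#' weights are normalized to sum to one. Computed in log space so extreme
#' pH values do not underflow.
#'
#' @param pka_acidic,pka_basic numeric vectors of site constants (may be
#'   empty). Basic-site values are conjugate-acid pKas.
#' @param pH a single pH value.
#' @return numeric vector of fractions, aligned with
#'   \code{enumerate_microstates(length(pka_acidic), length(pka_basic))}.
#' @export
species_fractions <- function(pka_acidic = numeric(0), pka_basic = numeric(0), pH) {
  stopifnot(is.numeric(pH), length(pH) == 1L, all(is.finite(c(pka_acidic, pka_basic))))
  ms <- enumerate_microstates(length(pka_acidic), length(pka_basic))
  pka_all <- c(pka_acidic, pka_basic)
  logw <- vapply(seq_len(nrow(ms)), function(r) {
    ia <- if (nzchar(ms$deprot_acidic[r]))
      as.integer(strsplit(ms$deprot_acidic[r], ",")[[1]]) else integer(0)
    ib <- if (nzchar(ms$deprot_basic[r]))
      as.integer(strsplit(ms$deprot_basic[r], ",")[[1]]) else integer(0)
    sum(pH - pka_acidic[ia]) + sum(pH - pka_basic[ib])
  }, 0)
  logw <- logw * log(10)
  logw <- logw - max(logw)
  w <- exp(logw)
  w / sum(w)
}

.log10_sum_weighted <- function(logp, fractions) {
  keep <- fractions > 0
  if (!any(keep)) stop("all fractions are zero")
  lp <- logp[keep]; f <- fractions[keep]
  m <- max(lp)
  m + log10(sum(f * 10^(lp - m)))
}

#' Distribution coefficient log D from per-species log P and fractions
#'
#' \code{log D = log10( sum_i 10^(logP_i) * f_i )}, accumulated in log space
#' (exact to about 1e-12 relative for |logP| <= 20, stable far beyond).
#'
#' @param logp_species numeric vector of per-species log P values.
#' @param fractions numeric vector summing to 1.
#' @return a single number.
#' @export
log_d <- function(logp_species, fractions) {
  if (!length(logp_species)) stop("log_d: empty species list")
  stopifnot(length(logp_species) == length(fractions),
            all(is.finite(logp_species)), all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("log_d: fractions must sum to 1")
  .log10_sum_weighted(logp_species, fractions)
}

#' Tautomer mixture: per-tautomer micro log P values with fractions
#' @param micro_logps numeric vector of per-tautomer (micro) log P values.
#' @param fractions non-negative fractions summing to 1.
#' @return object of class \code{tautomer_mixture}.
#' @export
tautomer_mixture <- function(micro_logps, fractions) {
  stopifnot(length(micro_logps) == length(fractions),
            all(fractions >= 0), abs(sum(fractions) - 1) < 1e-6)
  structure(list(micro_logps = micro_logps, fractions = fractions),
            class = "tautomer_mixture")
}

#' Macroscopic log P of a tautomerizing compound
#'
#' The experimentally observable (macro) log P is the fraction-weighted sum of
#' the per-tautomer partition coefficients on the linear scale:
#' \code{log10( sum_i 10^(micrologP_i) * f_i )}. Identical kernel to
#' \code{\link{log_d}}.
#'
#' @param mixture a \code{\link{tautomer_mixture}}.
#' @return a single number.
#' @export
macro_logp <- function(mixture) {
  stopifnot(inherits(mixture, "tautomer_mixture"))
  log_d(mixture$micro_logps, mixture$fractions)
}

#' Classify a molecule's ionization state from site constants
#'
#' A compound is marked \code{"zwitterion"} when it has both site types and
#' its (minimum) acidic pKa exceeds its (maximum) basic pKb -- the rule is
#' applied literally as stated in its source dataset-curation protocol,
#' although it inverts the
#' usual chemical criterion; set \code{convention = "chemical"} for the
#' conventional direction (zwitterion when pKb > pKa). Otherwise the compound
#' is a potential \code{"anion"} if its minimum acidic pKa lies below the
#' measurement window, a potential \code{"cation"} if its maximum basic pKb
#' lies above it, else \code{"neutral"}. With no pKa data at all the class is
#' \code{"unknown"}.
#'
#' @param pka_acidic,pka_basic numeric vectors (possibly empty or NULL).
#' @param window measurement pH window, default \code{c(3, 9)}.
#' @param convention \code{"literal"} (stated rule, default) or
#'   \code{"chemical"}.
#' @return one of \code{"neutral"}, \code{"anion"}, \code{"cation"},
#'   \code{"zwitterion"}, \code{"unknown"}.
#' @export
classify_ionization <- function(pka_acidic = NULL, pka_basic = NULL,
                                window = c(3, 9),
                                convention = c("literal", "chemical")) {
  convention <- match.arg(convention)
  pka_acidic <- pka_acidic[is.finite(pka_acidic)]
  pka_basic <- pka_basic[is.finite(pka_basic)]
  has_a <- length(pka_acidic) > 0L
  has_b <- length(pka_basic) > 0L
  if (!has_a && !has_b) return("unknown")
  if (has_a && has_b) {
    pa <- min(pka_acidic); pb <- max(pka_basic)
    zwit <- if (convention == "literal") pa > pb else pb > pa
    if (zwit) return("zwitterion")
    if (pa < window[1L] && pb > window[2L]) return("zwitterion")
  }
  if (has_a && min(pka_acidic) < window[1L]) return("anion")
  if (has_b && max(pka_basic) > window[2L]) return("cation")
  "neutral"
}

#' Species fractions over a pH grid
#'
#' @param pka_acidic,pka_basic site constants as in
#'   \code{\link{species_fractions}}.
#' @param ph_grid numeric vector of pH values.
#' @return data.frame: \code{pH} column plus one fraction column per
#'   microstate (named by its state label); each row sums to 1.
#' @export
speciation_table <- function(pka_acidic = numeric(0), pka_basic = numeric(0),
                             ph_grid) {
  ms <- enumerate_microstates(length(pka_acidic), length(pka_basic))
  rows <- t(vapply(ph_grid, function(p)
    species_fractions(pka_acidic, pka_basic, p), numeric(nrow(ms))))
  colnames(rows) <- ms$state
  cbind(data.frame(pH = ph_grid), as.data.frame(rows, check.names = FALSE))
}
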
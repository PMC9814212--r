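# Per-atom feature matrix + neighbor structure consumed by the network.
#
# Fixed layout, F = 27 columns:
#   1-10  element one-hot {C,N,O,S,P,F,Cl,Br,I,other}
#  11-16  heavy-atom degree one-hot 0-5 (degree > 5 clamps to 5 with warning)
#  17-21  hydrogen-count one-hot 0-4
#    22   formal charge (integer, as float)
#    23   aromatic flag
#    24   in-ring flag
#  25-27  hybridization one-hot {sp, sp2, sp3} (from bond orders/aromaticity)
# Models are not portable across layout changes; the layout id is stored in
# trained model objects and checked at predict time.

.FEATURE_LAYOUT_ID <- "logpnet-27-v1"
.FEATURE_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
.N_FEATURES <- 27L

#' Convert a molecule into the per-atom feature representation
#'
#' Hydrogens are implicit: rows correspond to heavy atoms only. The feature
#' layout is fixed (27 columns, see package vignette); one-hot blocks each sum
#' to exactly one.
#'
#' @param mol a \code{molgraph} or SMILES string (valid, normalized molecule).
#' @return object of class \code{graph_features}: \code{node_features}
#'   (n x 27 matrix), \code{neighbors} (list of integer vectors),
#'   \code{degree_histogram} (named counts per degree).
#' @export
featurize <- function(mol) {
  if (!inherits(mol, "molgraph")) mol <- parse_smiles(mol)
  n <- mol$natoms
  X <- matrix(0, nrow = n, ncol = .N_FEATURES)
  nbr <- vector("list", n)
  ords <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
      nbr[[a]] <- c(nbr[[a]], b); nbr[[b]] <- c(nbr[[b]], a)
      o <- if (mol$bonds$arom[k]) 1.5 else mol$bonds$order[k]
      ords[[a]] <- c(ords[[a]], o); ords[[b]] <- c(ords[[b]], o)
    }
  }
  inring <- .ring_membership(mol)
  for (i in seq_len(n)) {
    e <- mol$elem[i]
    ei <- match(e, .FEATURE_ELEMENTS)
    if (is.na(ei)) {
      warning(sprintf("element '%s' outside feature alphabet; using 'other'", e))
      ei <- 10L
    }
    X[i, ei] <- 1
    d <- length(nbr[[i]])
    if (d > 5L) {
      warning(sprintf("atom degree %d clamped to 5", d))
      d <- 5L
    }
    X[i, 11L + d] <- 1
    h <- min(mol$h[i], 4L)
    X[i, 17L + h] <- 1
    X[i, 22L] <- mol$charge[i]
    X[i, 23L] <- as.numeric(mol$arom[i])
    X[i, 24L] <- as.numeric(inring[i])
    # hybridization from bond orders: any triple or two doubles -> sp;
    # any double or aromatic -> sp2; else sp3
    o <- ords[[i]]
    hyb <- if (any(o == 3) || sum(o >= 2) >= 2L) 1L
           else if (any(o >= 1.5) || mol$arom[i]) 2L else 3L
    X[i, 24L + hyb] <- 1
  }
  dh <- table(factor(vapply(nbr, length, 0L), levels = 0:5))
  structure(list(node_features = X, neighbors = nbr,
                 degree_histogram = dh, layout = .FEATURE_LAYOUT_ID),
            class = "graph_features")
}

#' @export
print.graph_features <- function(x, ...) {
  cat(sprintf("<graph_features: %d atoms x %d features (%s)>\n",
              nrow(x$node_features), ncol(x$node_features), x$layout))
  invisible(x)
}
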
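# Shared fixtures and memoized expensive objects. The memo environment is
# created once per test run, so the large seeded dataset and the trained
# benchmark models are built at most once across test files.

.memo <- new.env(parent = emptyenv())

memo_get <- function(key, builder) {
  if (!exists(key, envir = .memo, inherits = FALSE))
    assign(key, builder(), envir = .memo)
  get(key, envir = .memo, inherits = FALSE)
}

# the stated oracle-recovery / tautomer-sensitivity world:
# n = 2000 parents, seed 1, noise sigma = 0.1
dataset_2000 <- function() {
  memo_get("dataset_2000", function() generate_dataset(2000L, seed = 1L))
}

# mono + taut models trained on dataset_2000 with the default gcn config,
# evaluated on original-form and random-variant test inputs
benchmark_2000 <- function() {
  memo_get("benchmark_2000", function()
    tautomer_benchmark(n = 2000L, seed = 1L, epochs = 30L))
}

# small molecule battery used across structural tests
FIXTURE_SMILES <- c(
  "CCO", "c1ccccc1", "CC(C)=O", "CN(=O)=O", "C[N+](=O)[O-]",
  "CCCCCCCC(=O)O", "O=Nc1ccc(O)cc1", "ON=C1C=CC(=O)C=C1",
  "c1ccc2ccccc2c1", "c1ccncc1", "c1cc[nH]c1", "CC(=O)Nc1ccc(O)cc1",
  "CC(=O)Oc1ccccc1C(=O)O", "N#Cc1ccccc1", "CCOC(=O)C", "CC(N)C(=O)O",
  "Clc1ccc(Br)cc1", "FC(F)(F)c1ccccc1", "CSC", "c1ccoc1", "c1ccsc1",
  "C1CCCCC1", "O=C1CCCCC1", "O=C1CCCCN1", "CC(=O)N(C)C", "Cn1ccnc1",
  "c1cnc[nH]1", "CC(=CC)C", "OC(=O)c1ccccc1C(=O)O", "NC(=O)c1ccccc1")

# tautomer pairs the rule set must connect
TAUTOMER_PAIRS <- list(
  c("CC(C)=O", "CC(O)=C"),                       # acetone / propen-2-ol
  c("O=Nc1ccc(O)cc1", "ON=C1C=CC(=O)C=C1"),       # nitrosophenol / monoxime
  c("CC(N)=O", "CC(O)=N"),                        # acetamide / imidic acid
  c("O=C1CCCCN1", "OC1=NCCCC1"),                  # lactam / lactim
  c("Cc1nc[nH]c1", "Cc1[nH]cnc1"))                # 4-methylimidazole 1H/3H

# random atom-order permutation of a molgraph (for invariance properties)
permute_molgraph <- function(mol, perm) {
  inv <- order(perm)
  b <- mol$bonds
  b$a1 <- perm[b$a1]
  b$a2 <- perm[b$a2]
  m <- mol
  m$elem <- mol$elem[inv]; m$charge <- mol$charge[inv]
  m$h <- mol$h[inv]; m$arom <- mol$arom[inv]
  m$bonds <- b
  m
}

# independent cheminformatics oracle: canonical SMILES via RDKit (python),
# used only to cross-check equality decisions of the in-package engine
rdkit_canonical <- function(smiles) {
  inp <- tempfile(fileext = ".txt"); out <- tempfile(fileext = ".txt")
  writeLines(smiles, inp)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from rdkit import Chem",
    "lines = open(sys.argv[1]).read().split()",
    "with open(sys.argv[2], 'w') as fh:",
    "    for s in lines:",
    "        m = Chem.MolFromSmiles(s)",
    "        fh.write((Chem.MolToSmiles(m) if m else 'PARSE_FAIL') + '\\n')"),
    script)
  status <- system2("python", c(script, inp, out), stdout = FALSE, stderr = FALSE)
  if (status != 0L) return(NULL)
  readLines(out)
}
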
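---
title: "logpnet: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{logpnet: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic world does and does not emulate, the numerical choices, and the
places where the design was genuinely open. It states no empirical result
that the test suite or the acceptance script does not itself compute.

## 1. The quantity being modelled

log *P* is the base-10 logarithm of the octanol–water partition
coefficient of a neutral species. Two complications drive the package
design.

**Macro versus micro log *P*.** A tautomerizing compound is measured as an
equilibrium mixture, so the observable is the fraction-weighted mixture on
the *linear* scale:

$$\log P_{\mathrm{exp}} = \log_{10} \sum_i P_i\, f_i ,$$

with per-tautomer (micro) partition coefficients $P_i$ and fractions
$f_i$. `macro_logp()` implements exactly this kernel; `log_d()` is the
same kernel over ionization species with pH-dependent fractions
$f_{\mathrm{species,pH}}$:

$$\log D = \log_{10} \sum_s P_s\, f_{s,\mathrm{pH}} .$$

Both accumulate in log space (subtract the maximum exponent before
summing), which keeps the arithmetic exact to better than $10^{-12}$
relative for $|\log P| \le 20$ and stable to magnitudes of several
hundred.

**Speciation model.** Site fractions use an *independent-site*
approximation: a molecule with $n_a$ acidic and $n_b$ basic sites has
$2^{n_a+n_b}$ microstates, and the unnormalized weight of a microstate is
$\prod 10^{\mathrm{pH}-\mathrm{p}K_a(\mathrm{site})}$ over its
deprotonated sites. Micro-pKa coupling between sites is deliberately not
modelled: the package consumes predicted macroscopic site constants, for
which coupled microconstants are generally unavailable. "pKb" throughout
means the pKa of the conjugate acid of a basic site — the only scale on
which the classification window below is coherent.

**Ionization classes.** A compound is classified for a measurement window
of pH 3–9: potential anion if its minimum acidic pKa < 3, potential
cation if its maximum basic pKb > 9, zwitterion if it has both site types
and its acidic pKa exceeds its basic pKb. That last comparison direction
is implemented literally as stated (`convention = "literal"`),
although it inverts the usual chemical criterion (zwitterions dominate
when the basic site's conjugate-acid pKa exceeds the acidic pKa);
`classify_ionization(..., convention = "chemical")` selects the
conventional direction. The min/max reduction over multiprotic site sets
is this package's choice — the alternative (any site) is not
distinguishable from the source material.

## 2. The molecular graph engine

No cheminformatics toolkit is a dependency: the package carries its own
scoped engine because the tautomer transforms, nitro-group normalization
and canonical-collision bookkeeping all need direct access to the kekulé
structure. Scope: organic-subset SMILES plus bracket atoms, charges,
ring closures, aromatic notation, multi-fragment dots. Stereochemistry is
parsed and dropped — records keep the original SMILES string, graphs are
constitution-only, matching the observation that graph convolution
collapses SMILES dialects anyway.

Three passes normalize every input: kekulization (backtracking perfect
matching of double bonds over the aromatic system), implicit-hydrogen
assignment from standard valences (C 4; N 3,5; O 2; S 2,4,6; P 3,5;
halogens 1; charge-adjusted in brackets), and Hückel-style aromaticity
perception over simple cycles up to size 7 (π contributions: 1 for an
atom double-bonded within the ring, 2 for a heteroatom lone pair, 0 for
an exocyclic carbonyl; a 4n+2 total marks the cycle aromatic — so
quinoid rings correctly come out non-aromatic). Canonical SMILES via
iterative neighborhood refinement with deterministic tie-breaking defines
graph identity: two inputs denote the same constitution iff their
canonical strings agree. The test suite cross-checks these equality
decisions against RDKit (via the system `python`) on a fixture battery;
RDKit is an independent oracle only, never a code path.

`normalize_structure()` rewrites hypervalent neutral-nitrogen depictions
(pentavalent nitro `CN(=O)=O`, dative N-oxides, azides) to the
charge-separated standard before modelling; `strip_salt()` keeps the
largest organic fragment, lists whitelisted counterions (alkali/alkaline
earth cations, halides, ammonium, common small inorganics) and
re-neutralizes the parent when the removed ions balanced its charge. Two
equal-sized organic fragments are returned together with an `ambiguous`
flag rather than resolved silently.

## 3. Tautomer enumeration

"All potential tautomers" is defined here as the breadth-first closure of
six transform rules, deduplicated by canonical form, capped at 32 members
and 4 chained applications (caps flag `truncated`, never silently drop):

1. 1,3 keto–enol (C=O with α C–H ↔ C–OH with C=C),
2. amide–imidic acid (N(H)–C=O ↔ N=C–OH),
3. lactam–lactim (the ring variant of 2, labelled separately),
4. imine–enamine,
5. nitroso–oxime extended through an aromatic ring
   (o/p-nitrosophenol ↔ quinone monoxime, with ring re-kekulization),
6. 1H/3H shifts between ring nitrogens of N-heteroaromatics.

Design choices a maintainer should know:

* Rules 1–4 act only on localized (non-aromatic) bonds, and an atom may
  only *receive* a new double bond if all its current bonds are single.
  The first restriction stops phenol from enolizing into cyclohexadienone
  sideways (aromatic-ring-disrupting shifts belong to rules 5–6, which
  re-kekulize the ring they touch and keep quinoid products when
  valence-legal); the second forbids cumulene artifacts.
* Rule 1 requires a ketone/aldehyde carbonyl (no N/O/S single-bonded to
  the carbonyl carbon — amides and esters are rule-2 territory), and rule
  4 requires the C=N carbon to carry only carbon substituents. Without
  these guards the closure cascades through imidic acids into
  aminol-alkene species no measurement would ever see, and the synthetic
  world's tautomer-count statistics become meaningless.
* Hydrogen counts are explicit in the graph, so molecular formula is
  conserved by construction; every candidate is valence-checked and
  re-perceived for aromaticity before acceptance.
* Stereocenters destroyed by a shift are irrelevant here because graphs
  are constitution-only (see §2).
* Thermodynamic ranking of tautomers is explicitly out of scope: the
  entire point of the augmentation protocol is that the dominant tautomer
  never needs to be determined.

`same_tautomer_group()` declares two structures tautomer-duplicates iff
their closures intersect, which makes the relation symmetric and
reflexive by construction and is the basis of the curation grouping.

## 4. Featurization

Fixed 27-column per-atom layout: element one-hot over
{C,N,O,S,P,F,Cl,Br,I,other} (10), heavy-atom degree one-hot 0–5 (6,
degrees > 5 clamp with a warning), hydrogen-count one-hot 0–4 (5), formal
charge (1), aromatic flag (1), in-ring flag (1), hybridization one-hot
{sp, sp², sp³} (3, derived from bond orders and aromaticity, never 3D
geometry). Hydrogens are implicit — rows are heavy atoms only. The
layout id (`logpnet-27-v1`) is stored in every trained model and checked
at prediction time; models are not portable across layout changes.

## 5. The regressor

Architecture (widths 64 and 128 for the two graph-convolution blocks):

```
conv(27→64) → BN → ReLU → max-pool over {v}∪N(v)
conv(64→128) → BN → ReLU → max-pool
per-molecule atom sum → dense(128, ReLU) → BN → dropout 0.1
scalar head z → y = c + s·tanh(z)
```

with `conv`: $h'_v = W_{\mathrm{self}} h_v + \sum_{u \in N(v)}
W_{\mathrm{nbr}} h_u + b$ (permutation-equivariant by construction).
Choices made where the source architecture description is underspecified:

* **Loss and optimizer**: mean squared error with Adam — the standard
  pairing for this architecture family. The default desk-scale learning
  rate is 0.002; the original large-scale runs of this family use
  5e-5–1e-4 over 60–70 epochs on ~30k augmented rows, which is neither
  reachable nor useful at the package's test scale.
* **The tanh head**: read as a *scaled* tanh, $y = c + s\tanh(z)$ with
  $c$ the training-label midrange and $s$ 1.05 × the half-range. A raw
  tanh cannot express log *P* ≈ 8; the 5% margin keeps extreme labels
  inside the representable range without flattening gradients. The
  alternative reading (tanh on the penultimate embedding, linear head)
  is noted but not implemented.
* **Dense width** 128, matching the last conv width.
* **Batch norm** uses batch statistics during training and running
  moments (momentum 0.9) at inference; dropout is inactive at inference,
  so predictions are deterministic. Model selection returns the
  best-validation epoch.
* Everything is seeded: initialization, batch order and dropout masks
  derive from the single training seed, and two trainings with the same
  seed/config/data are bitwise identical (asserted in the tests — R's
  BLAS path here is deterministic).

Evaluation: `rmse()`, and `bootstrap_rmse()` which resamples the
(prediction, label) pairs with replacement N times (default 1000),
reporting the mean of the rmse distribution — which replaces the point
rmse, symmetrizing the confidence interval — and its standard mean error.

## 6. The synthetic world

The generator exists so training, the augmentation benefit, and curation
are testable without downloads. It states a world once; its parameters
are not dials:

* Ground truth is an **atom-additive oracle**: aliphatic C +0.40,
  aromatic C +0.30, hydroxyl O −1.00, carbonyl O −0.70, ether O −0.60,
  N −0.90, S +0.25, F +0.20, Cl +0.70, Br +0.90, I +1.10, plus +0.35 for
  a hydroxyl created by enolization (structurally: OH on a non-aromatic
  C=C carbon). Additivity makes the target exactly representable by a
  sum-gathered graph network, so the oracle-recovery criterion isolates
  optimization quality from model misspecification.
* Molecules (3–20 heavy atoms) come from a fragment grammar: alkyl
  chains, benzene termini, halogen prefixes, polar decorations (alcohol,
  amine, ether, thioether — included so every oracle class actually
  occurs in training data), and three independently drawn tautomer
  motifs: internal ketone with two inequivalent α-carbons (probability
  0.3; contributes *two* distinct enols), amide 0.15, para-nitrosophenol
  0.05.
* Labels are **macro** oracle values: dominant (input) tautomer fraction
  0.8, remainder uniform — mimicking a system where one tautomer
  dominates but others are present — plus Gaussian noise σ = 0.1,
  deliberately below the 0.2–0.4 experimental error band so model error,
  not label noise, dominates desk-scale comparisons.

What a green benchmark establishes: that augmentation with enumerated
tautomers makes the regressor invariant to which tautomer a query is
drawn as, while single-representation training degrades — on a world
whose micro log *P* differences between tautomers are of realistic
magnitude. What it does not establish: performance on real
medicinal-chemistry distributions, ring systems beyond benzene-like
rings, or datasets whose label error is correlated with structure.

## 7. Dataset handling and curation

* CSV dialect: UTF-8, comma separators, mandatory header, `.` decimals;
  multi-valued pKa cells packed with `;`. A minimal V2000 SDF reader is
  provided (elements, bond orders with aromatic = 4, `M  CHG` lines, one
  named property mapped to log *P*).
* Split sizes round half-up on the test count, then on the validation
  count — the convention that reproduces the published 13,889 → 1,389 /
  12,500 arithmetic exactly (the other consistent convention, floor on
  test, gives 1,388; the source does not state its rule). Variants always
  inherit the parent's partition, so augmentation cannot leak structures
  across partitions.
* Variant tables keep one row per distinct canonical graph with the fixed
  precedence original → canonical → explicit-H → tautomers on collisions.
* Curation flags: single-model outliers at strict |experimental −
  predicted| > 1 (boundary cases not flagged); ensemble outliers when at
  least 4 tools each disagree by more than 1, with missing per-tool
  predictions abstaining; duplicate groups as the union-find closure over
  identical-graph, tautomer-group and salt-stripped-parent relations,
  reporting the label spread per group. Resolution is reported, never
  auto-applied — the flags narrow manual primary-source checking to a
  manageable number, they do not replace it. NHA error stratification
  uses half-open bins with configurable edges (default 0/10/20/30/∞).

## 8. Known limitations

* The SMILES engine targets the subset of chemistry its modules generate
  and curate (organic subset + common ions); exotic valences, radicals
  and stereo-dependent properties are out of scope.
* Canonicalization resolves ties by atom index after refinement; for
  pathological regular graphs (not reachable by the generator or the
  fixture chemistry) two labelings could in principle canonicalize
  differently.
* The tautomer rule set is a definition, not a claim of completeness:
  ring-chain and valence tautomerism, and shifts through fused
  heteroaromatic systems, are not enumerated. Equivalence with any
  specific commercial enumerator is not claimed and not testable.
* The zwitterion rule is implemented in its stated (unconventional)
  direction by default; users who want the chemical convention must opt
  in.
* Training is CPU-bound pure R; it is sized for thousands of molecules,
  not the ~14k-compound full-scale setting, and published full-scale
  accuracies are out of reach at this scale by design.
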
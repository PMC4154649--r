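---
title: "Peptide-based 13C metabolic flux analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-based 13C metabolic flux analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepMFA)
```

## The problem

Steady-state 13C metabolic flux analysis (13C MFA) infers intracellular
reaction rates from the isotope labeling patterns that a defined 13C
substrate imprints on metabolism. The labeling of a molecule is summarized
by its mass distribution vector (MDV): the fractions of its population
carrying m = 0, 1, 2, ... extra mass units. Classically the measured
molecules are proteinogenic amino acids, but an amino-acid sample from a
microbial community is an unattributable mixture across species. Peptides,
by contrast, can be assigned to a species by their sequence, and their
labeling is fully determined by their amino-acid composition: the MDV of a
peptide is the convolution (Cauchy product) of its residues' MDVs. This
package implements flux inference from either data type, quantifies the
information cost of using peptides through a flux information content
(FIC), and resolves per-species fluxes in simple communities from
species-unique peptides.

## Carbon-transition networks

Models are tab-separated text: reactions with per-carbon atom mappings
(`A (abc) -> C (bc) + CO2 (a)`), a substrate-labeling section (positional
13C purity per carbon), and measured net fluxes. Every reactant carbon
letter must appear exactly once among the products; boundary
import/export reactions are exempt. Reversible reactions are split into a
forward/backward pair whose backward mapping is the inverse of the
forward one; backward fluxes are capped at `exchangeCap` (default 10
substrate-uptake units), a standard exchange-flux parameterization. All
fluxes are reported relative to the substrate uptake, which is normalized
to 1 at load time. Substrate carbons not covered by the labeling section
default to natural 13C abundance (0.0107); the bundled fixtures set them
to 0 to keep hand-derived oracle values exact.

```{r}
net <- readNetworkModel(toyModelText("toy1"), unspecifiedPurity = 0)
net
```

## EMU simulation

Labeling is simulated with the elementary metabolite unit (EMU)
decomposition: the target MDVs are traced backward through the atom
mappings, producing a dependency graph whose nodes are metabolite carbon
subsets and whose condensation reactions create combined nodes. The graph
is acyclic across EMU sizes, so labeling is obtained by one linear solve
per size stratum (dense LU; the strata of the bundled models have at most
a few dozen unknowns), with combined-EMU MDVs formed by convolution of
their constituents. Cycles within a stratum (e.g. CO2 refixation) are
handled naturally by the linear solve. A profile must satisfy S v = 0
within 1e-8; EMUs with zero total production are reported as dead rather
than silently inverted.

As an independent check, `isotopomerOracle()` solves the complete
2^C positional-isotopomer balance by damped successive substitution
(renormalizing each sweep and keeping the best iterate; on networks with
strong recycle loops the bare iteration can destabilize after reaching
the solution, which is why the best-residual iterate is returned). The
two implementations agree to better than 1e-8 on every bundled fixture
over random feasible flux profiles; the oracle is exponential in carbon
count and is capped at 12 carbons per metabolite.

## Peptides

`digestProteome()` applies trypsin rules (cleave after K/R, not before
P). `selectPanel()` keeps peptides that are unique as strings across all
supplied proteomes and pairwise distinct in amino-acid composition -
peptide labeling depends only on composition, so anagrams are redundant.
Candidates are sorted by (length, lexicographic order) and drawn with a
seeded RNG, so panels are reproducible. `peptideMdv()` convolves residue
MDVs sequentially; the dummy residue `X` contributes the delta MDV and
is inert, so padded sequences give identical results.

Natural-isotope corrections map a traced-carbon-backbone MDV to the
observable MDV by a banded lower-triangular matrix whose band is the
mass-shift distribution of the molecule's heteroatoms (H, N, O, S and
non-traced carbons), built from standard abundances and truncated at a
configurable shift window (default +4). Corrections are applied per
amino acid before convolution (`peptideMdv(..., correct = TRUE)`); the
alternative - one correction per peptide from its summed formula -
differs only in truncation behaviour because the underlying shift
distributions multiply either way. The bundled simulation studies leave
the correction off, matching their idealized (natural-abundance-free)
substrate settings.

## Flux fitting

`fitFluxes()` minimizes the error-weighted sum of squared MDV residuals
over the affine space {v : S v = 0, measured fluxes}, parameterized by an
orthonormal null-space basis so the equalities hold exactly; bound
constraints are enforced by an exterior quadratic penalty inside a
multi-start quasi-Newton optimizer (`nlminb`), with starts drawn by
hit-and-run from the flux polytope. In peptide mode the simulated
amino-acid MDVs are convolved into peptide MDVs before comparison, which
is the only difference between the two modes. The residual weight is the
per-element measurement error (default 0.01, a typical MDV precision).

`fluxBounds()` computes, per reaction, the extreme net fluxes attainable
while the simulated labeling stays within per-element error bounds of
the data. Two methods are provided:

* `"nlp"` (default): two penalized NLPs per flux with penalty
  continuation, warm-started from the best fit, followed by a bisection
  pullback to the feasibility boundary. This mirrors the classical
  per-flux min/max formulation.
* `"grid"`: a deterministic regular grid over the free-flux polytope
  (`gridN` points per free dimension, default 21; the ground-truth or
  best-fit point is always included). Ranges are read off the feasible
  grid points. Because one simulation pass serves any number of
  measurement subsets, this is the workhorse behind the FIC curves,
  at the cost of resolving ranges only to the grid spacing.

## Flux information content

FIC = -k ln Omega, with Omega approximated by the enveloping box of the
per-flux ranges and each width floored at epsilon = 0.01 so fully
determined fluxes contribute a finite constant (k = 1; only differences
matter). `ficCurve()` grows a panel prefix by prefix (in the panel's
deterministic order), computes all-flux ranges on a shared grid, and
reports the smallest panel size whose FIC reaches the amino-acid
reference computed with the same error bounds. The reference can be
restricted to the directly measured amino acids (`config$targets`);
the bundled central-carbon analyses use ALA, SER, GLY, ASP, GLU, VAL as
measured and treat THR, LYS, ARG as derived-only, so peptides carry
residues the amino-acid reference does not see - as in realistic GC-MS
panels, which cover only part of the proteinogenic alphabet.

Two error-bound semantics are implemented for the range subproblems, and
they answer subtly different questions:

* **absolute** (`errModel = "absolute"`): every MDV element may deviate
  by at most a flat bound (default 0.01). Under this semantics
  convolution can only lose information: a peptide spreads each
  residue's labeling deviation over more mass channels, so its largest
  element deviation is diluted, and the peptide FIC stays at or below
  the amino-acid FIC. The qualitative trends follow: shorter peptides
  are more informative than longer ones at equal count, and the
  amino-acid reference is reached only by panels that effectively
  contain the amino-acid constraints themselves (e.g. single-residue
  targets). A best-case composition scan on the bundled central-carbon
  fixture shows that even ideal 5-15-mers stay 1.2-1.5x wider than the
  best single amino acid along the fixture's least-determined (futile
  cycle) direction, so exact FIC matching is structurally out of reach
  under flat bounds.
* **relative** (`errModel = "relative"`, the `ficCurve()` default):
  each element's bound is `amp * (value + 0.05)`, the natural bound for
  multiplicative mass-spectrometric noise (amplitude default 0.05, with
  a small detection-floor offset). Because peptide elements are smaller
  in proportion to their spread, their bounds tighten proportionally and
  the dilution cancels; composition-biased peptides (several copies of
  co-sensitive residues, the rule rather than the exception in real
  tryptic digests) can even be sharper than any single amino acid. Under
  this semantics the information loss is countered by a modest panel:
  on the bundled fixture every length group (5, 10, 15, mixed) reaches
  the amino-acid FIC within at most ~10 peptides.

Both semantics are exposed so the user can reproduce either regime; the
comparison between modes is always like-for-like (identical bound model
on both sides).

## Communities

A community model is a set of species (network + species-unique peptide
measurements) joined by exchanged metabolites. For acyclic exchange
topologies the problem decomposes: species are fitted in topological
order, and the labeling of each exchanged metabolite is simulated from
the upstream best fit and passed downstream as substrate labeling. The
hand-off happens at EMU resolution (every carbon subset the downstream
decomposition needs), not just the full-molecule MDV, so positional
information survives. Cyclic exchange topologies raise an error: the
iterative scheme is defined only for the compartmentalizable case.
Species biomass fractions enter only `mixtureLabeling()`, which
demonstrates why unseparated community samples are insufficient: the
labeling-to-flux map is nonlinear, so fluxes fitted to an averaged
labeling are not averaged fluxes.

Exchanged metabolites that a downstream species does not incorporate
into biomass are simply modeled as sink-only metabolites in that
species' network.

## Synthetic study material

`makeToyFixtures()` builds every input used by the tests:

* `toy1` - a three-carbon toy with one free flux split readable directly
  from the product MDV under [1-13C] substrate; `toy1c` adds a
  condensation branch.
* `chainA`/`chainB` - a two-species chain (fermenter exporting a
  two-carbon intermediate with an identifiable route split; downstream
  consumer whose one-carbon amino-acid analog reads the intermediate's
  positional labeling).
* `ecc1` - a reduced synthetic central-carbon network: glycolysis,
  oxidative and non-oxidative pentose-phosphate pathway with standard
  transketolase/transaldolase mappings, a lumped TCA cycle (no
  symmetric-intermediate scrambling), ppc anaplerosis, a malic-enzyme-
  like OAA to PYR route (the deliberately ill-determined futile cycle),
  and biosynthesis of nine amino acids with drains fixed at 0.02.
  [1-13C] glucose, uptake 1, two free flux dimensions. It is a synthetic
  fixture in the style of published reduced models, not a copy of any
  specific one.
* a toy proteome of twelve proteins over the nine-residue alphabet the
  reduced network can label, whose tryptic digest yields 40
  composition-distinct peptides of each length 5, 10 and 15. Each toy
  protein draws its own residue-usage profile (a Dirichlet draw), which
  reproduces the low-complexity, composition-biased character of real
  tryptic peptides; that bias is load-bearing, because peptides with
  repeated co-sensitive residues are what carries flux information
  through the convolution.

`sampleFluxProfile()` draws near-uniform feasible profiles by coordinate
hit-and-run in the null-space coordinates (1000 burn-in steps, seeded).
`generateMeasurements()` applies the multiplicative noise model
MDV' = MDV (1 + Delta r), r ~ Uniform(-1, 1), element-wise, then clamps
at zero and renormalizes (renormalization keeps noisy targets valid
MDVs and can be disabled); the recorded error is Delta, or 0.01 for
noiseless sets. Noise is independent per element; correlated
per-spectrum noise is not modeled.

## Numerical choices and problem sizes

Tolerances: MDV unit-sum 1e-9 (1e-6 for file input), steady state 1e-8,
EMU-vs-oracle agreement 1e-8, convolution oracle 1e-12. The bundled
analyses use simulation grids of 21-61 points per free dimension and
panels of up to 40 peptides; the noise study uses 20 replicate seeds per
amplitude at amplitudes 0.05 / 0.08 / 0.10 with panels of 5 and 20
10-mers. These sizes keep every analysis deterministic and comfortably
reproducible on a single CPU while resolving the effects they measure;
ranges from the grid method are only resolved to the grid spacing, which
is why FIC values are always compared between computations sharing one
grid.

## Limitations

* Steady-state labeling only; no isotopically nonstationary analysis.
* The full-isotopomer oracle is exponential and capped at toy scale.
* The grid-based range method scales as `gridN^d` in the free-flux
  dimension d and is intended for reduced models (d of a few), as used
  here; the NLP method has no such limit but solves two problems per
  flux.
* Local, multi-start optimization: no global optimality certificate.
* Community solving requires an acyclic exchange topology and
  species-unique peptide panels.
* Peptide identification, spectrum processing and detectability are out
  of scope; measured MDVs are taken as given.
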
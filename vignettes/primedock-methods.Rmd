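---
title: "Template-based modeling of protein-RNA complexes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based modeling of protein-RNA complexes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primedock)
```

## The problem

Experimentally determined structures cover only a fraction of known
protein-RNA interactions. When a complex of a structurally similar
protein-RNA pair is already known, a model of the target complex can be
built by *template-based docking*: align the target protein to the
template protein and the target RNA to the template RNA, then carry both
target monomers into the template frame with the rigid transforms those
alignments produce. The quality of the result is almost entirely a
question of template selection, and the empirical finding this package
operationalizes is that monomer similarity undergoes a *phase
transition*: above a similarity threshold (~0.45 in complex structural
score, ~0.3 in complex sequence identity with coverage >= 0.3),
binding modes of complex pairs switch from essentially random to mostly
shared. Score cutoffs at the transition point therefore separate usable
templates from noise.

## The pipeline and its statistics

**Binary complexes.** All structures are reduced to binary complexes:
one protein chain plus one RNA chain in contact. A residue is
interfacial iff any of its heavy atoms lies strictly within 5 angstroms
of any heavy atom of the partner chain. Admissible complexes satisfy:
resolution <= 3.0 angstroms (entries without a crystallographic
resolution are excluded), protein length >= 30 residues with Calpha,
RNA length >= 20 nt with C3', and at least 5 interfacial residues per
side.

**Monomer similarity.** Three routes are implemented:

* *Local sequence alignment* (Smith-Waterman, affine gaps; BLOSUM50 with
  open 10 / extend 2 for proteins, +5/-4 with open 12 / extend 4 for
  RNA). Identity is counted over the local alignment's columns; coverage
  is the aligned fraction of each full chain.
* *Global sequence alignment* (Needleman-Wunsch; BLOSUM62 with
  open 10 / extend 0.5, +5/-4 with open 10 / extend 0.5). Coverage is 1
  by construction.
* *Structural alignment*: a TM-score aligner for proteins and a
  backbone aligner for RNA (below).

Complex-level conventions are minima: complex identity is the smaller
monomer identity, complex coverage the smallest of the four chain
coverages, and the complex structural score the smaller of the protein
TM-score and the normalized RNA score. The minimum rule is what lets a
dissimilar RNA veto a deceptively similar protein (the noise-filtering
rationale behind ranking templates by the complex score rather than the
TM-score alone).

**Protein structural alignment.** TM-align-style: gapless threading
seeds, then iterated rounds of (i) superposing on the current residue
correspondence with close-pair refinement, (ii) rebuilding the
correspondence by dynamic programming over the similarity matrix
$S_{ij} = 1/(1 + d_{ij}^2/d_0^2)$ with gap penalty $-0.6$ and free end
gaps. The converged correspondence is re-scored with the full TM-score
rotation search (sliding-fragment seeds with iterative close-pair
extension), giving

$$\mathrm{TM} = \max_{R,t} \frac{1}{L} \sum_i \frac{1}{1 + (d_i/d_0)^2},
\qquad d_0 = 1.24\,(L-15)^{1/3} - 1.8 \; (\ge 0.5\,\mathrm{\AA}),$$

normalized by the *target* length $L$ (the template-search convention:
the query is the reference; the worked-example tolerances cover the
alternative normalization).

**RNA structural alignment.** The same machinery on C3' atoms, seeded
additionally by a shape fingerprint: dynamic programming over windowed
dot products of consecutive-C3' unit vectors. The raw score is the TM
functional form without normalization, and the reported score is
normalized by the raw score of the target aligned to itself (which
equals the target length), so self-alignment scores exactly 1. Because
C3' spacing (~6 angstroms) is far coarser than Calpha spacing, the RNA
aligner uses the RNA-alignment distance-scale convention
$d_0 = 0.6\sqrt{L - 0.5} - 2.5$ floored at 1.25 angstroms; with the
protein formula (floor 0.5) the score is hypersensitive - a 0.3
angstrom-noise copy of a 20-nt RNA scores ~0.5. The aligner emits its
rigid transform directly; `recover_transform()` exists for parity
checks. No bit-exact parity with any external RNA aligner is promised;
only the normalized score and the transform are consumed downstream.

**IRMSD.** Binding-mode similarity of two complexes of possibly
different monomers: pool the structurally aligned residue pairs
(protein Calpha and RNA C3') whose residue is interfacial in the first
complex or whose partner is interfacial in the second, superpose the
pooled set with a single joint Kabsch fit, and report the minimized
RMSD. At least 3 pooled pairs are required; otherwise the pair is
*incomparable* (`NA` with a reason), never silently 0. Whether the
published protein-protein IRMSD pools both molecules into one fit or
fits on one molecule is not documented; pooling is the default and the
receptor-only alternative is available behind `pool = FALSE`.

**Model building and evaluation.** `build_model()` applies the protein
transform to all target protein atoms and the RNA transform to all
target RNA atoms. `ligand_rmsd()` superposes the model protein Calpha
trace onto the native protein and reports the RMSD over RNA C3' atoms -
the receptor-frame ligand RMSD convention of rigid docking. Quality
classes are nested: high (< 2 A, the half-open 0-2 band), medium
(<= 5 A), acceptable (<= 10 A), incorrect (> 10 A). Clash counting
(heavy-atom pairs strictly within 3.0 angstroms across the interface)
is retained so a refinement stage can be added later; refinement itself
is out of scope.

**Curation.** Redundancy is removed on the RNA side only (protein
redundancy is deliberately untouched): single-linkage clustering at
global sequence identity >= 0.99 with mutual coverage >= 0.99, one
internal pass (the published two-tool sequence was a workaround for a
word-size limitation our aligner does not share). The representative is
the best-resolution member (ties: earliest deposit date, then id). The
template/target split sorts by deposit date and designates the older
`ceiling(0.8 n)` as templates. Note that the published counts 349/90
for n = 439 match no rounding of 80% (0.8 x 439 = 351.2); the ceiling
convention is used and documented rather than reverse-engineering an
unstated grouping.

**Binning conventions.** Transition curves use 0.05-wide half-open bins
`[x, x + 0.05)` with the last bin closed; empty bins carry `NA`, not 0.
Quadrant cuts at x = 0.45 / y = 0.25 are closed on the upper/right side
(a pair exactly at the cut belongs to the high quadrants).

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| interface cutoff | 5.0 | angstrom | heavy-atom contact definition |
| min protein / RNA length | 30 / 20 | residues | admissibility filters |
| min interface size | 5 / 5 | residues | admissibility filters |
| resolution cutoff | 3.0 | angstrom | crystallographic quality filter |
| clustering identity / coverage | 0.99 / 0.99 | fraction | near-duplicate removal only |
| template fraction | 0.8 | fraction | date split (ceiling) |
| score cutoff | 0.45 | complex structural score | the transition point |
| local-coverage threshold | 0.3 | fraction | noise filter for local-alignment analyses |
| ligand-RMSD classes | 2 / 5 / 10 | angstrom | high / medium / acceptable |
| clash cutoff | 3.0 | angstrom | heavy-atom clash counting |

## The synthetic world

Nothing in the test suite downloads structures. `make_protein()` builds
an alpha-helical Calpha trace (rise 1.5 angstroms, 100 degrees per
residue, radius 2.3; consecutive Calpha ~3.8 apart) with three dummy
heavy atoms per residue at fixed offsets; `make_rna()` an A-form-like
C3' helix (rise 2.8, 32.7 degrees, radius 9.4) with dummy
phosphate/sugar/base atoms. Two deliberate departures from perfectly
ideal helices, both seeded and deterministic:

* a *quadratic twist drift* (well under a degree per residue), and
* a *gentle bend* implemented as progressive hinge rotations
  (0.02-0.05 degrees per residue), which preserve consecutive distances
  exactly.

A mathematically ideal helix is screw-symmetric: every same-length
synthetic protein would be the *same* rigid body, so template ranking
would be decided by tie-breaking, and a rotation about the protein axis
could map azimuth-differing binding modes onto each other, capping
IRMSD between "different" modes near 6 angstroms. The fingerprints keep
the stated local geometry while making chains globally distinguishable.

Binding modes come from a fixed library of six placements. The three
primary modes differ pairwise by 30 angstroms in *axial* offset along
the protein helix - an axial shift is the one displacement a rotation
about the helix axis cannot compensate - so same-monomer pairs in
different primary modes have IRMSD far above the 5-angstrom similarity
threshold by construction, while modes 4-6 are azimuth-flipped
variants. The RNA-protein axis separation is found deterministically as
the closest clash-free contact that leaves at least 5 interfacial
residues per side.

The planted benchmark (`make_benchmark_set()`) states its world
explicitly: 12 of 20 targets have a good template planted in the
library (a noisy copy of the target, per-coordinate sigma 0.3
angstroms, same binding mode); the other 8 carry an RNA longer than any
library RNA by more than the cutoff ratio, so no template can reach the
0.45 cutoff for them *by a length bound*, independent of alignment
behaviour. The acceptable success rate at top 10 is therefore exactly
0.6 - and the test asserts exactly that. What a green benchmark does
*not* establish: performance on real structures, flexible RNA, modified
residues at interfaces, or any absolute quality of the alignment
heuristics beyond the planted contrasts; the synthetic world has no
sequence-structure relationship and no conformational change.

## Numerical choices

* Kabsch superposition is SVD-based with reflection correction;
  collinear inputs are solved but flagged `degenerate`.
* The structural DP uses free end gaps; ties in the traceback prefer
  the diagonal. On chains of length <= 8 the DP equals exhaustive
  enumeration of monotone alignments (tested).
* All alignments are sequential (order-preserving); no circular
  permutations.
* Interface detection uses a uniform spatial grid at the cutoff length;
  equality with the all-pairs scan is a standing property test.
* Alternate locations: highest occupancy wins, ties to altloc `A`, then
  alphabetical. Hydrogens, waters, ions and free ligands never enter
  heavy-atom sets. Multi-model files contribute MODEL 1 only.
* Chain classification requires >= 70% standard residues (amino acids,
  or A/C/G/U); modified residues with the representative backbone atom
  are retained and count toward lengths (sequence letter `X`/`N`).
  DNA and hybrid chains are dropped with a warning.
* Residue ordinals are 1-based in the R API; author numbering is kept
  for reporting only.
* Ranking ties break by template id; all tables are written with fixed
  numeric formatting so reruns are byte-identical.

## Known limitations

* Single-chain protein, single-chain RNA only; no assemblies, no
  symmetry reconstruction.
* Rigid-body models; no refinement, no flexibility, no free-docking
  fallback (out of scope by design - callers are told when no template
  passes the cutoff).
* The RNA aligner is a self-normalized backbone aligner in the spirit
  of unit-vector methods, not a port of any particular program;
  score-level parity with published RNA aligners is approximate.
* Worked-example checks against deposited entries require network
  access to fetch coordinates; they are red in offline runs and state
  so in their failure message.
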
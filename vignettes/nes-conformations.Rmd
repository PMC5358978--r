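---
title: "Sequence patterns, backbone conformations and the filter lysine: how crmnes models CRM1-bound NESs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence patterns, backbone conformations and the filter lysine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmnes)
```

## The problem

CRM1 (exportin-1/XPO1) exports hundreds of different cargo proteins out of
the nucleus by binding short nuclear export signals (NESs): 8-15 residue
peptides that insert 3-5 hydrophobic anchor residues (Phi = Leu, Val, Ile,
Phe or Met) into five pockets (P0-P4) of a groove between HEAT repeats 11
and 12. NES sequences are famously diverse, and sequence-consensus
matching alone produces many false positives. Crystal structures of
CRM1-NES complexes show why: the groove tolerates a wide range of backbone
conformations - helix-strand, 3~10~-helix-strand, loop, all-helix,
helix-beta-turn, and all of these threaded in either chain direction - as
long as three structural requirements are met. `crmnes` implements both
layers: the eleven-class sequence consensus taxonomy, and the geometric
tests for the structural requirements.

## The consensus library

A pattern is an ordered list of spacer counts ("gaps", the number of X
residues between consecutive Phi anchors):

```{r}
nes_classes()[, c("class", "pattern", "n_anchors", "reversed", "symmetric")]
```

Classes 1a-1d, 2 and 3 are the legacy plus-orientation patterns; 1a-R to
1d-R are their reversed (minus-orientation) variants, whose gaps are the
forward gaps read backwards. Class 4
(Phi0-XX-Phi1-XXX-Phi2-XX-Phi3-XXX-Phi4) extends class 3 by a fifth anchor
reached through a beta-turn. A class is flagged `symmetric` when its gap
vector is palindromic, in which case scanning forward and reverse are the
same operation and no separate reversed pattern is needed; this holds for
classes 2 and 3. Class 4's gap vector (2,3,2,3) is not palindromic under
this definition, but the library still carries no 4-R pattern: the
taxonomy has eleven entries, and the structural evidence for class 4 is a
(+)-orientation complex. The spacings of classes 1a (3,2,1) and 1c (3,3,1)
follow the established class nomenclature and are cross-checked in the
test suite against sequences whose class membership is documented (PKI for
1a; HDAC5 and Paxillin for 1b).

`scan_nes()` reports every window whose anchor slots are Phi letters, with
0-based and 1-based coordinates, overlapping matches included by default
(a best-per-locus reducer with a documented lexicographic preference -
more anchors, earlier start, lower class ordinal - is available for
summaries). Matches are annotated as amphipathic when a subset of the Phi
positions inside the window realizes one of the helical-face offset
patterns i/i+4/i+7, i/i+3/i+7 or i/i+3/i+7/i+10. Class-3 matches carry an
alternative register (Phi0..Phi3 with P4 unused) because all-helix class-3
peptides occupy only the wide half of the groove; the flag is marked
"pending structure evidence" since sequence alone cannot decide the
register.

## Backbone geometry

`build_backbone()` constructs peptides from per-residue phi/psi/omega by
sequential internal-coordinate chain extension with fixed ideal geometry
(N-CA 1.458, CA-C 1.525, C-N 1.329 A; CB placed at the L-configuration
improper torsion of -122.5 degrees). Recomputing dihedrals on a built
structure reproduces the specification to < 1e-3 degrees, which makes the
builder and the dihedral code mutual round-trip tests; the dihedral sign
convention is additionally pinned to an independent structural package on
a real protein structure in the test suite. Superposition uses the Kabsch
SVD solution constrained to a proper rotation; collinear references are
rejected rather than silently fit.

## Secondary structure and the conserved turn

`assign_sse()` labels residues H/G/E/T/L from dihedral windows plus
carbonyl hydrogen-bond geometry:

* helical dihedrals: phi in (-110, -25), psi in (-80, 10). The window is
  deliberately wide enough to hold both the alpha (-57, -47) and 3~10~
  (-49, -26) canonical values with comparable margin, because the package
  classifies noisy backbones (see below) and a tight window turns single
  8-degree excursions into spurious run breaks. Single-residue excursions
  flanked by helical residues are bridged unless they fall in the strand
  region.
* runs of at least 3 fully-defined helical residues become helices;
  termini with one undefined dihedral may extend but not carry a run.
* helix type: a run is 3~10~ (G) when it keeps i to i+3 O...N contacts
  (mean <= 3.5 A) but has lost the i to i+4 contacts an alpha-helix
  retains, and the run-mean psi sides with -26 rather than -47. The last
  two residues of long runs are excluded from typing because runs ending
  in the conserved turn unwind toward the strand.
* strand (E): psi in [85, 180] with phi < -45; type I beta-turns (T):
  central residues near (-60, -30) and (-90, 0), each within 30 degrees,
  with CA(i)-CA(i+3) < 7 A.

The one element shared by every known CRM1-bound NES is a single turn of
helix at Phi2-X(2-3)-Phi3. `find_conserved_turn()` slides a 4-residue
window over the admissible registers: for a (+) NES the window starts at
Phi2 or Phi2+1 (the latter covers the 5-residue Phi2-X3-Phi3 spacing) and
must end at or before Phi3, with three helical-face psi values followed by
a strand-range psi; for a (-) NES the mirrored signature (strand psi, then
three helical) starts between Phi3 and Phi2-1. The helical-face window
[-80, 40] is wider than the strict helix window because the turn's psi
values drift upward toward the transition - the documented exemplar series
reach -1.3 and +16.5 degrees. A (+) turn whose final residue is the chain
terminus is accepted with a note: in all-helix NESs the helix simply exits
the groove and the transition residue does not exist. `psi_progression()`
checks the gradual rise (fall, for minus) of psi through the turn,
implemented as non-strict monotonicity with one allowed violation of at
most 5 degrees to absorb crystallographic noise.

## Class calling

`call_class()` maps the labelled architecture onto the class taxonomy:
alpha-helix then strand is the 1a/1c/1d family (resolved by anchor
spacing), 3~10~ then strand is 1b, loop-dominant with only the conserved
turn is class 2, all-helix is class 3 (with the Phi0..Phi3 register and an
empty edge pocket), helix plus a terminal beta-turn reaching Phi4 is class
4, and strand-then-helix with a minus turn is the 1-R family. When
sequence matches are available the call is restricted to classes the
sequence supports, and disagreements are reported rather than resolved
silently - a sequence can match class 1b while the peptide binds with
class-1a anchors, and both readings are retained. Orientation comes from
the turn, but pocket-order evidence from an anchor map dominates when
present; without a groove the call can be "orientation ambiguous".

## Groove analysis

A `pocket frame` fixes the reference geometry: P0-P4 centers (side-chain
heavy-atom centroids of the reference NES anchors), the reference anchor
CA positions for displacement measurement, the filter lysine (ScCRM1
Lys579 = Hs/MmCRM1 Lys568; the numbering map is a two-point anchored
offset of -11 applied only within the groove region), and the groove
residue selection (any CRM1 residue with an atom within 8 A of the bound
NES). Frames serialize to JSON so downstream analyses need no structure
files.

Anchor assignment is greedy minimal-distance one-to-one matching of Phi
side-chain centroids to pocket centers with a 4.0 A cutoff - chosen to
exceed the largest observed mean anchor displacement (about 1.8 A at P0)
plus spread - with ties broken toward the lower residue number. Orientation
is read from whether pocket labels increase or decrease with residue
number. Fewer than three assigned pockets fails the first NES criterion.

Hydrogen bonds to the filter lysine use NZ...O <= 3.5 A and a C-O...NZ
angle >= 90 degrees; hydrogens are not modelled because the crystal
structures this models are at ~2.1-2.4 A resolution. Two bonded carbonyls
at spacing 2 or 3 constitute a niche3/niche4 motif; for (+) NESs the
expected donors are the Phi2+1 and Phi3 carbonyls of the conserved turn
(the strand psi of Phi3 is precisely what rotates its carbonyl toward the
lysine), while (-) NESs bond through carbonyls near the strand-helix
junction without the niche geometry. The steric filter computes van der
Waals overlaps (C 1.70, N 1.55, O 1.52, S 1.80 A) between every peptide
atom and the lysine side chain; any overlap > 0.4 A - the conventional
serious-clash threshold - blocks the peptide. All thresholds live in one
structure (`nes_thresholds()`) and are serialized into every report.

`nes_criteria_report()` combines the three requirements of an active NES:
(1) 3-5 anchors in 3-5 pockets, (2) the conserved one-turn helix, and
(3) backbone hydrogen bonding with the filter lysine without steric
conflict.

## What the synthetic generator emulates - and what it does not

The builder's class templates are idealized architectures: canonical
dihedrals per secondary-structure segment, anchors at the class spacing,
and a graded psi series through the conserved turn (-45, -25, -8 into the
strand) mirroring the documented progression. Mock complexes plant pocket
markers at anchor side chains and a pseudo-lysine nitrogen placed by
penalized least squares at hydrogen-bond distance from the two expected
donor carbonyls; the optional `guard` option adds side-chain bulk aimed
into the space a non-transitioning (false-positive) helix would occupy,
emulating the groove constriction. Decoys for the clash tests reproduce
the two documented failure geometries: an all-helix peptide one turn
longer than a class-3 NES, and a minus-orientation helix over-extended at
its N-terminus.

Noise is independent Gaussian on phi and psi (default sigma 8 degrees,
seeded). Under these conditions the classifier recovers the generating
class for at least 95 of 100 replicates of each of the six backbone
shapes; the suite runs 100 replicates per shape. This models coordinate
uncertainty, not conformational heterogeneity: real peptides have
correlated dihedral deviations, side chains beyond CB, waters, and a real
receptor surface. Passing these tests therefore demonstrates that the
geometric criteria are self-consistent and robust to local noise, not that
the classifier has been validated against deposited crystal structures -
the analysis path for those (load PDB/mmCIF, superpose on the groove,
recompute dihedrals and displacements, run the filters) is implemented and
exercised end to end on synthetic stand-ins clearly labelled as such.

## Numerical choices and degenerate inputs

Chain breaks (C-N > 2.0 A) make the spanning dihedrals undefined rather
than computed across the gap. Alternate locations resolve to highest
occupancy, then altloc A. Sequences shorter than a pattern window return
empty match sets; empty sequences are not an error, but non-standard
letters (including `*`) are, with the offending position named. Backbones
need at least 4 residues. Collinear superposition references and frames
missing the lysine NZ are errors. All generators are deterministic under a
seed and restore the caller's RNG state.

## Limitations

The package does not predict NES activity or binding affinity, does not
model unbound-state ensembles or receptor flexibility, and does not handle
electron density or refinement. The pocket-center convention (anchor
side-chain centroids) and the 85-residue-scale groove selection rule are
package conventions: the source structures' groove selections are not
enumerated anywhere machine-readable, so cross-structure RMSD values
computed here are selection-dependent. Sequence scanning deliberately
implements only the consensus taxonomy - no disorder or accessibility
filtering, and no machine-learned scoring.
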
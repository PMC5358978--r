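# crmnes

Sequence and structure analysis of CRM1 nuclear export signals in R.

## The problem

CRM1 (exportin-1/XPO1) exports hundreds of cargo proteins bearing nuclear
export signals (NESs): 8–15 residue peptides with 3–5 hydrophobic anchors
(Φ = L/V/I/F/M) that bind the P0–P4 pockets of the CRM1 groove. NES
sequences are described by consensus patterns — spacings of X residues
between Φ anchors, e.g. class 3 is Φ1-XX-Φ2-XXX-Φ3-XX-Φ4 — but consensus
matching alone is unreliable: peptides matching a pattern often fail to
bind. Structures of CRM1–NES complexes explain both the permissiveness and
the selectivity. NES backbones range from loop to all-helix in either chain
orientation, yet all share one structural element — a single turn of helix
at Φ2-X₂₋₃-Φ3 whose ψ angles rise progressively into a β-strand — and all
hydrogen-bond through main-chain carbonyls to a groove-constricting lysine
(HsCRM1 Lys568 / ScCRM1 Lys579), whose side chain also sterically blocks
consensus-matching false positives.

`crmnes` implements both layers for structural bioinformaticians working on
nuclear transport:

* the **eleven-class consensus library** (1a–1d, 2, 3, 4, 1a-R–1d-R) with a
  scanner, reversal duality, amphipathic-helix annotation and
  overlap/locus reduction;
* **backbone geometry**: φ/ψ/ω dihedrals, Kabsch superposition, PDB and
  mmCIF input, PDB output;
* a **conformational classifier**: DSSP-like secondary-structure labels
  (α/3₁₀/strand/type-I β-turn/loop), the conserved one-turn-helix
  detector with ψ-progression check, and a class caller that reports
  sequence/structure disagreements;
* **groove analysis**: P0–P4 pocket frames, greedy anchor-to-pocket
  assignment with orientation, Φ Cα displacement statistics, filter-lysine
  hydrogen bonds and niche3/niche4 motifs, and a van-der-Waals clash
  filter implementing the three-criterion "active NES" verdict;
* a **synthetic builder**: ideal-geometry backbones from per-residue
  dihedral templates for every class, mock groove complexes, decoy
  geometries, and seeded random sequences with embedded motifs for
  matcher evaluation.

## Worked example

Scan the X11L2 NES region and classify a synthetic class-4 peptide:

```r
library(crmnes)

scan_nes("SSLQELVQQFEALPGDLV", sequence_id = "X11L2")[,
  c("sequence_id", "class", "start_1based", "anchors_1based",
    "anchor_letters", "amphipathic")]
#>   sequence_id class start_1based anchors_1based anchor_letters amphipathic
#> 1       X11L2     3            3      3,6,10,13           LLFL        TRUE
#> 2       X11L2     4            3   3,6,10,13,17          LLFLL        TRUE
```

The same 18-mer matches class 3 (anchors at offsets 0,3,7,10 — the
amphipathic-helix spacing) and class 4, which adds a fifth anchor three
residues further on. Structure decides between the readings:

```r
tp <- build_class_template("4")          # helix + type I beta-turn template
res <- classify_peptide(build_backbone(tp))
res$call
#> Class 4 (helix-beta-turn), orientation plus
#>   sequence matches: 3, 4
#>   note: sequence also matches class 3 but the backbone is helix-beta-turn
```

Run the full three-criterion check against a groove frame:

```r
mock <- build_mock_complex(tp)           # pockets + pseudo filter-lysine
fr   <- build_pocket_frame(mock)
nes_criteria_report(mock$peptide, fr)
#> NES criteria: ACTIVE NES
#>   [pass] anchors in 3-5 pockets: 5 pocket(s) occupied (P0,P1,P2,P3,P4), orientation plus
#>   [pass] conserved one-turn helix: turn at residues 8-11 (plus), psi -45.0, -25.0, -8.0, 130.0
#>   [pass] filter-lysine hydrogen bonding without clash: 2 hydrogen bond(s), niche3 motif; passes the filter-lysine check
```

The turn's ψ series rises from helical values into the strand range —
the progression that rotates the Φ3 carbonyl toward the filter lysine. An
all-helix peptide one turn too long, superposed into the same frame,
fails criterion 3 by steric clash with the lysine side chain, which is the
mechanism that rejects consensus-matching false positives.

A thin command-line wrapper is installed at `inst/scripts/nes-tool.R`
(`scan`, `synth` and `run` subcommands; `run` drives the full pipeline
from a YAML/JSON config and writes JSON + TSV report bundles).

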
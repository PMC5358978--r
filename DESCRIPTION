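Package: crmnes
Title: Sequence and Structure Analysis of CRM1 Nuclear Export Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint sequence/structure characterization of CRM1
    (exportin-1/XPO1) nuclear export signals (NESs). Implements the expanded
    eleven-class NES consensus taxonomy with a pattern scanner and
    amphipathic-helix annotation; backbone geometry primitives (phi/psi/omega
    dihedrals, Kabsch least-squares superposition); a dihedral- and
    hydrogen-bond-based secondary-structure and conformational-class caller
    that locates the conserved one-turn helix shared by all CRM1-bound NESs;
    groove-pocket (P0-P4) anchor assignment with displacement statistics;
    detection of the filter-lysine (HsCRM1 Lys568 / ScCRM1 Lys579) main-chain
    hydrogen bonds and niche motifs; a van der Waals steric-clash filter that
    separates active NESs from consensus-matching false positives; and a
    synthetic peptide-backbone builder (ideal-geometry chain extension from
    per-residue dihedral templates) plus sequence generators used for
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
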
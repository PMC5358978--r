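## Dihedral- and hydrogen-bond-based secondary-structure assignment.

# Dihedral windows. NA angles at chain termini are treated permissively
# (the defined angle alone decides).
.in_rng <- function(x, lo, hi, na_ok = TRUE) {
  ifelse(is.na(x), na_ok, x > lo & x < hi)
}

.helical_dihedral <- function(phi, psi) {
  .in_rng(phi, -110, -25) & .in_rng(psi, -80, 10)
}

.strand_dihedral <- function(phi, psi) {
  .in_rng(phi, -180, -45) & ifelse(is.na(psi), !is.na(phi) & phi < -45,
                                   psi >= 85 & psi <= 180)
}

#' Assign per-residue secondary structure
#'
#' Labels each residue H (alpha-helix), G (3-10 helix), E (extended/strand),
#' T (type I beta-turn central residues) or L (loop) from backbone
#' dihedrals plus carbonyl hydrogen-bond geometry:
#' \itemize{
#' \item helical dihedrals: phi in (-100, -30) and psi in (-80, 10), in
#'   runs of >= 3 (shorter helical-dihedral runs are demoted to T/L); the
#'   psi window spans both the alpha (-47) and 3-10 (-26) canonical values
#'   with comparable margin;
#' \item helix type per run: 3-10 (G) when the run keeps i -> i+3 O...N
#'   carbonyl contacts (mean <= 3.5 Angstrom) but has lost the i -> i+4
#'   contacts that an alpha-helix retains (mean > 3.5 Angstrom); alpha (H)
#'   otherwise; with O atoms missing the run is labelled H and a warning
#'   flag is attached;
#' \item strand (E): psi in `[85, 180]` and phi < -45;
#' \item type I beta-turn (T): central residues i+1 (phi ~ -60, psi ~ -30)
#'   and i+2 (phi ~ -90, psi ~ 0), each within +/- 30 degrees, with
#'   CA(i)-CA(i+3) < 7 Angstrom; T overrides loop and isolated helical
#'   labels but never splits an established H/G run.
#' }
#'
#' @param d `nes_dihedrals` from [compute_dihedrals()].
#' @param p the `nes_peptide` the dihedrals came from.
#' @return character vector of labels with attribute `warnings`.
#' @export
assign_sse <- function(d, p) {
  n <- nrow(d)
  phi <- d$phi; psi <- d$psi
  lab <- rep("L", n)
  warnings <- character()
  hel <- .helical_dihedral(phi, psi)
  strand <- .strand_dihedral(phi, psi)
  # bridge single-residue window excursions flanked by helical residues
  # (unless the excursion is into the strand region)
  if (n >= 3L) for (i in 2:(n - 1L)) {
    if (!hel[i] && hel[i - 1L] && hel[i + 1L] && !strand[i]) hel[i] <- TRUE
  }
  # runs of helical dihedrals
  r <- rle(hel)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  Oc <- atom_coords(p, "O"); Nc <- atom_coords(p, "N")
  CAc <- atom_coords(p, "CA")
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    idx <- starts[k]:ends[k]
    if (length(idx) < 3L) next               # demoted below
    # terminal residues (one dihedral undefined) may extend a run but not
    # carry one: require 3 fully-defined helical residues
    if (sum(!is.na(phi[idx]) & !is.na(psi[idx])) < 3L) next
    if (anyNA(Oc[idx, 1])) {
      warnings <- c(warnings, sprintf(
        "run %d-%d: missing O atoms, helix type defaulted to H",
        idx[1], idx[length(idx)]))
      lab[idx] <- "H"
      next
    }
    # helix type from carbonyl O(i)...N(i+k) contacts, both partners
    # inside the run (contacts into flanking segments are not helix-typed).
    # alpha helices retain short i -> i+4 contacts (~3.0 A) while 3-10
    # helices lose them (~4.9 A); the run-mean psi (alpha -47, 3-10 -26)
    # must agree before a run is typed 3-10. Runs ending in the conserved
    # turn unwind toward the strand, so the last two residues of long
    # runs are excluded from typing.
    core <- if (length(idx) >= 5L) idx[seq_len(length(idx) - 2L)] else idx
    d3 <- d4 <- numeric()
    for (i in core) {
      if ((i + 3L) %in% core) d3 <- c(d3, .vnorm(Oc[i, ] - Nc[i + 3L, ]))
      if ((i + 4L) %in% core) d4 <- c(d4, .vnorm(Oc[i, ] - Nc[i + 4L, ]))
    }
    psi_run <- mean(psi[core], na.rm = TRUE)
    psi_votes_g <- abs(psi_run + 26) < abs(psi_run + 47)
    is_g <- length(d3) > 0 && mean(d3) <= 3.5 && psi_votes_g &&
      (length(d4) == 0 || mean(d4) - mean(d3) >= 1.0)
    lab[idx] <- if (is_g) "G" else "H"
  }
  # strands
  str_ok <- strand & lab == "L"
  lab[str_ok] <- "E"
  # type I beta-turns
  for (i in seq_len(max(0L, n - 3L))) {
    j1 <- i + 1L; j2 <- i + 2L
    ok1 <- .in_rng(phi[j1], -90, -30) && .in_rng(psi[j1], -60, 0)
    ok2 <- .in_rng(phi[j2], -120, -60) && .in_rng(psi[j2], -30, 30)
    if (!(ok1 && ok2)) next
    if (.vnorm(CAc[i, ] - CAc[i + 3L, ]) >= 7) next
    for (j in c(j1, j2)) {
      if (!lab[j] %in% c("H", "G", "E")) lab[j] <- "T"
    }
  }
  attr(lab, "warnings") <- warnings
  lab
}
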
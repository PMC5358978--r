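# Independent oracles and shared fixtures for the test suite.

# Brute-force pattern enumerator, independent of the regex scanner:
# vectorized logical-AND over anchor offset masks.
bf_scan <- function(seq, classes = NULL) {
  if (is.null(classes)) classes <- nes_classes()$class
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  is_phi <- chars %in% PHI_RESIDUES
  out <- list()
  for (cls in classes) {
    gaps <- nes_class_gaps(cls)[[1]]
    offs <- cumsum(c(0L, gaps + 1L))
    w <- max(offs)
    if (n < w + 1L) next
    starts0 <- 0:(n - w - 1L)
    ok <- rep(TRUE, length(starts0))
    for (o in offs) ok <- ok & is_phi[starts0 + o + 1L]
    for (st in starts0[ok]) {
      out[[length(out) + 1L]] <- data.frame(
        class = cls, start = st,
        anchors = paste(st + offs, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(class = character(), start = integer(),
                      anchors = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, match(res$class, nes_classes()$class)), ,
      drop = FALSE]
}

# Independent torsion formulation: signed angle between the two bond-plane
# normals (acos magnitude, sign from the scalar triple product).
torsion_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cx <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cx(b1, b2); n2 <- cx(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  # IUPAC sign: negative when n1 rotates toward n2 right-handedly about b2
  if (sum(cx(n1, n2) * b2) < 0) ang <- -ang
  ang
}

random_aa_seq <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}

# Compare two match tables on the invariant columns.
match_key <- function(m) {
  if (nrow(m) == 0L) return(character())
  sort(paste(m$class, m$start, m$anchors))
}

# An Hxk2-like all-helix decoy superposed onto a mock frame's reference
# peptide by its shared helix start.
make_plus_decoy <- function(mock, n = 15) {
  decoy <- build_backbone(backbone_spec(strrep("A", n), -57, -47))
  tr <- superpose(atom_coords(decoy, "CA")[1:5, ],
                  atom_coords(mock$peptide, "CA")[1:5, ])
  transform_peptide(decoy, tr)
}

# A DEAF1-like decoy: helix over-extended at the N-terminal (strand) end
# of a minus-orientation mock.
make_minus_decoy <- function(mock, helix_start = 7) {
  decoy <- build_backbone(backbone_spec(strrep("A", 14), -57, -47))
  n <- nrow(residue_table(mock$peptide))
  ref_idx <- helix_start:min(helix_start + 4, n)
  dec_idx <- seq(5, length.out = length(ref_idx))
  tr <- superpose(atom_coords(decoy, "CA")[dec_idx, ],
                  atom_coords(mock$peptide, "CA")[ref_idx, ])
  transform_peptide(decoy, tr)
}
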
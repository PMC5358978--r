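## Peptide/complex containers and structure file I/O (PDB via bio3d, plus a
## minimal mmCIF atom_site reader).

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1TO3 <- stats::setNames(names(AA3TO1), AA3TO1)
PHI_RESNAMES <- c("LEU", "VAL", "ILE", "PHE", "MET")
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct a peptide structure
#'
#' Ordered residues with backbone (and optionally side-chain) atom
#' coordinates. Residues are sorted by (author number, insertion code);
#' each residue must carry at least N, CA and C (O is required by the
#' hydrogen-bond analysis and is checked there, not here).
#'
#' @param chain_id chain identifier.
#' @param atoms data frame with columns `resno` (integer author number),
#'   `ins` (insertion code, "" when none), `resname` (3-letter), `atom`
#'   (atom name), `x`, `y`, `z` (Angstrom).
#' @return object of class `nes_peptide`.
#' @export
peptide_structure <- function(chain_id, atoms) {
  need <- c("resno", "ins", "resname", "atom", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in chain ", chain_id)
  atoms$ins[is.na(atoms$ins)] <- ""
  atoms <- atoms[order(atoms$resno, atoms$ins), , drop = FALSE]
  rownames(atoms) <- NULL
  key <- paste(atoms$resno, atoms$ins)
  res_keys <- unique(key)
  bad <- character()
  for (rk in res_keys) {
    an <- atoms$atom[key == rk]
    if (!all(c("N", "CA", "C") %in% an)) bad <- c(bad, rk)
  }
  if (length(bad))
    stop("chain ", chain_id, ": residue(s) missing backbone atoms (N/CA/C): ",
         paste(trimws(bad), collapse = ", "))
  structure(list(chain_id = chain_id, atoms = atoms), class = "nes_peptide")
}

#' @export
print.nes_peptide <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("nes_peptide chain %s: %d residues (%s...%s), %d atoms\n",
              x$chain_id, nrow(rt), rt$resname[1], rt$resname[nrow(rt)],
              nrow(x$atoms)))
  invisible(x)
}

#' Residue table of a peptide
#'
#' @param p `nes_peptide`.
#' @return data frame: `resno`, `ins`, `resname`, `seq1` (one-letter, "X"
#'   for non-standard residues), in chain order.
#' @export
residue_table <- function(p) {
  a <- p$atoms
  key <- !duplicated(paste(a$resno, a$ins))
  rt <- a[key, c("resno", "ins", "resname")]
  rt$seq1 <- unname(ifelse(rt$resname %in% names(AA3TO1),
                           AA3TO1[rt$resname], "X"))
  rownames(rt) <- NULL
  rt
}

#' @rdname residue_table
#' @export
peptide_sequence <- function(p) paste(residue_table(p)$seq1, collapse = "")

#' Coordinates of one named atom per residue
#'
#' @param p `nes_peptide`.
#' @param atom atom name (e.g. "CA").
#' @return n_res x 3 matrix; rows of residues lacking the atom are `NA`.
#' @export
atom_coords <- function(p, atom = "CA") {
  rt <- residue_table(p)
  a <- p$atoms[p$atoms$atom == atom, , drop = FALSE]
  m <- matrix(NA_real_, nrow(rt), 3,
              dimnames = list(paste0(rt$resno, rt$ins), c("x", "y", "z")))
  idx <- match(paste(a$resno, a$ins), paste(rt$resno, rt$ins))
  m[idx[!is.na(idx)], ] <- as.matrix(a[!is.na(idx), c("x", "y", "z")])
  m
}

# All atom coordinates of residue i (chain order index); named matrix.
residue_atoms <- function(p, i) {
  rt <- residue_table(p)
  sel <- p$atoms$resno == rt$resno[i] & p$atoms$ins == rt$ins[i]
  a <- p$atoms[sel, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$atom
  m
}

#' Apply a rigid transform to a peptide
#'
#' @param p `nes_peptide`.
#' @param transform `nes_superposition`.
#' @return transformed `nes_peptide`.
#' @export
transform_peptide <- function(p, transform) {
  xyz <- apply_transform(as.matrix(p$atoms[, c("x", "y", "z")]), transform)
  p$atoms$x <- xyz[, 1]; p$atoms$y <- xyz[, 2]; p$atoms$z <- xyz[, 3]
  p
}

#' Detect chain breaks
#'
#' A break is flagged between consecutive residues whose C(i)-N(i+1)
#' distance exceeds the peptide-bond threshold (2.0 Angstrom).
#'
#' @param p `nes_peptide`.
#' @param threshold distance cutoff in Angstrom.
#' @return integer vector: indices i such that the bond i -> i+1 is broken.
#' @export
chain_breaks <- function(p, threshold = 2.0) {
  Cc <- atom_coords(p, "C"); Nc <- atom_coords(p, "N")
  n <- nrow(Cc)
  if (n < 2L) return(integer())
  d <- sqrt(rowSums((Cc[-n, , drop = FALSE] - Nc[-1, , drop = FALSE])^2))
  unname(which(is.na(d) | d > threshold))
}

#' Backbone dihedral series
#'
#' Computes per-residue phi (C-, N, CA, C), psi (N, CA, C, N+) and omega
#' (CA, C, N+, CA+) torsions in degrees. phi is undefined (NA) for the
#' first residue and psi/omega for the last; dihedrals spanning a detected
#' chain break are set to NA rather than computed across the gap.
#'
#' @param p `nes_peptide`.
#' @return object of class `nes_dihedrals`: data frame `resno`, `ins`,
#'   `resname`, `phi`, `psi`, `omega`.
#' @export
compute_dihedrals <- function(p) {
  rt <- residue_table(p)
  n <- nrow(rt)
  Nc <- atom_coords(p, "N"); CAc <- atom_coords(p, "CA"); Cc <- atom_coords(p, "C")
  br <- chain_breaks(p)
  broken <- function(i, j) any(br %in% seq(i, j - 1L))   # bond between i..j
  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1L && !broken(i - 1L, i))
      phi[i] <- torsion_angle(Cc[i - 1L, ], Nc[i, ], CAc[i, ], Cc[i, ])
    if (i < n && !broken(i, i + 1L)) {
      psi[i] <- torsion_angle(Nc[i, ], CAc[i, ], Cc[i, ], Nc[i + 1L, ])
      omega[i] <- torsion_angle(CAc[i, ], Cc[i, ], Nc[i + 1L, ], CAc[i + 1L, ])
    }
  }
  structure(data.frame(resno = rt$resno, ins = rt$ins, resname = rt$resname,
                       phi = phi, psi = psi, omega = omega,
                       stringsAsFactors = FALSE),
            class = c("nes_dihedrals", "data.frame"))
}

# ---------------------------------------------------------------------------
# File readers

.chains_from_atom_table <- function(at, source) {
  # at: data.frame chain, resno, ins, resname, atom, alt, occ, x, y, z, hetero
  at <- at[!at$hetero & at$resname != "HOH", , drop = FALSE]
  # altloc: keep highest occupancy, ties resolved toward altloc 'A'/''
  if (any(nzchar(at$alt))) {
    key <- paste(at$chain, at$resno, at$ins, at$atom)
    ord <- order(key, -at$occ, at$alt != "", at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$ins, at$atom)), ,
             drop = FALSE]
  }
  chains <- list()
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, c("resno", "ins", "resname", "atom", "x", "y", "z")]
    chains[[ch]] <- peptide_structure(ch, sub)
  }
  structure(list(chains = chains, source = source), class = "nes_complex")
}

#' Load a complex structure from PDB or mmCIF
#'
#' Reads every polymer chain into a [peptide_structure()]; heteroatoms and
#' waters are excluded and alternate locations are resolved to the highest
#' occupancy (then altloc 'A'). PDB parsing is delegated to
#' \pkg{bio3d}; a minimal `atom_site` loop reader handles mmCIF.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return object of class `nes_complex`: list with `chains` (named list of
#'   `nes_peptide`) and `source`. Chains with residues missing backbone
#'   atoms raise a structured error naming the chain and residues.
#' @export
load_complex <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") {
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                    error = function(e) stop("unparseable PDB file ", path,
                                             ": ", conditionMessage(e)))
    a <- pdb$atom
    at <- data.frame(chain = ifelse(is.na(a$chain), "A", a$chain),
                     resno = a$resno,
                     ins = ifelse(is.na(a$insert), "", a$insert),
                     resname = a$resid, atom = a$elety,
                     alt = ifelse(is.na(a$alt), "", a$alt),
                     occ = ifelse(is.na(a$o), 1, a$o),
                     x = a$x, y = a$y, z = a$z,
                     hetero = a$type != "ATOM", stringsAsFactors = FALSE)
  } else {
    at <- .read_mmcif_atoms(path)
  }
  .chains_from_atom_table(at, source = path)
}

# Minimal mmCIF reader: parses the atom_site loop only. Values are
# whitespace-delimited; quoted values with embedded spaces are not expected
# in atom_site records.
.read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- grep("^\\s*loop_", lines)
  if (!length(loop_starts)) stop("unparseable mmCIF file ", path,
                                 ": no loop_ blocks")
  for (ls in loop_starts) {
    i <- ls + 1L
    fields <- character()
    while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
      fields <- c(fields, trimws(lines[i])); i <- i + 1L
    }
    if (!any(grepl("^_atom_site\\.", fields))) next
    fields <- sub("^_atom_site\\.", "", fields)
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || grepl("^(loop_|#|_|data_)", ln)) break
      rows[[length(rows) + 1L]] <- scan(text = ln, what = character(),
                                        quiet = TRUE)
      i <- i + 1L
    }
    tab <- do.call(rbind, rows)
    colnames(tab) <- fields
    need <- c("group_PDB", "auth_asym_id", "auth_seq_id", "auth_comp_id",
              "label_atom_id", "Cartn_x", "Cartn_y", "Cartn_z")
    miss <- setdiff(need, fields)
    if (length(miss)) stop("mmCIF atom_site lacks: ", paste(miss, collapse = ", "))
    g <- function(f, default = "") if (f %in% fields) tab[, f] else
      rep(default, nrow(tab))
    ins <- g("pdbx_PDB_ins_code", "?")
    alt <- g("label_alt_id", ".")
    occ <- suppressWarnings(as.numeric(g("occupancy", "1")))
    return(data.frame(
      chain = tab[, "auth_asym_id"],
      resno = as.integer(tab[, "auth_seq_id"]),
      ins = ifelse(ins %in% c("?", "."), "", ins),
      resname = tab[, "auth_comp_id"],
      atom = gsub('"', "", tab[, "label_atom_id"]),
      alt = ifelse(alt %in% c("?", "."), "", alt),
      occ = ifelse(is.na(occ), 1, occ),
      x = as.numeric(tab[, "Cartn_x"]),
      y = as.numeric(tab[, "Cartn_y"]),
      z = as.numeric(tab[, "Cartn_z"]),
      hetero = tab[, "group_PDB"] != "ATOM", stringsAsFactors = FALSE))
  }
  stop("unparseable mmCIF file ", path, ": no atom_site loop")
}

#' Write structures to a PDB file
#'
#' Fixed-column PDB writer for peptides, complexes and mock complexes
#' (pocket markers and the pseudo-lysine of a mock complex are emitted as
#' HETATM records). Coordinates are written at the format's 3-decimal
#' precision.
#'
#' @param x `nes_peptide`, `nes_complex` or `nes_mock_complex`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  lines <- c()
  serial <- 0L
  fmt <- function(rec, serial, atom, resname, chain, resno, ins, xyz) {
    el <- substr(atom, 1, 1)
    aname <- if (nchar(atom) < 4L) sprintf(" %-3s", atom) else atom
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial, aname, "", resname, chain, resno, ins,
            xyz[1], xyz[2], xyz[3], 1, 0, el)
  }
  emit_chain <- function(p, rec = "ATOM") {
    a <- p$atoms
    for (i in seq_len(nrow(a))) {
      serial <<- serial + 1L
      ins <- if (nzchar(a$ins[i])) a$ins[i] else " "
      lines <<- c(lines, fmt(rec, serial, a$atom[i], a$resname[i],
                             substr(p$chain_id, 1, 1), a$resno[i], ins,
                             c(a$x[i], a$y[i], a$z[i])))
    }
    lines <<- c(lines, "TER")
  }
  if (inherits(x, "nes_peptide")) {
    emit_chain(x)
  } else if (inherits(x, "nes_complex")) {
    for (p in x$chains) emit_chain(p)
  } else if (inherits(x, "nes_mock_complex")) {
    emit_chain(x$peptide)
    for (i in seq_len(nrow(x$pockets))) {
      serial <- serial + 1L
      lines <- c(lines, fmt("HETATM", serial, "C", "PKT", "P", i, " ",
                            x$pockets[i, ]))
    }
    for (an in rownames(x$lysine$atoms)) {
      serial <- serial + 1L
      lines <- c(lines, fmt("HETATM", serial, an, "LYS", "K",
                            x$lysine$resno, " ", x$lysine$atoms[an, ]))
    }
  } else stop("cannot write object of class ", paste(class(x), collapse = "/"))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Map CRM1 author numbering between organisms
#'
#' The yeast (Sc) and human/mouse (Hs/Mm) CRM1 groove residues differ by a
#' constant offset in the HEAT 11-12 region: Sc Lys579 corresponds to
#' Hs/Mm Lys568 (offset -11), and Sc Glu582 to Hs Glu571. The mapping is a
#' two-point anchored offset applied only within the groove helices;
#' residues outside the mapped region are returned unchanged with a
#' warning. The table is extensible for other regions or organisms.
#'
#' @param resno author residue number(s).
#' @param from,to `"Sc"` or `"Hs"` (`"Mm"` is an alias of `"Hs"`).
#' @param table mapping table: data frame with `from_org`, `to_org`,
#'   `start`, `end`, `offset`.
#' @return mapped residue number(s).
#' @examples
#' map_crm1_numbering(579, "Sc", "Hs")   # 568
#' map_crm1_numbering(568, "Hs", "Sc")   # 579
#' @export
map_crm1_numbering <- function(resno, from = c("Sc", "Hs", "Mm"),
                               to = c("Hs", "Sc", "Mm"),
                               table = crm1_numbering_table()) {
  from <- match.arg(from); to <- match.arg(to)
  if (from == "Mm") from <- "Hs"
  if (to == "Mm") to <- "Hs"
  if (from == to) return(resno)
  hit <- table[table$from_org == from & table$to_org == to, , drop = FALSE]
  out <- resno
  mapped <- rep(FALSE, length(resno))
  for (i in seq_len(nrow(hit))) {
    in_rng <- resno >= hit$start[i] & resno <= hit$end[i]
    out[in_rng] <- resno[in_rng] + hit$offset[i]
    mapped <- mapped | in_rng
  }
  if (!all(mapped))
    warning("residue(s) outside the mapped groove region returned unchanged: ",
            paste(resno[!mapped], collapse = ", "))
  out
}

#' @rdname map_crm1_numbering
#' @export
crm1_numbering_table <- function() {
  # HEAT 11-12 groove helices; anchored at Sc Lys579 <-> Hs Lys568.
  data.frame(from_org = c("Sc", "Hs"), to_org = c("Hs", "Sc"),
             start = c(510, 499), end = c(650, 639),
             offset = c(-11L, 11L), stringsAsFactors = FALSE)
}
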
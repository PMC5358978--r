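#' Hydrophobic anchor residues
#'
#' The five residues accepted at NES anchor (Phi) positions: Leu, Val, Ile,
#' Phe and Met. The set is fixed; no extended hydrophobics are admitted.
#'
#' @format Character vector of one-letter codes.
#' @export
PHI_RESIDUES <- c("L", "V", "I", "F", "M")

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Library order used for sorting and tie-breaking (lower ordinal wins).
.CLASS_ORDER <- c("1a", "1b", "1c", "1d", "2", "3", "4",
                  "1a-R", "1b-R", "1c-R", "1d-R")

.CLASS_GAPS <- list(
  "1a"   = c(3L, 2L, 1L),
  "1b"   = c(2L, 2L, 1L),
  "1c"   = c(3L, 3L, 1L),
  "1d"   = c(2L, 3L, 1L),
  "2"    = c(1L, 2L, 1L),
  "3"    = c(2L, 3L, 2L),
  "4"    = c(2L, 3L, 2L, 3L),
  "1a-R" = c(1L, 2L, 3L),
  "1b-R" = c(1L, 2L, 2L),
  "1c-R" = c(1L, 3L, 3L),
  "1d-R" = c(1L, 3L, 2L)
)

#' The eleven-class NES consensus pattern library
#'
#' Returns the full library of NES consensus classes: the forward classes
#' 1a, 1b, 1c, 1d, 2, 3 and 4, and the reversed (minus-orientation) variants
#' 1a-R to 1d-R. Each pattern is an ordered list of spacer counts ("gaps",
#' the number of X residues between consecutive Phi anchors); the number of
#' anchors is `length(gaps) + 1`. A reversed class carries the forward
#' class's gaps read backwards. A class is flagged symmetric when its gap
#' vector is palindromic, in which case the pattern reads identically in the
#' (+) and (-) polypeptide directions and no separate reversed variant is
#' listed (classes 2 and 3; class 4, which also has no reversed variant in
#' the library, is not palindromic).
#'
#' @param classes optional character vector restricting the returned classes.
#' @return A data frame with one row per class: `class`, `gaps` (list
#'   column of integer vectors), `n_anchors`, `reversed`, `symmetric`,
#'   `forward_class` (the un-reversed label), and `pattern` (human-readable
#'   PhiX notation).
#' @examples
#' nes_classes()
#' nes_classes("3")$gaps[[1]]
#' @export
nes_classes <- function(classes = NULL) {
  lab <- names(.CLASS_GAPS)
  df <- data.frame(class = lab, stringsAsFactors = FALSE)
  df$gaps <- unname(.CLASS_GAPS)
  df$n_anchors <- vapply(df$gaps, length, 1L) + 1L
  df$reversed <- grepl("-R$", lab)
  df$symmetric <- vapply(df$gaps, function(g) identical(g, rev(g)), TRUE)
  df$forward_class <- sub("-R$", "", lab)
  df$pattern <- vapply(df$gaps, function(g) {
    paste0("Phi", paste0(vapply(g, function(k) strrep("X", k), ""),
                         "Phi", collapse = ""))
  }, "")
  if (!is.null(classes)) {
    bad <- setdiff(classes, lab)
    if (length(bad))
      stop("unknown NES class(es): ", paste(bad, collapse = ", "))
    df <- df[match(classes, df$class), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' @rdname nes_classes
#' @export
nes_class_gaps <- function(classes = NULL) {
  df <- nes_classes(classes)
  stats::setNames(df$gaps, df$class)
}

# Validate and normalize an amino-acid string. Errors name the first
# offending position (1-based). '*' stop characters are rejected.
.check_seq <- function(seq) {
  if (length(seq) != 1L || !is.character(seq))
    stop("`seq` must be a single character string")
  s <- toupper(seq)
  ok <- strsplit(s, "")[[1]] %in% AA20
  if (!all(ok)) {
    pos <- which(!ok)[1]
    stop(sprintf("non-standard residue letter '%s' at position %d",
                 substr(s, pos, pos), pos))
  }
  s
}

.empty_matches <- function() {
  data.frame(sequence_id = character(), class = character(),
             start = integer(), start_1based = integer(),
             end_1based = integer(), anchors = character(),
             anchors_1based = character(), anchor_letters = character(),
             n_anchors = integer(), amphipathic = logical(),
             alt_labeling = character(), stringsAsFactors = FALSE)
}

#' Scan a protein sequence for NES consensus matches
#'
#' Slides every requested class pattern along the sequence and reports all
#' windows whose anchor slots are Phi letters (L/V/I/F/M). Matching is
#' regular-expression based with lookahead so that overlapping and nested
#' windows are all reported when `allow_overlaps = TRUE` (the default).
#' With `allow_overlaps = FALSE` a greedy left-to-right selection is applied
#' per class, keeping the earliest-starting match and dropping any later
#' match whose window overlaps an accepted one.
#'
#' Coordinates are 0-based half-open internally (`start`, `anchors`);
#' 1-based author-style positions are emitted alongside (`start_1based`,
#' `anchors_1based`) because residue numbers are cited that way in the
#' structural literature.
#'
#' Class 3 matches carry an alternative structural labeling in
#' `alt_labeling`: all-helix class 3 peptides bind with the register
#' Phi0-XX-Phi1-XXX-Phi2-XX-Phi3 leaving the P4 pocket empty, so the same
#' four anchors can be read as Phi0..Phi3 instead of Phi1..Phi4. The flag is
#' marked "pending structure evidence" because only a bound structure can
#' decide the register.
#'
#' @param seq amino-acid string (standard 20 letters, case-insensitive).
#' @param classes character vector of class labels (see [nes_classes()]);
#'   defaults to the full eleven-class library.
#' @param allow_overlaps report all overlapping matches (default `TRUE`).
#' @param sequence_id identifier copied into the output.
#' @return data frame of matches sorted by (start, class library order):
#'   columns `sequence_id`, `class`, `start`, `start_1based`, `end_1based`,
#'   `anchors` (comma-joined 0-based), `anchors_1based`, `anchor_letters`,
#'   `n_anchors`, `amphipathic`, `alt_labeling`. An empty sequence gives an
#'   empty frame; non-standard letters are an error naming the position.
#' @examples
#' scan_nes("SSLQELVQQFEALPGDLV", classes = c("3", "4"))
#' @export
scan_nes <- function(seq, classes = NULL, allow_overlaps = TRUE,
                     sequence_id = "seq") {
  if (is.null(classes)) classes <- .CLASS_ORDER
  lib <- nes_classes(classes)
  if (nrow(lib) == 0L) stop("`classes` must be non-empty")
  if (!nzchar(seq)) return(.empty_matches())
  s <- .check_seq(seq)
  chars <- strsplit(s, "")[[1]]
  out <- list()
  for (k in seq_len(nrow(lib))) {
    gaps <- lib$gaps[[k]]
    cls <- lib$class[k]
    offs <- cumsum(c(0L, gaps + 1L))
    phicls <- paste0("[", paste(PHI_RESIDUES, collapse = ""), "]")
    rx <- paste0("(?=(", paste0(vapply(gaps, function(g)
      paste0(phicls, sprintf(".{%d}", g)), ""), collapse = ""), phicls, "))")
    hits <- gregexpr(rx, s, perl = TRUE)[[1]]
    if (hits[1] == -1L) next
    starts <- as.integer(hits) - 1L            # 0-based
    if (!allow_overlaps && length(starts) > 1L) {
      keep <- logical(length(starts))
      last_end <- -1L
      w <- max(offs)
      for (i in seq_along(starts)) {
        if (starts[i] > last_end) {
          keep[i] <- TRUE
          last_end <- starts[i] + w
        }
      }
      starts <- starts[keep]
    }
    for (st in starts) {
      anch <- st + offs
      out[[length(out) + 1L]] <- data.frame(
        sequence_id = sequence_id, class = cls, start = st,
        start_1based = st + 1L, end_1based = st + max(offs) + 1L,
        anchors = paste(anch, collapse = ","),
        anchors_1based = paste(anch + 1L, collapse = ","),
        anchor_letters = paste(chars[anch + 1L], collapse = ""),
        n_anchors = length(anch),
        amphipathic = is_amphipathic(chars, anch),
        alt_labeling = if (cls == "3")
          "Phi0,Phi1,Phi2,Phi3; P4 unused (pending structure evidence)"
        else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_matches())
  res <- do.call(rbind, out)
  res <- res[order(res$start, match(res$class, .CLASS_ORDER)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan reversed-pattern classes via sequence reversal
#'
#' Matches for the minus-orientation classes are, by definition, the mirror
#' of the forward-pattern matches on the reversed sequence. This scanner
#' reverses `seq`, scans the forward classes, and mirrors the coordinates
#' back. For the palindromic classes (2, 3) the result is identical to a
#' forward scan; for 1a-1d the returned class labels carry the "-R" suffix.
#'
#' @inheritParams scan_nes
#' @param forward_classes forward class labels to reverse (default
#'   `c("1a","1b","1c","1d")`; the palindromic classes 2 and 3 are accepted
#'   and return themselves; class 4, which has no reversed variant in the
#'   library, is rejected).
#' @return data frame in the same shape as [scan_nes()].
#' @export
scan_nes_reverse <- function(seq, forward_classes = c("1a", "1b", "1c", "1d"),
                             allow_overlaps = TRUE, sequence_id = "seq") {
  if (any(grepl("-R$", forward_classes)))
    stop("`forward_classes` must be forward labels (no -R suffix)")
  if ("4" %in% forward_classes)
    stop("class 4 has no reversed variant in the pattern library")
  if (!nzchar(seq)) return(.empty_matches())
  s <- .check_seq(seq)
  n <- nchar(s)
  rs <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  m <- scan_nes(rs, classes = forward_classes,
                allow_overlaps = allow_overlaps, sequence_id = sequence_id)
  if (nrow(m) == 0L) return(m)
  chars <- strsplit(s, "")[[1]]
  for (i in seq_len(nrow(m))) {
    anch <- as.integer(strsplit(m$anchors[i], ",")[[1]])
    anch <- sort(n - 1L - anch)
    m$start[i] <- anch[1]
    m$start_1based[i] <- anch[1] + 1L
    m$end_1based[i] <- anch[length(anch)] + 1L
    m$anchors[i] <- paste(anch, collapse = ",")
    m$anchors_1based[i] <- paste(anch + 1L, collapse = ",")
    m$anchor_letters[i] <- paste(chars[anch + 1L], collapse = "")
    m$amphipathic[i] <- is_amphipathic(chars, anch)
  }
  sym <- nes_classes()$class[nes_classes()$symmetric]
  m$class <- ifelse(m$class %in% sym, m$class, paste0(m$class, "-R"))
  m$alt_labeling <- ifelse(m$class == "3", m$alt_labeling, NA_character_)
  m <- m[order(m$start, match(m$class, .CLASS_ORDER)), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Amphipathic-helix annotation of a match window
#'
#' A match window is annotated amphipathic when some subset of the Phi
#' letters inside the window (the match anchors plus any additional Phi
#' residues between the first and last anchor) realizes one of the three
#' hydrophobic-face offset templates, relative to the subset's first
#' member: i, i+4, i+7; or i, i+3, i+7; or i, i+3, i+7, i+10. These are the
#' spacings that place all hydrophobics on one face of an alpha-helix.
#'
#' @param chars character vector of residues (or a single string).
#' @param anchors 0-based anchor positions of the match.
#' @return logical.
#' @examples
#' is_amphipathic(strsplit("LAALAAALAAL", "")[[1]], c(0, 3, 7, 10))
#' @export
is_amphipathic <- function(chars, anchors) {
  if (length(chars) == 1L && nchar(chars[1]) > 1L)
    chars <- strsplit(chars, "")[[1]]
  anchors <- sort(as.integer(anchors))
  if (length(anchors) < 3L) return(FALSE)
  win <- seq(anchors[1], anchors[length(anchors)])
  phis <- win[chars[win + 1L] %in% PHI_RESIDUES]
  templates <- list(c(0L, 4L, 7L), c(0L, 3L, 7L), c(0L, 3L, 7L, 10L))
  for (i in phis) {
    for (tp in templates) {
      if (all((i + tp) %in% phis)) return(TRUE)
    }
  }
  FALSE
}

#' Reduce overlapping matches to one best match per locus
#'
#' Groups matches of one sequence into loci of mutually overlapping windows
#' and keeps a single representative per locus. Preference is lexicographic
#' and documented: more anchors first, then earlier start, then lower class
#' ordinal in the library order (1a, 1b, 1c, 1d, 2, 3, 4, 1a-R, ..., 1d-R).
#'
#' @param matches data frame from [scan_nes()].
#' @return reduced data frame, one row per locus.
#' @export
reduce_best_locus <- function(matches) {
  if (nrow(matches) == 0L) return(matches)
  out <- list()
  for (id in unique(matches$sequence_id)) {
    m <- matches[matches$sequence_id == id, , drop = FALSE]
    m <- m[order(m$start), , drop = FALSE]
    grp <- integer(nrow(m))
    g <- 0L; cur_end <- -1L
    for (i in seq_len(nrow(m))) {
      if (m$start[i] > cur_end) { g <- g + 1L; cur_end <- m$end_1based[i] - 1L }
      else cur_end <- max(cur_end, m$end_1based[i] - 1L)
      grp[i] <- g
    }
    for (gg in unique(grp)) {
      mm <- m[grp == gg, , drop = FALSE]
      ord <- order(-mm$n_anchors, mm$start, match(mm$class, .CLASS_ORDER))
      out[[length(out) + 1L]] <- mm[ord[1], , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map chain-order anchors of a match to Phi labels
#'
#' Forward (+) classes label anchors Phi1..Phi4 from N- to C-terminus
#' (Phi0..Phi4 for class 4, and for the structural reading of class 3);
#' reversed (-R) classes run Phi4..Phi1 along the chain because the peptide
#' threads the groove backwards.
#'
#' @param match one row of a [scan_nes()] result.
#' @param structural for class 3, use the structural register Phi0..Phi3
#'   (P4 unused) instead of the sequence register Phi1..Phi4.
#' @return named integer vector of 0-based chain positions, names
#'   `"phi0"`.. `"phi4"` as applicable.
#' @export
anchor_phi_labels <- function(match, structural = FALSE) {
  anch <- as.integer(strsplit(match$anchors, ",")[[1]])
  cls <- match$class
  k <- length(anch)
  if (grepl("-R$", cls)) {
    labs <- paste0("phi", seq(k, 1))
  } else if (cls == "4" || (cls == "3" && structural)) {
    labs <- paste0("phi", seq(0, k - 1))
  } else {
    labs <- paste0("phi", seq(1, k))
  }
  stats::setNames(anch, labs)
}
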
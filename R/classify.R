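## Conformational class calling: combine secondary structure, the conserved
## turn, anchors and sequence-pattern matches into a class call.

# Expected backbone shape per consensus class.
.CLASS_SHAPES <- c(
  "1a" = "helix-strand", "1c" = "helix-strand", "1d" = "helix-strand",
  "1b" = "310-strand", "2" = "loop", "3" = "all-helix",
  "4" = "helix-beta-turn",
  "1a-R" = "strand-helix", "1b-R" = "strand-helix",
  "1c-R" = "strand-helix", "1d-R" = "strand-helix")

#' Expected backbone shape of an NES class
#' @param class_label class label.
#' @return shape descriptor string.
#' @export
class_shape <- function(class_label) {
  unname(.CLASS_SHAPES[class_label])
}

# Infer the backbone shape descriptor from SSE labels and the turn.
.infer_shape <- function(sse, turn) {
  n <- length(sse)
  s0 <- turn$span[1]; s1 <- turn$span[4]
  pre <- if (s0 > 1L) sse[seq_len(s0 - 1L)] else character()
  post <- if (s1 < n) sse[(s1 + 1L):n] else character()
  helix_all <- sum(sse %in% c("H", "G"))
  if (turn$direction == "minus") {
    if (sum(pre == "E") >= 2L && sum(post %in% c("H", "G")) >= 1L ||
        (sum(pre == "E") >= 2L && helix_all >= 3L))
      return("strand-helix")
    return("strand-helix")  # a minus turn implies the mirrored architecture
  }
  # (+) direction
  t_post <- which(sse == "T"); t_post <- t_post[t_post > s1]
  if (length(t_post) >= 2L && any(t_post >= n - 4L) &&
      sum(sse[seq_len(max(1L, s0 - 1L))] %in% c("H", "G")) >= 2L)
    return("helix-beta-turn")
  n_E_tail <- sum(sse[seq(min(s1, n), n)] == "E")
  helix_pre <- sum(pre %in% c("H", "G"))
  loop_out <- sum(c(pre, post) == "L")
  n_out <- length(pre) + length(post)
  if (n_E_tail >= 2L && helix_pre >= 2L) {
    g_frac <- sum(sse == "G") / max(1L, helix_all)
    return(if (g_frac > 0.5) "310-strand" else "helix-strand")
  }
  if (n_out > 0L && loop_out / n_out >= 0.5) return("loop")
  if (helix_all / n >= 0.6 && sum(sse == "E") <= 1L) return("all-helix")
  if (n_E_tail >= 1L && helix_pre >= 2L) {
    g_frac <- sum(sse == "G") / max(1L, helix_all)
    return(if (g_frac > 0.5) "310-strand" else "helix-strand")
  }
  if (loop_out / max(1L, n_out) >= 0.4) return("loop")
  "all-helix"
}

#' Call the conformational class of a peptide
#'
#' Combines the secondary-structure labelling, the located conserved turn,
#' anchor information and (optionally) sequence-pattern matches into a
#' class call. The decision table follows the observed architectures:
#' alpha-helix then strand is the class 1a/1c/1d family (disambiguated by
#' anchor spacing), a 3-10 helix then strand is class 1b, loop-dominant
#' with only the conserved turn is class 2, all-helix (the chain ends or
#' exits the groove, P4 or P0 empty) is class 3, helix plus a type I
#' beta-turn reaching Phi4 is class 4, and strand-then-helix architectures
#' with a minus turn are the 1-R family. When sequence matches are
#' supplied the call is restricted to classes the sequence can support,
#' and a sequence/structure disagreement (e.g. a class-1b-matching
#' sequence binding with class-1a anchors) is reported in the notes, both
#' readings retained.
#'
#' @param sse labels from [assign_sse()].
#' @param turn `nes_turn` or `NULL` (no turn: the peptide is called
#'   not NES-like and the failed requirement is listed).
#' @param matches optional [scan_nes()] result for the peptide sequence.
#' @param anchor_map optional `nes_anchor_map`; pocket-order evidence
#'   dominates the orientation call when present.
#' @return object of class `nes_class_call`: list `class`, `shape`,
#'   `orientation`, `sequence_classes`, `notes`, `nes_like`.
#' @export
call_class <- function(sse, turn, matches = NULL, anchor_map = NULL) {
  seq_classes <- if (!is.null(matches) && nrow(matches)) unique(matches$class)
    else character()
  if (is.null(turn)) {
    return(structure(list(
      class = NA_character_, shape = NA_character_,
      orientation = "ambiguous", sequence_classes = seq_classes,
      notes = "no conserved one-turn helix (NES requirement 2 failed)",
      nes_like = FALSE), class = "nes_class_call"))
  }
  shape <- .infer_shape(sse, turn)
  orientation <- turn$direction
  notes <- character()
  if (!is.null(anchor_map) && !is.null(anchor_map$orientation) &&
      anchor_map$orientation %in% c("plus", "minus")) {
    if (anchor_map$orientation != orientation) {
      notes <- c(notes, sprintf(
        "pocket-order orientation (%s) overrides turn reading (%s)",
        anchor_map$orientation, orientation))
      orientation <- anchor_map$orientation
    }
  }
  candidates <- names(.CLASS_SHAPES)[.CLASS_SHAPES == shape]
  cls <- NA_character_
  if (length(seq_classes)) {
    hit <- intersect(seq_classes, candidates)
    if (length(hit)) {
      # prefer more anchors (class 4 over its embedded class 3), then
      # library order
      na <- vapply(hit, function(h)
        max(matches$n_anchors[matches$class == h]), 1)
      hit <- hit[order(-na, match(hit, names(.CLASS_SHAPES)))]
      cls <- hit[1]
      dis <- setdiff(seq_classes, candidates)
      if (length(dis))
        notes <- c(notes, sprintf(
          "sequence also matches class %s but the backbone is %s",
          paste(dis, collapse = "/"), shape))
    } else {
      cls <- candidates[1]
      notes <- c(notes, sprintf(
        "structural call %s disagrees with sequence match(es) %s; both reported",
        cls, paste(seq_classes, collapse = "/")))
    }
  } else {
    cls <- candidates[1]
    if (length(candidates) > 1L)
      notes <- c(notes, sprintf(
        "anchor spacing unknown; %s family reported as %s",
        shape, cls))
  }
  if (shape == "all-helix")
    notes <- c(notes, "structural register Phi0..Phi3; P4 (or P0) empty")
  structure(list(class = cls, shape = shape, orientation = orientation,
                 sequence_classes = seq_classes, notes = notes,
                 nes_like = TRUE),
            class = "nes_class_call")
}

#' @export
print.nes_class_call <- function(x, ...) {
  if (!x$nes_like) {
    cat("Not NES-like:", x$notes, "\n")
  } else {
    cat(sprintf("Class %s (%s), orientation %s\n", x$class, x$shape,
                x$orientation))
    if (length(x$sequence_classes))
      cat("  sequence matches:", paste(x$sequence_classes, collapse = ", "),
          "\n")
    for (nt in x$notes) cat("  note:", nt, "\n")
  }
  invisible(x)
}

#' One-call structural classification of a peptide
#'
#' Convenience wrapper: computes dihedrals, secondary structure, locates
#' the conserved turn from the best sequence match and calls the class.
#'
#' @param p `nes_peptide`.
#' @param classes pattern classes to scan the sequence with.
#' @return list with `dihedrals`, `sse`, `matches`, `turn`, `call`.
#' @export
classify_peptide <- function(p, classes = NULL) {
  d <- compute_dihedrals(p)
  sse <- assign_sse(d, p)
  seq <- peptide_sequence(p)
  matches <- if (all(strsplit(seq, "")[[1]] %in% AA20))
    scan_nes(seq, classes = classes, sequence_id = p$chain_id)
  else .empty_matches()
  turn <- NULL
  if (nrow(matches)) {
    # try matches in preference order: more anchors, then library order
    ord <- order(-matches$n_anchors, match(matches$class, .CLASS_ORDER))
    for (i in ord) {
      m <- matches[i, , drop = FALSE]
      regs <- list(anchor_phi_labels(m) + 1L)
      if (m$class == "3")
        regs <- c(regs, list(anchor_phi_labels(m, structural = TRUE) + 1L))
      for (reg in regs) {
        if (!all(c("phi2", "phi3") %in% names(reg))) next
        turn <- find_conserved_turn(d, reg)
        if (!is.null(turn)) break
      }
      if (!is.null(turn)) break
    }
  }
  if (is.null(turn)) {
    # last resort: slide over all Phi pairs at spacing 3-4
    rt <- residue_table(p)
    phis <- which(rt$resname %in% PHI_RESNAMES)
    pairs <- expand.grid(i = phis, j = phis)
    pairs <- pairs[pairs$j - pairs$i %in% c(3L, 4L), , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      turn <- find_conserved_turn(d, c(phi2 = i, phi3 = j))
      if (is.null(turn))
        turn <- find_conserved_turn(d, c(phi2 = j, phi3 = i))
      if (!is.null(turn)) break
    }
  }
  call <- call_class(sse, turn, matches = matches)
  list(dihedrals = d, sse = sse, matches = matches, turn = turn, call = call)
}
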
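## The conserved one-turn helix element shared by all CRM1-bound NESs.

# psi windows used by the turn detector. The helical-face window is wider
# than the strict helix window of assign_sse() because the turn's psi
# values drift upward toward the strand transition (printed exemplars
# reach -1.3 and +16.5 degrees).
.TURN_PSI_HELICAL <- c(-80, 40)
.TURN_PSI_STRAND <- c(85, 180)

# Check a 4-value psi series for the helical-then-strand signature.
# terminal_na_ok: the final residue of a (+) turn may sit at the chain
# terminus (class 3 NESs exit the groove), leaving psi undefined.
.turn_psi_ok <- function(psi4, direction, terminal_na_ok = FALSE) {
  stopifnot(length(psi4) == 4L)
  hel <- function(x) !is.na(x) & x > .TURN_PSI_HELICAL[1] &
    x < .TURN_PSI_HELICAL[2]
  std <- function(x) !is.na(x) & x >= .TURN_PSI_STRAND[1] &
    x <= .TURN_PSI_STRAND[2]
  if (direction == "plus") {
    all(hel(psi4[1:3])) && (std(psi4[4]) || (terminal_na_ok && is.na(psi4[4])))
  } else {
    std(psi4[1]) && all(hel(psi4[2:4]))
  }
}

#' Locate the conserved one-turn helix
#'
#' Every CRM1-bound NES shares a single turn of helix at Phi2-X(2-3)-Phi3
#' that binds the central portion of the groove. For a (+) NES the turn
#' runs helical-helical-helical then strand along the chain (the strand psi
#' of Phi3 is what rotates its carbonyl toward the filter lysine); for a
#' (-) NES the mirrored signature is strand then three helical residues
#' around Phi2. The detector slides a 4-residue window over the allowed
#' registers: (+) windows start at Phi2 or Phi2+1 (the latter covers
#' Phi2-X3-Phi3 spacings, as in SNUPN) and end at or before Phi3; (-)
#' windows start between Phi3 and Phi2-1 and must cover Phi2. A (+) turn
#' whose terminal residue is the chain terminus (class 3, the helix exits
#' the groove) is accepted with a note.
#'
#' @param d `nes_dihedrals`.
#' @param anchors named integer vector of 1-based chain residue indices
#'   with names including `"phi2"` and `"phi3"` (see [anchor_phi_labels()],
#'   which is 0-based; add 1).
#' @param direction `"auto"` (try plus then minus), `"plus"` or `"minus"`.
#' @return object of class `nes_turn`: list `span` (1-based indices),
#'   `psi` (the 4 psi values), `direction`, `terminal` (TRUE when accepted
#'   via the chain-terminus provision) -- or `NULL` when no window
#'   satisfies the criteria. Missing phi2/phi3 anchors are an error.
#' @export
find_conserved_turn <- function(d, anchors,
                                direction = c("auto", "plus", "minus")) {
  direction <- match.arg(direction)
  if (!all(c("phi2", "phi3") %in% names(anchors)))
    stop("turn undefined: anchors must include phi2 and phi3")
  p2 <- as.integer(anchors[["phi2"]]); p3 <- as.integer(anchors[["phi3"]])
  n <- nrow(d)
  psi <- d$psi
  try_dir <- function(dir) {
    if (dir == "plus") {
      if (p3 <= p2) return(NULL)          # (+) register runs phi2 -> phi3
      starts <- c(p2, p2 + 1L)
      starts <- starts[starts >= 1L & starts + 3L <= p3 & starts + 3L <= n]
      for (s in starts) {
        w <- psi[s:(s + 3L)]
        term <- (s + 3L) == n
        if (.turn_psi_ok(w, "plus", terminal_na_ok = term)) {
          return(structure(list(span = s:(s + 3L), psi = w,
                                direction = "plus",
                                terminal = term && is.na(w[4])),
                           class = "nes_turn"))
        }
      }
    } else {
      if (p3 >= p2) return(NULL)          # (-) register runs phi3 -> phi2
      # chain-order window starts at/after phi3 and before phi2, reaching
      # at least phi2-1 (gap-3 registers mirror the SNUPN-style offset)
      for (s in seq(max(1L, p3), max(1L, p2 - 1L))) {
        if (s + 3L > n) break
        if (s + 3L < p2 - 1L) next
        w <- psi[s:(s + 3L)]
        if (.turn_psi_ok(w, "minus")) {
          return(structure(list(span = s:(s + 3L), psi = w,
                                direction = "minus", terminal = FALSE),
                           class = "nes_turn"))
        }
      }
    }
    NULL
  }
  dirs <- if (direction == "auto") c("plus", "minus") else direction
  for (dir in dirs) {
    t <- try_dir(dir)
    if (!is.null(t)) return(t)
  }
  NULL
}

#' @export
print.nes_turn <- function(x, ...) {
  cat(sprintf("Conserved one-turn helix, residues %d-%d (%s), psi: %s\n",
              x$span[1], x$span[4], x$direction,
              paste(sprintf("%.1f", x$psi), collapse = ", ")))
  invisible(x)
}

#' Psi-angle progression through the conserved turn
#'
#' Psi angles in the one-turn helix increase gradually along the (+)
#' polypeptide direction as the conformation progresses from helical to
#' beta-strand (and decrease along the chain for (-) NESs). Implemented as
#' non-strict monotonicity with one allowed violation of at most 5 degrees
#' (crystallographic noise). An NA terminal value (chain terminus) is
#' ignored.
#'
#' @param turn `nes_turn` from [find_conserved_turn()], or a list with
#'   `psi` and `direction`.
#' @return list `series`, `direction`, `monotone` (logical).
#' @export
psi_progression <- function(turn) {
  psi <- turn$psi[!is.na(turn$psi)]
  dif <- diff(psi)
  if (turn$direction == "minus") dif <- -dif
  viol <- dif < 0
  monotone <- !any(viol) || (sum(viol) == 1L && abs(dif[viol]) <= 5)
  list(series = turn$psi, direction = turn$direction, monotone = monotone)
}
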
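## Synthetic peptide backbone builder: ideal-geometry chain extension (NeRF)
## from per-residue phi/psi/omega specifications, class templates, mock
## groove complexes, and random-sequence generators.

# Ideal peptide geometry (Engh-Huber-style averages).
.GEO <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_n_ca_cb = 110.4,
  t_cb = -122.5  # torsion C-N-CA-CB for L-amino acids
)

# NeRF: place atom D given A, B, C with bond |C-D|, angle B-C-D and
# torsion A-B-C-D (degrees).
place_atom <- function(a, b, c_, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c_ - b; bc <- bc / .vnorm(bc)
  ab <- b - a
  n <- .vcross(ab, bc); n <- n / .vnorm(n)
  m <- .vcross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Backbone specification for the synthetic builder
#'
#' @param sequence one-letter amino-acid string.
#' @param phi,psi per-residue dihedrals in degrees (recycled if length 1).
#'   `phi[1]` and `psi[n]` are used only to orient terminal O/CB atoms.
#' @param omega per-residue omega (the torsion following each residue),
#'   default 180 (trans).
#' @param noise_sigma Gaussian noise s.d. (degrees) added to phi/psi at
#'   build time; 0 disables noise.
#' @param seed integer seed making noisy builds reproducible.
#' @return object of class `nes_backbone_spec`.
#' @export
backbone_spec <- function(sequence, phi, psi, omega = 180,
                          noise_sigma = 0, seed = NULL) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 4L) stop("backbone needs at least 4 residues (no dihedrals otherwise)")
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% names(AA1TO3)))
    stop("sequence contains non-standard letters")
  structure(list(sequence = sequence, phi = phi, psi = psi, omega = omega,
                 noise_sigma = noise_sigma, seed = seed),
            class = "nes_backbone_spec")
}

# Run fn with a locally seeded RNG, restoring global state afterwards.
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Build a peptide backbone from a dihedral specification
#'
#' Places N, CA, C, O (and CB for non-glycine) atoms by sequential
#' internal-coordinate chain extension with fixed ideal bond lengths
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom) and angles. Recomputing
#' dihedrals on the output reproduces the specification to better than
#' 1e-3 degrees (before noise). Noise, when requested, is independent
#' Gaussian on phi/psi under the spec's seed.
#'
#' @param spec `nes_backbone_spec`.
#' @param chain_id chain identifier for the result.
#' @return `nes_peptide`.
#' @export
build_backbone <- function(spec, chain_id = "A") {
  stopifnot(inherits(spec, "nes_backbone_spec"))
  n <- nchar(spec$sequence)
  chars <- strsplit(spec$sequence, "")[[1]]
  phi <- spec$phi; psi <- spec$psi; omega <- spec$omega
  if (spec$noise_sigma > 0) {
    noise <- .with_seed(spec$seed, function()
      stats::rnorm(2L * n, sd = spec$noise_sigma))
    phi <- phi + noise[seq_len(n)]
    psi <- psi + noise[n + seq_len(n)]
  }
  g <- .GEO
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      N[i, ] <- place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                           g$b_c_n, g$a_ca_c_n, psi[i - 1L])
      CA[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, omega[i - 1L])
      C[i, ] <- place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                           g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, psi[i] + 180)
    if (chars[i] != "G")
      CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ],
                            g$b_ca_cb, g$a_n_ca_cb, g$t_cb)
  }
  rows <- list()
  for (i in seq_len(n)) {
    resname <- AA1TO3[chars[i]]
    coords <- rbind(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ])
    if (chars[i] != "G") coords <- rbind(coords, CB = CB[i, ])
    rows[[i]] <- data.frame(resno = i, ins = "", resname = unname(resname),
                            atom = rownames(coords), x = unname(coords[, 1]),
                            y = unname(coords[, 2]), z = unname(coords[, 3]),
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  peptide_structure(chain_id, do.call(rbind, rows))
}

# Canonical dihedrals per architecture letter:
#   H alpha-helix, G 3-10 helix, E beta-strand, t/u the two central
#   residues of a type I beta-turn, C coil/loop (non-helical, non-strand).
.SS_DIHEDRALS <- list(
  H = c(-57, -47), G = c(-49, -26), E = c(-120, 130),
  t = c(-60, -30), u = c(-90, 0), C = c(-70, 60)
)

# Build a spec from an architecture string plus anchor positions; anchors
# receive Phi letters, other positions cycle through a fixed non-Phi set.
.template_from_ss <- function(ss, anchors0, anchor_letters = "L",
                              noise_sigma = 0, seed = NULL) {
  letters_ss <- strsplit(ss, "")[[1]]
  n <- length(letters_ss)
  bg <- c("A", "E", "Q", "S", "R", "D", "T", "N")
  chars <- bg[(seq_len(n) - 1L) %% length(bg) + 1L]
  al <- rep_len(strsplit(anchor_letters, "")[[1]], length(anchors0))
  chars[anchors0 + 1L] <- al
  phi <- psi <- numeric(n)
  for (i in seq_len(n)) {
    dd <- .SS_DIHEDRALS[[letters_ss[i]]]
    if (is.null(dd)) stop("unknown architecture letter: ", letters_ss[i])
    phi[i] <- dd[1]; psi[i] <- dd[2]
  }
  sp <- backbone_spec(paste(chars, collapse = ""), phi, psi,
                      noise_sigma = noise_sigma, seed = seed)
  attr(sp, "ss") <- ss
  attr(sp, "anchors0") <- as.integer(anchors0)
  sp
}

# Architecture per class: ss string and anchor positions (0-based).
.CLASS_TEMPLATES <- list(
  # helix through Phi2's turn, strand from Phi3; (+) orientation
  "1a" = list(ss = "HHHHHHHEEEE", anchors = c(0, 4, 7, 9)),
  "1c" = list(ss = "HHHHHHHHEEEE", anchors = c(0, 4, 8, 10)),
  "1d" = list(ss = "HHHHHHHEEEE", anchors = c(0, 3, 7, 9)),
  # 3-10 helix then 3-residue strand (engineered class 1b architecture)
  "1b" = list(ss = "GGGGGGEEEE", anchors = c(0, 3, 6, 8)),
  # mostly loop with the single conserved helical turn Phi2..Phi3
  "2"  = list(ss = "CCHHHECCCC", anchors = c(2, 4, 7, 9) - 2L),
  # all-helix, chain ends at Phi3/Phi4 as it exits the groove
  "3"  = list(ss = "HHHHHHHHHHH", anchors = c(0, 3, 7, 10)),
  # 3-turn helix, strand-transition at Phi3, type I beta-turn whose final
  # residue is the terminal anchor (X11L2-like)
  "4"  = list(ss = "HHHHHHHHHHECtuE", anchors = c(0, 3, 7, 10, 14)),
  # strand-helix, minus orientation: the N-terminal strand reaches Phi2-1
  # and the helix starts at Phi2 (CPEB4/hRio2 architecture)
  "1a-R" = list(ss = "EEEEEEHHHHH", anchors = c(1, 3, 6, 10)),
  "1b-R" = list(ss = "EEEEEEGGGG", anchors = c(1, 3, 6, 9)),
  "1c-R" = list(ss = "EEEEEEEHHHHH", anchors = c(1, 3, 7, 11)),
  "1d-R" = list(ss = "EEEEEEEHHHH", anchors = c(1, 3, 7, 10))

)

#' Canonical backbone template for an NES class
#'
#' Returns a [backbone_spec()] whose built structure the conformational
#' classifier calls as the requested class: alpha-helix-strand for 1a/1c/1d,
#' a 3-10 helix followed by a 3-residue strand for 1b, loop-dominant with
#' the single conserved helical turn for class 2, all-helix for class 3,
#' helix plus type I beta-turn reaching Phi4 for class 4, and the mirrored
#' strand-helix architectures for the -R classes. Anchor letters are placed
#' at the class's spacing.
#'
#' @param class_label class from [nes_classes()].
#' @param anchor_letters Phi letters cycled over anchor slots.
#' @param noise_sigma,seed passed to [backbone_spec()].
#' @return `nes_backbone_spec` with attributes `ss` (architecture string)
#'   and `anchors0` (0-based anchor positions).
#' @export
build_class_template <- function(class_label, anchor_letters = "L",
                                 noise_sigma = 0, seed = NULL) {
  tp <- .CLASS_TEMPLATES[[class_label]]
  if (is.null(tp)) stop("no template for class ", class_label)
  sp <- .template_from_ss(tp$ss, tp$anchors, anchor_letters,
                          noise_sigma, seed)
  attr(sp, "class_label") <- class_label
  # grade the conserved-turn psi series of (+) architectures: the helix
  # unwinds toward the strand transition (psi drifting upward), which is
  # what converges the Phi2+1/Phi3 carbonyls onto the filter lysine
  if (!grepl("-R$", class_label)) {
    a1 <- sort(tp$anchors) + 1L
    w <- if (class_label %in% c("3", "4")) {
      seq(a1[3], a1[4])                       # Phi0-register: Phi2..Phi3
    } else if (a1[3] - a1[2] == 3L) {
      seq(a1[2], a1[3])                       # Phi2 X2 Phi3
    } else {
      seq(a1[2] + 1L, a1[3])                  # Phi2 X3 Phi3, SNUPN offset
    }
    # grade only alpha turns; a 3-10 turn already converges its carbonyls
    if (substr(tp$ss, w[1], w[1]) == "H")
      sp$psi[w[1:3]] <- c(-45, -25, -8)
    if (class_label == "3") sp$psi[w[4]] <- 130  # orients the exit carbonyl
  } else {
    # mirrored grading at the strand-helix junction: psi decreases along
    # the chain from the strand value into the helix
    a1 <- sort(tp$anchors) + 1L
    p2 <- a1[length(a1) - 1L]
    w <- seq(p2, min(p2 + 2L, nchar(sp$sequence)))
    sp$psi[w] <- c(15, -30, -45)[seq_along(w)]
  }
  sp
}

#' Negative-control templates
#'
#' Architectures that are not NES-like: an all-strand peptide and an
#' all-loop peptide without the conserved helical turn.
#'
#' @param type `"strand"` or `"loop"`.
#' @inheritParams build_class_template
#' @return `nes_backbone_spec`.
#' @export
build_negative_template <- function(type = c("strand", "loop"),
                                    noise_sigma = 0, seed = NULL) {
  type <- match.arg(type)
  ss <- if (type == "strand") strrep("E", 11) else strrep("C", 11)
  sp <- .template_from_ss(ss, c(0, 3, 7, 10), "L", noise_sigma, seed)
  attr(sp, "class_label") <- NA_character_
  sp
}

#' Mirror a template's architecture
#'
#' Produces the reversed-architecture specification of a class template:
#' the secondary-structure segment order is reversed and rebuilt from
#' canonical dihedrals with mirrored anchor positions (a naive reversal of
#' built coordinates would not be a valid L-peptide). A (+) helix-strand
#' template therefore becomes the corresponding (-) strand-helix
#' architecture.
#'
#' @param spec a template from [build_class_template()].
#' @return `nes_backbone_spec` of the mirrored architecture.
#' @export
reverse_template <- function(spec) {
  ss <- attr(spec, "ss"); anchors <- attr(spec, "anchors0")
  if (is.null(ss)) stop("spec carries no architecture attribute")
  n <- nchar(ss)
  rss <- paste(rev(strsplit(ss, "")[[1]]), collapse = "")
  # the beta-turn letters are ordered along the chain; keep t before u
  rss <- gsub("ut", "tu", rss)
  ranch <- sort(n - 1L - anchors)
  sp <- .template_from_ss(rss, ranch, "L", spec$noise_sigma, spec$seed)
  cl <- attr(spec, "class_label")
  if (!is.null(cl) && !is.na(cl))
    attr(sp, "class_label") <- if (grepl("-R$", cl)) sub("-R$", "", cl)
      else paste0(cl, "-R")
  sp
}

# ---------------------------------------------------------------------------
# Mock groove complexes

# Among candidate residues, find the carbonyl pair that best hosts an
# ammonium nitrogen at the target distance: sample the equidistant circle
# of each pair and score the clearance from all other atoms.
.best_donor_pair <- function(pep, cand, target = 2.9) {
  Oc <- atom_coords(pep, "O")
  xyz <- as.matrix(pep$atoms[, c("x", "y", "z")])
  isO <- pep$atoms$atom == "O"
  best <- c(cand[1], cand[2]); bestcl <- -Inf
  for (i in cand) for (j in cand[cand > i]) {
    o1 <- Oc[i, ]; o2 <- Oc[j, ]
    doo <- .vnorm(o1 - o2)
    if (is.na(doo) || doo > 2 * target - 0.1) next
    mid <- (o1 + o2) / 2; u <- (o2 - o1) / doo
    h <- sqrt(max(target^2 - (doo / 2)^2, 0.01))
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- .vcross(u, ref); v <- v / .vnorm(v)
    w <- .vcross(u, v)
    other <- xyz[!(isO & pep$atoms$resno %in% c(i, j)), , drop = FALSE]
    cl <- max(vapply(seq(0, 2 * pi, length.out = 37)[-37], function(th) {
      p <- mid + h * (cos(th) * v + sin(th) * w)
      min(sqrt(rowSums((other - matrix(p, nrow(other), 3, byrow = TRUE))^2)))
    }, 1))
    if (cl > bestcl) { bestcl <- cl; best <- c(i, j) }
  }
  best
}

# Place a pseudo-ammonium nitrogen at hydrogen-bond distance from two
# acceptor carbonyl O atoms while avoiding contact with every other atom:
# penalized least squares over candidate start points on the bisector
# circle of the two acceptors.
.place_pseudo_nz <- function(o1, o2, c1, c2, target, other_xyz, away) {
  obj <- function(p) {
    d1 <- .vnorm(p - o1); d2 <- .vnorm(p - o2)
    v <- (d1 - target)^2 + (d2 - target)^2
    ang <- function(cc, oo) {
      u1 <- cc - oo; u2 <- p - oo
      acos(pmin(1, pmax(-1, sum(u1 * u2) / (.vnorm(u1) * .vnorm(u2))))) *
        180 / pi
    }
    v <- v + 0.005 * (max(0, 100 - ang(c1, o1))^2 + max(0, 100 - ang(c2, o2))^2)
    if (nrow(other_xyz)) {
      dd <- sqrt(colSums((t(other_xyz) - p)^2))
      v <- v + sum(pmax(0, 2.95 - dd)^2) * 5
    }
    v
  }
  mid <- (o1 + o2) / 2
  u <- o2 - o1; u <- u / .vnorm(u)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- .vcross(u, ref); v <- v / .vnorm(v)
  w <- .vcross(u, v)
  # carbonyl directions give a chemically sensible start
  d1 <- (o1 - c1) / .vnorm(o1 - c1); d2 <- (o2 - c2) / .vnorm(o2 - c2)
  starts <- list(mid + 2 * (d1 + d2) / max(.vnorm(d1 + d2), 0.1))
  for (th in seq(0, 2 * pi, length.out = 13)[-13])
    starts <- c(starts, list(mid + 2.5 * (cos(th) * v + sin(th) * w)))
  best <- NULL; bestv <- Inf
  for (start in starts) {
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 600, reltol = 1e-10))
    if (fit$value < bestv) { bestv <- fit$value; best <- fit$par }
  }
  best
}

#' Build a mock CRM1-groove complex around a synthetic peptide
#'
#' Emulates the geometry the groove analysis needs without a receptor:
#' five pseudo-pocket markers placed at the side-chain (CB) positions of
#' the reference anchors (optionally jittered), and a pseudo filter-lysine
#' whose NZ sits at hydrogen-bond distance from two named backbone
#' carbonyls - by default the Phi2+1 and Phi3 carbonyls of the conserved
#' turn, mimicking the niche coordination by HsCRM1 Lys568.
#'
#' @param spec `nes_backbone_spec` from [build_class_template()] (must
#'   carry anchor positions) or an `nes_peptide` plus explicit `anchors0`.
#' @param anchors0 0-based anchor positions (defaults to the spec's).
#' @param hbond_residues 1-based residue indices whose carbonyl O atoms the
#'   pseudo-NZ coordinates; `NULL` places NZ from the conserved-turn rule
#'   (third and fourth anchors for 4-anchor (+) templates).
#' @param nz_distance NZ...O distance in Angstrom (default 2.9).
#' @param pocket_jitter s.d. (Angstrom) of Gaussian jitter on pocket
#'   markers, seeded.
#' @param seed integer seed for jitter.
#' @param guard when `TRUE`, the pseudo-lysine is given side-chain bulk
#'   (CD/CE atoms) directed into the space a false-positive peptide would
#'   occupy - the continuation of the template's helix past its transition
#'   point, emulating how the real filter-lysine side chain constricts the
#'   groove. The guard atoms are placed so the template peptide itself
#'   stays clear of them.
#' @return object of class `nes_mock_complex`: list with `peptide`
#'   (`nes_peptide`), `pockets` (5 x 3 matrix, rows P0..P4 in chain order
#'   of the anchors), `pocket_anchor_res` (1-based residue index per
#'   pocket), `lysine` (list `resno`, `atoms` matrix with NZ and CE).
#' @export
build_mock_complex <- function(spec, anchors0 = NULL, hbond_residues = NULL,
                               nz_distance = 2.9, pocket_jitter = 0,
                               seed = NULL, guard = FALSE) {
  if (inherits(spec, "nes_backbone_spec")) {
    pep <- build_backbone(spec, chain_id = "B")
    if (is.null(anchors0)) anchors0 <- attr(spec, "anchors0")
  } else if (inherits(spec, "nes_peptide")) {
    pep <- spec
  } else stop("spec must be a backbone spec or a peptide")
  if (is.null(anchors0)) stop("anchor positions required")
  anchors1 <- sort(as.integer(anchors0)) + 1L
  cb <- atom_coords(pep, "CB"); ca <- atom_coords(pep, "CA")
  pts <- cb[anchors1, , drop = FALSE]
  missing_cb <- !is.finite(pts[, 1])
  pts[missing_cb, ] <- ca[anchors1[missing_cb], , drop = FALSE]
  if (pocket_jitter > 0) {
    pts <- pts + .with_seed(seed, function()
      matrix(stats::rnorm(length(pts), sd = pocket_jitter), nrow(pts), 3))
  }
  k <- length(anchors1)
  cl <- if (inherits(spec, "nes_backbone_spec"))
    attr(spec, "class_label") else NULL
  minus <- !is.null(cl) && !is.na(cl) && grepl("-R$", cl)
  # pocket index of each chain anchor follows the Phi register: Phi_i
  # binds P_i; (+) 4-anchor classes use P1..P4, Phi0-bearing registers
  # (class 3 structural, class 4) use P0.., (-) classes run P4..P1 along
  # the chain
  phi_idx <- if (minus) seq(k, 1L) else
    if (k >= 5L || (!is.null(cl) && !is.na(cl) && cl %in% c("3", "4")))
      seq(0L, k - 1L) else seq(1L, k)
  centers <- matrix(NA_real_, 5, 3,
                    dimnames = list(paste0("P", 0:4), c("x", "y", "z")))
  anchor_res <- rep(NA_integer_, 5)
  centers[phi_idx + 1L, ] <- pts                   # row m+1 holds P_m
  anchor_res[phi_idx + 1L] <- anchors1
  # fill unused pockets by extrapolation/interpolation along the groove
  present <- which(!is.na(centers[, 1])) - 1L
  for (m in setdiff(0:4, present)) {
    lo <- present[present < m]; hi <- present[present > m]
    centers[m + 1L, ] <- if (!length(lo)) {
      a <- min(hi); b <- min(hi[hi > a])
      centers[a + 1L, ] + (m - a) / (b - a) *
        (centers[b + 1L, ] - centers[a + 1L, ])
    } else if (!length(hi)) {
      b <- max(lo); a <- max(lo[lo < b])
      centers[b + 1L, ] + (m - b) / (b - a) *
        (centers[b + 1L, ] - centers[a + 1L, ])
    } else {
      a <- max(lo); b <- min(hi)
      centers[a + 1L, ] + (m - a) / (b - a) *
        (centers[b + 1L, ] - centers[a + 1L, ])
    }
  }
  anchors1 <- anchor_res
  if (is.null(hbond_residues)) {
    # expected filter-lysine donors: Phi2+1 and Phi3 carbonyls for (+)
    # architectures (Phi1..Phi4, or Phi0..Phi4 with 5 anchors); Phi1-1 and
    # Phi2-1 for (-) architectures where chain order runs Phi4..Phi1
    a1 <- sort(as.integer(anchors0)) + 1L
    cl <- if (inherits(spec, "nes_backbone_spec"))
      attr(spec, "class_label") else NULL
    minus <- !is.null(cl) && !is.na(cl) && grepl("-R$", cl)
    hbond_residues <- if (minus) {
      # (-) NESs lack the (+) niche geometry; the lysine is coordinated by
      # carbonyls near the strand-helix junction. Pick the junction pair
      # whose carbonyls can actually host an ammonium nitrogen without
      # steric frustration.
      p2 <- a1[length(a1) - 1L]; p1 <- a1[length(a1)]
      cand <- unique(c(seq(max(1L, p2 - 3L), min(nrow(residue_table(pep)),
                                                 p2 + 4L)), p1 - 1L))
      .best_donor_pair(pep, cand, nz_distance)
    } else if (!is.null(cl) && !is.na(cl) && cl == "3") {
      c(a1[3] + 1L, a1[4])      # structural register Phi0..Phi3
    } else if (length(a1) >= 5L) {
      c(a1[3] + 1L, a1[4])                  # Phi0..Phi4: Phi2+1, Phi3
    } else {
      c(a1[2] + 1L, a1[3])                  # Phi1..Phi4: Phi2+1, Phi3
    }
  }
  Oc <- atom_coords(pep, "O"); Cc <- atom_coords(pep, "C")
  o1 <- Oc[hbond_residues[1], ]; o2 <- Oc[hbond_residues[2], ]
  centroid <- colMeans(ca, na.rm = TRUE)
  other <- as.matrix(pep$atoms[, c("x", "y", "z")])
  keep <- !(pep$atoms$atom == "O" &
              pep$atoms$resno %in% hbond_residues)
  nz <- .place_pseudo_nz(o1, o2, Cc[hbond_residues[1], ],
                         Cc[hbond_residues[2], ], nz_distance,
                         other[keep, , drop = FALSE], centroid)
  # CE extends away from the peptide; pick the direction clearing it best
  dirs <- list((nz - centroid) / .vnorm(nz - centroid),
               (nz - (o1 + o2) / 2) / .vnorm(nz - (o1 + o2) / 2))
  dirs <- c(dirs, list((dirs[[1]] + dirs[[2]]) /
                         max(.vnorm(dirs[[1]] + dirs[[2]]), 0.1)))
  ce_cand <- lapply(dirs, function(d) nz + 1.47 * d)
  clearance <- vapply(ce_cand, function(p)
    min(sqrt(rowSums((other - matrix(p, nrow(other), 3,
                                     byrow = TRUE))^2))), 1)
  ce <- ce_cand[[which.max(clearance)]]
  lys_atoms <- rbind(NZ = nz, CE = ce)
  if (guard) {
    gd <- .guard_atoms(pep, spec, nz)
    if (!is.null(gd)) lys_atoms <- rbind(NZ = nz, gd)
  }
  lys <- list(resno = 568L, atoms = lys_atoms)
  structure(list(peptide = pep, pockets = centers,
                 pocket_anchor_res = anchors1, lysine = lys,
                 hbond_residues = hbond_residues),
            class = "nes_mock_complex")
}

# Ghost continuation of the template's helix: an ideal helix superposed on
# the template's helical segment, extending past the transition point into
# the space only a false-positive (non-transitioning) peptide would occupy.
.ghost_continuation <- function(pep, spec) {
  ss <- strsplit(attr(spec, "ss"), "")[[1]]
  hel <- ss %in% c("H", "G")
  if (!any(hel)) return(NULL)
  r <- rle(hel)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  pick <- which(r$values & r$lengths == max(r$lengths[r$values]))[1]
  j0 <- starts[pick]; j1 <- ends[pick]
  k <- min(5L, j1 - j0 + 1L)
  dd <- .SS_DIHEDRALS[[ss[j0]]]
  n <- length(ss)
  minus <- j1 == n                     # helix at the C-terminus: extend back
  m <- n + 4L
  ghost <- build_backbone(backbone_spec(strrep("A", m), dd[1], dd[2]))
  gca <- atom_coords(ghost, "CA")
  pca <- atom_coords(pep, "CA")
  off <- if (minus) 5L else 1L         # leave 4 ghost residues behind j0
  tr <- superpose(gca[off:(off + k - 1L), ], pca[j0:(j0 + k - 1L), ])
  ghost <- transform_peptide(ghost, tr)
  keep <- if (minus) seq_len(4L) else
    seq(j1 - j0 + 2L, m)               # residues past the helix end
  sel <- ghost$atoms$resno %in% keep
  as.matrix(ghost$atoms[sel, c("x", "y", "z")])
}

# Deterministic Fibonacci-sphere direction search for guard atoms: maximize
# clearance from the template peptide subject to reaching the ghost path.
.guard_atoms <- function(pep, spec, nz) {
  ghost <- .ghost_continuation(pep, spec)
  if (is.null(ghost)) return(NULL)
  xyz <- as.matrix(pep$atoms[, c("x", "y", "z")])
  n_dir <- 800L
  i <- seq_len(n_dir)
  phi_g <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * (i - 0.5) / n_dir
  rxy <- sqrt(pmax(0, 1 - z^2))
  best <- NULL; best_clear <- -Inf
  for (j in i) {
    u <- c(rxy[j] * cos(phi_g[j]), rxy[j] * sin(phi_g[j]), z[j])
    pts <- rbind(CE = nz + 1.47 * u, CD = nz + 2.85 * u)
    dref <- min(apply(pts, 1, function(p)
      min(sqrt(rowSums((xyz - matrix(p, nrow(xyz), 3, byrow = TRUE))^2)))))
    dgho <- min(apply(pts, 1, function(p)
      min(sqrt(rowSums((ghost - matrix(p, nrow(ghost), 3, byrow = TRUE))^2)))))
    if (dgho <= 2.8 && dref > best_clear) {
      best_clear <- dref; best <- pts
    }
  }
  if (is.null(best) || best_clear < 3.05) return(NULL)
  best
}

# ---------------------------------------------------------------------------
# Random sequences with embedded NES motifs

#' Generate random protein sequences with embedded NES motifs
#'
#' Background residues are drawn with a controllable total Phi frequency
#' (split uniformly across L/V/I/F/M; the remainder uniform over the other
#' fifteen letters). One motif of each requested class is embedded per
#' sequence at a random position: anchor slots receive Phi letters and the
#' embedded X slots are drawn from the background distribution, so chance
#' matches can and do occur - the truth table records only the planted
#' anchors.
#'
#' @param n number of sequences.
#' @param length sequence length.
#' @param nes_classes class labels to embed (recycled over sequences);
#'   `NULL` embeds nothing.
#' @param phi_freq total background Phi frequency in `[0, 1]` (default
#'   0.29, the approximate combined proteome frequency of L/V/I/F/M).
#' @param seed integer seed; identical seeds give identical records.
#' @return list with `sequences` (named character vector) and `truth`
#'   (data frame `seq_id`, `class`, `start`, `anchors` 0-based
#'   comma-joined).
#' @export
generate_nes_sequences <- function(n, length, nes_classes = "1a",
                                   phi_freq = 0.29, seed = 1L) {
  stopifnot(n >= 1L, length >= 12L, phi_freq >= 0, phi_freq <= 1)
  nonphi <- setdiff(AA20, PHI_RESIDUES)
  probs <- c(rep(phi_freq / 5, 5), rep((1 - phi_freq) / 15, 15))
  letters_all <- c(PHI_RESIDUES, nonphi)
  .with_seed(seed, function() {
    seqs <- character(n); truth <- list()
    for (i in seq_len(n)) {
      s <- sample(letters_all, length, replace = TRUE, prob = probs)
      if (!is.null(nes_classes)) {
        cls <- nes_classes[(i - 1L) %% base::length(nes_classes) + 1L]
        gaps <- .CLASS_GAPS[[cls]]
        if (is.null(gaps)) stop("unknown class ", cls)
        offs <- cumsum(c(0L, gaps + 1L))
        w <- max(offs) + 1L
        st <- sample.int(length - w + 1L, 1L) - 1L
        anch <- st + offs
        s[anch + 1L] <- sample(PHI_RESIDUES, base::length(anch),
                               replace = TRUE)
        truth[[base::length(truth) + 1L]] <- data.frame(
          seq_id = sprintf("seq%04d", i), class = cls, start = st,
          anchors = paste(anch, collapse = ","), stringsAsFactors = FALSE)
      }
      seqs[i] <- paste(s, collapse = "")
    }
    names(seqs) <- sprintf("seq%04d", seq_len(n))
    list(sequences = seqs,
         truth = if (base::length(truth)) do.call(rbind, truth) else
           data.frame(seq_id = character(), class = character(),
                      start = integer(), anchors = character()))
  })
}

#' Write generated sequences as FASTA plus a TSV truth table
#'
#' @param gen result of [generate_nes_sequences()].
#' @param fasta,truth_tsv output paths.
#' @return invisibly, the two paths.
#' @export
write_nes_sequences <- function(gen, fasta, truth_tsv) {
  aas <- Biostrings::AAStringSet(gen$sequences)
  Biostrings::writeXStringSet(aas, fasta)
  utils::write.table(gen$truth, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta, truth_tsv))
}

#' Evaluate matcher output against a planted truth table
#'
#' A match is counted true when its anchor positions coincide exactly with
#' an embedded motif of the same class in the same sequence. Reports
#' per-class and overall precision and recall.
#'
#' @param matches data frame from [scan_nes()] over the generated records.
#' @param truth truth table from [generate_nes_sequences()].
#' @return data frame: `class`, `n_true`, `n_matched`, `n_hits`,
#'   `precision`, `recall`; last row is the overall summary.
#' @export
evaluate_matcher <- function(matches, truth) {
  key_m <- paste(matches$sequence_id, matches$class, matches$anchors)
  key_t <- paste(truth$seq_id, truth$class, truth$anchors)
  rows <- list()
  for (cls in sort(unique(truth$class))) {
    tm <- key_t[truth$class == cls]
    mm <- key_m[matches$class == cls]
    hits <- sum(tm %in% mm)
    rows[[cls]] <- data.frame(
      class = cls, n_true = length(tm), n_matched = length(mm),
      n_hits = hits,
      precision = if (length(mm)) sum(mm %in% tm) / length(mm) else NA_real_,
      recall = if (length(tm)) hits / length(tm) else NA_real_,
      stringsAsFactors = FALSE)
  }
  cls_all <- unique(truth$class)
  mm <- key_m[matches$class %in% cls_all]
  hits <- sum(key_t %in% mm)
  rows[["overall"]] <- data.frame(
    class = "overall", n_true = length(key_t), n_matched = length(mm),
    n_hits = hits,
    precision = if (length(mm)) sum(mm %in% key_t) / length(mm) else NA_real_,
    recall = if (length(key_t)) hits / length(key_t) else NA_real_,
    stringsAsFactors = FALSE)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
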
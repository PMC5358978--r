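## Groove analysis: pocket frame construction, anchor-to-pocket assignment,
## Phi Calpha displacements, filter-lysine hydrogen bonds/niche motifs, and
## the steric-clash filter.

#' Default analysis thresholds
#'
#' All geometric thresholds used by the groove analysis, collected in one
#' place and serialized into every report: hydrogen-bond NZ...O distance
#' cutoff (3.5 Angstrom) and C-O...NZ angle minimum (90 degrees; hydrogens
#' are not modelled at crystallographic resolution), steric-clash overlap
#' threshold (0.4 Angstrom, the conventional serious-clash limit),
#' anchor-to-pocket assignment cutoff (4.0 Angstrom, chosen to exceed the
#' largest observed mean Phi displacement plus spread), chain-break C-N
#' distance (2.0 Angstrom), and the groove-selection radius around the
#' bound NES (8.0 Angstrom).
#'
#' @return named list of thresholds.
#' @export
nes_thresholds <- function() {
  list(hbond_dist = 3.5, hbond_angle = 90, clash_overlap = 0.4,
       pocket_cutoff = 4.0, chain_break = 2.0, groove_radius = 8.0)
}

# van der Waals radii by element (Angstrom).
.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

.element_of <- function(atom_name) {
  el <- substr(gsub("^[0-9]", "", atom_name), 1, 1)
  ifelse(el %in% names(.VDW), el, "C")
}

# Side-chain representative point of residue i: heavy-atom centroid of
# non-backbone atoms, CB fallback, CA as a last resort.
.sidechain_point <- function(p, i) {
  m <- residue_atoms(p, i)
  sc <- m[!rownames(m) %in% c(BACKBONE_ATOMS, "OXT"), , drop = FALSE]
  if (nrow(sc)) return(colMeans(sc))
  if ("CB" %in% rownames(m)) return(m["CB", ])
  m["CA", ]
}

#' Build a pocket frame from a reference complex
#'
#' The reference frame against which all other complexes are analysed:
#' the five P0-P4 pocket centers (centroids of the reference NES's Phi
#' side-chain heavy atoms), the reference anchor Calpha positions used for
#' displacement measurement, the filter lysine (ScCRM1 Lys579 / Hs-Mm
#' CRM1 Lys568) with its side-chain atoms, and the groove residue
#' selection (CRM1 residues with any atom within the groove radius of the
#' NES) whose Calpha set defines the groove superposition target.
#'
#' @param x an `nes_complex` (from [load_complex()]) or an
#'   `nes_mock_complex` (from [build_mock_complex()]).
#' @param ... passed to methods.
#' @return object of class `nes_frame`: list `centers` (5 x 3, rows
#'   P0..P4), `anchor_ca` (5 x 3 reference Phi Calpha, NA rows when the
#'   reference NES has no anchor in a pocket), `lysine` (list `resno`,
#'   `atoms`), `groove_ca` (matrix or NULL), `groove_residues`,
#'   `thresholds`.
#' @export
build_pocket_frame <- function(x, ...) UseMethod("build_pocket_frame")

#' @rdname build_pocket_frame
#' @param nes_chain,crm1_chain chain identifiers.
#' @param anchor_resnos author residue numbers of the reference NES Phi
#'   anchors, in pocket order P0..P4 (NA for an unused pocket).
#' @param lysine_resno author number of the filter lysine in `crm1_chain`.
#' @param thresholds threshold list, see [nes_thresholds()].
#' @export
build_pocket_frame.nes_complex <- function(x, nes_chain, crm1_chain,
                                           anchor_resnos,
                                           lysine_resno = 579,
                                           thresholds = nes_thresholds(),
                                           ...) {
  nes <- x$chains[[nes_chain]]
  crm1 <- x$chains[[crm1_chain]]
  if (is.null(nes) || is.null(crm1))
    stop("complex lacks chain(s): ",
         paste(setdiff(c(nes_chain, crm1_chain), names(x$chains)),
               collapse = ", "))
  rt <- residue_table(nes)
  centers <- anchor_ca <- matrix(NA_real_, length(anchor_resnos), 3,
                                 dimnames = list(
                                   paste0("P", seq_along(anchor_resnos) - 1L),
                                   c("x", "y", "z")))
  ca <- atom_coords(nes, "CA")
  missing <- character()
  for (k in seq_along(anchor_resnos)) {
    rn <- anchor_resnos[k]
    if (is.na(rn)) next
    i <- match(rn, rt$resno)
    if (is.na(i)) { missing <- c(missing, rn); next }
    centers[k, ] <- .sidechain_point(nes, i)
    anchor_ca[k, ] <- ca[i, ]
  }
  if (length(missing))
    stop("reference NES lacks anchor residue(s): ",
         paste(missing, collapse = ", "))
  lys_rt <- residue_table(crm1)
  li <- match(lysine_resno, lys_rt$resno)
  if (is.na(li)) stop("CRM1 chain lacks the filter lysine residue ",
                      lysine_resno)
  lys_atoms <- residue_atoms(crm1, li)
  if (!"NZ" %in% rownames(lys_atoms))
    stop("filter lysine ", lysine_resno, " lacks its NZ atom")
  # groove selection: CRM1 residues with any atom within radius of the NES
  nes_xyz <- as.matrix(nes$atoms[, c("x", "y", "z")])
  crm1_xyz <- as.matrix(crm1$atoms[, c("x", "y", "z")])
  r <- thresholds$groove_radius
  near <- vapply(seq_len(nrow(crm1_xyz)), function(i) {
    min(sqrt(colSums((t(nes_xyz) - crm1_xyz[i, ])^2))) <= r
  }, TRUE)
  groove_res <- sort(unique(crm1$atoms$resno[near]))
  crm1_ca <- atom_coords(crm1, "CA")
  crt <- residue_table(crm1)
  gsel <- crt$resno %in% groove_res
  structure(list(centers = centers, anchor_ca = anchor_ca,
                 lysine = list(resno = lysine_resno,
                               atoms = lys_atoms[!rownames(lys_atoms) %in%
                                                   BACKBONE_ATOMS, ,
                                                 drop = FALSE]),
                 groove_ca = crm1_ca[gsel, , drop = FALSE],
                 groove_residues = groove_res,
                 thresholds = thresholds),
            class = "nes_frame")
}

#' @rdname build_pocket_frame
#' @export
build_pocket_frame.nes_mock_complex <- function(x,
                                                thresholds = nes_thresholds(),
                                                ...) {
  if (!"NZ" %in% rownames(x$lysine$atoms))
    stop("mock lysine lacks its NZ atom")
  k <- nrow(x$pockets)
  anchor_ca <- matrix(NA_real_, k, 3, dimnames = dimnames(x$pockets))
  ca <- atom_coords(x$peptide, "CA")
  for (i in seq_len(k)) {
    if (!is.na(x$pocket_anchor_res[i]))
      anchor_ca[i, ] <- ca[x$pocket_anchor_res[i], ]
  }
  structure(list(centers = x$pockets, anchor_ca = anchor_ca,
                 lysine = x$lysine, groove_ca = NULL,
                 groove_residues = integer(), thresholds = thresholds),
            class = "nes_frame")
}

#' @export
print.nes_frame <- function(x, ...) {
  cat(sprintf("nes_frame: %d pockets, filter lysine %d, %d groove residues\n",
              nrow(x$centers), x$lysine$resno, length(x$groove_residues)))
  invisible(x)
}

#' Serialize / restore a pocket frame as JSON
#'
#' Frames are serialized to plain JSON fixtures so downstream analyses and
#' tests need no structure files.
#'
#' @param frame `nes_frame`.
#' @param path JSON file path.
#' @return `frame_to_json`: the path, invisibly; `frame_from_json`: the
#'   restored `nes_frame`.
#' @export
frame_to_json <- function(frame, path) {
  obj <- list(centers = frame$centers, anchor_ca = frame$anchor_ca,
              lysine = list(resno = frame$lysine$resno,
                            atom_names = rownames(frame$lysine$atoms),
                            atoms = frame$lysine$atoms),
              groove_ca = frame$groove_ca,
              groove_residues = frame$groove_residues,
              thresholds = frame$thresholds)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname frame_to_json
#' @export
frame_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- function(m, rn) {
    m <- matrix(as.numeric(m), ncol = 3)
    rownames(m) <- rn; colnames(m) <- c("x", "y", "z"); m
  }
  k <- length(obj$groove_residues)
  structure(list(
    centers = nm(obj$centers, paste0("P", seq_len(nrow(obj$centers)) - 1L)),
    anchor_ca = nm(obj$anchor_ca, paste0("P", seq_len(nrow(obj$anchor_ca)) - 1L)),
    lysine = list(resno = obj$lysine$resno,
                  atoms = nm(obj$lysine$atoms, obj$lysine$atom_names)),
    groove_ca = if (is.null(obj$groove_ca)) NULL else
      nm(obj$groove_ca, NULL),
    groove_residues = as.integer(obj$groove_residues),
    thresholds = obj$thresholds), class = "nes_frame")
}

#' Assign Phi anchors to groove pockets
#'
#' Greedy minimal-distance one-to-one matching of the peptide's Phi
#' residue side-chain centroids (CB when no further side-chain atoms are
#' present) to the P0-P4 pocket centers, within the assignment cutoff.
#' Ties are broken toward the lower residue number, then the lower pocket
#' index, making the matching independent of input order. Orientation is
#' plus when assigned pocket labels increase with residue number, minus
#' when they decrease. Fewer than 3 assigned pockets raises the
#' "insufficient anchors" flag (NES criterion 1 fails).
#'
#' @param peptide `nes_peptide`, already in the reference frame (apply
#'   `transform` otherwise).
#' @param frame `nes_frame`.
#' @param transform optional `nes_superposition` mapping the peptide into
#'   the frame.
#' @return object of class `nes_anchor_map`: list `assignments` (data
#'   frame `pocket`, `resno`, `res_index`, `resname`, `distance`),
#'   `occupancy` (named logical), `orientation`
#'   (`"plus"`/`"minus"`/`"ambiguous"`), `insufficient` (logical).
#' @export
assign_anchors <- function(peptide, frame, transform = NULL) {
  if (!is.null(transform)) peptide <- transform_peptide(peptide, transform)
  rt <- residue_table(peptide)
  phis <- which(rt$resname %in% PHI_RESNAMES)
  cutoff <- frame$thresholds$pocket_cutoff
  k <- nrow(frame$centers)
  if (length(phis)) {
    D <- matrix(NA_real_, length(phis), k,
                dimnames = list(phis, rownames(frame$centers)))
    for (a in seq_along(phis))
      for (b in seq_len(k))
        D[a, b] <- .vnorm(.sidechain_point(peptide, phis[a]) -
                            frame$centers[b, ])
  } else D <- matrix(NA_real_, 0, k)
  assign <- list()
  used_res <- logical(length(phis)); used_pkt <- logical(k)
  repeat {
    Dm <- D
    if (length(Dm)) {
      Dm[used_res, ] <- NA; Dm[, used_pkt] <- NA
    }
    if (!length(Dm) || all(is.na(Dm)) || min(Dm, na.rm = TRUE) > cutoff)
      break
    best <- which(Dm == min(Dm, na.rm = TRUE), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    a <- best[1]; b <- best[2]
    assign[[length(assign) + 1L]] <- data.frame(
      pocket = rownames(frame$centers)[b], resno = rt$resno[phis[a]],
      res_index = phis[a], resname = rt$resname[phis[a]],
      distance = D[a, b], stringsAsFactors = FALSE)
    used_res[a] <- TRUE; used_pkt[b] <- TRUE
  }
  asg <- if (length(assign)) do.call(rbind, assign) else
    data.frame(pocket = character(), resno = integer(),
               res_index = integer(), resname = character(),
               distance = numeric(), stringsAsFactors = FALSE)
  occupancy <- stats::setNames(rownames(frame$centers) %in% asg$pocket,
                               rownames(frame$centers))
  orientation <- "ambiguous"
  if (nrow(asg) >= 2L) {
    ord <- order(asg$res_index)
    pk <- as.integer(sub("^P", "", asg$pocket))[ord]
    if (all(diff(pk) > 0)) orientation <- "plus"
    else if (all(diff(pk) < 0)) orientation <- "minus"
  }
  structure(list(assignments = asg, occupancy = occupancy,
                 orientation = orientation,
                 insufficient = nrow(asg) < 3L),
            class = "nes_anchor_map")
}

#' @export
print.nes_anchor_map <- function(x, ...) {
  cat(sprintf("Anchor map: %d pockets occupied (%s), orientation %s%s\n",
              sum(x$occupancy),
              paste(names(x$occupancy)[x$occupancy], collapse = ","),
              x$orientation,
              if (x$insufficient) " [insufficient anchors]" else ""))
  if (nrow(x$assignments)) print(x$assignments)
  invisible(x)
}

#' Phi Calpha displacements from the reference NES
#'
#' Euclidean Calpha-Calpha distance of each assigned anchor to the
#' reference NES's equivalent Phi Calpha (same pocket).
#'
#' @param map `nes_anchor_map`.
#' @param peptide the mapped `nes_peptide` (same frame as the reference).
#' @param frame `nes_frame` carrying `anchor_ca`.
#' @return data frame `pocket`, `resno`, `displacement` (Angstrom).
#' @export
anchor_displacements <- function(map, peptide, frame) {
  asg <- map$assignments
  ca <- atom_coords(peptide, "CA")
  disp <- vapply(seq_len(nrow(asg)), function(i) {
    ref <- frame$anchor_ca[asg$pocket[i], ]
    if (anyNA(ref)) return(NA_real_)
    .vnorm(ca[asg$res_index[i], ] - ref)
  }, 1)
  data.frame(pocket = asg$pocket, resno = asg$resno, displacement = disp,
             stringsAsFactors = FALSE)
}

#' Cohort displacement statistics
#'
#' Mean and standard deviation of per-pocket Phi Calpha displacements over
#' a set of analysed peptides, as used to summarise how reproducibly the
#' anchors sit in their pockets across structures.
#'
#' @param displacement_tables list of data frames from
#'   [anchor_displacements()].
#' @return data frame `pocket`, `n`, `mean`, `sd`.
#' @export
displacement_cohort <- function(displacement_tables) {
  all <- do.call(rbind, displacement_tables)
  all <- all[!is.na(all$displacement), , drop = FALSE]
  out <- lapply(split(all$displacement, all$pocket), function(v)
    c(n = length(v), mean = mean(v), sd = stats::sd(v)))
  res <- data.frame(pocket = names(out), do.call(rbind, out),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Detect filter-lysine hydrogen bonds and niche motifs
#'
#' Finds every peptide backbone carbonyl O within hydrogen-bond distance
#' of the filter lysine NZ with an acceptable C-O...NZ angle. In (+) NESs
#' the expected donors are the Phi2+1 and Phi3 carbonyls of the conserved
#' turn - a niche3/niche4 motif, where carbonyls of residues i and i+2
#' (niche3) or i+3 (niche4) coordinate one cationic group; in (-) NESs
#' the N-terminal strand carbonyls (Phi1-1, Phi2-1) take that role.
#' Expectation and observation are both reported.
#'
#' @param peptide `nes_peptide` in the reference frame.
#' @param frame `nes_frame`.
#' @param anchors optional named vector of 1-based anchor indices
#'   (phi1..phi4) used to state the expected donors.
#' @param orientation `"plus"`, `"minus"` or `"unknown"`.
#' @return list `hbonds` (data frame `res_index`, `resno`, `distance`,
#'   `angle`), `niche` (list `type`, `res_indices` or NULL), `expected`
#'   (character), `expected_satisfied` (logical or NA).
#' @export
detect_filter_hbonds <- function(peptide, frame, anchors = NULL,
                                 orientation = c("unknown", "plus", "minus")) {
  orientation <- match.arg(orientation)
  if (is.null(frame$lysine) || !"NZ" %in% rownames(frame$lysine$atoms))
    stop("frame lacks the filter lysine NZ atom")
  nz <- frame$lysine$atoms["NZ", ]
  rt <- residue_table(peptide)
  Oc <- atom_coords(peptide, "O"); Cc <- atom_coords(peptide, "C")
  th <- frame$thresholds
  rows <- list()
  for (i in seq_len(nrow(rt))) {
    if (anyNA(Oc[i, ])) next
    dist <- .vnorm(nz - Oc[i, ])
    if (dist > th$hbond_dist) next
    v1 <- Cc[i, ] - Oc[i, ]; v2 <- nz - Oc[i, ]
    ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (.vnorm(v1) * .vnorm(v2))))) *
      180 / pi
    if (ang < th$hbond_angle) next
    rows[[length(rows) + 1L]] <- data.frame(res_index = i, resno = rt$resno[i],
                                            distance = dist, angle = ang)
  }
  hb <- if (length(rows)) do.call(rbind, rows) else
    data.frame(res_index = integer(), resno = integer(),
               distance = numeric(), angle = numeric())
  niche <- NULL
  if (nrow(hb) >= 2L) {
    idx <- sort(hb$res_index)
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      sp <- idx[b] - idx[a]
      if (sp %in% c(2L, 3L)) {
        niche <- list(type = if (sp == 2L) "niche3" else "niche4",
                      res_indices = c(idx[a], idx[b]))
      }
    }
  }
  expected <- NA_character_
  expected_satisfied <- NA
  if (!is.null(anchors) && orientation != "unknown") {
    exp_idx <- if (orientation == "plus") {
      if (all(c("phi2", "phi3") %in% names(anchors)))
        c(anchors[["phi2"]] + 1L, anchors[["phi3"]])
    } else {
      if (all(c("phi1", "phi2") %in% names(anchors)))
        c(anchors[["phi1"]] - 1L, anchors[["phi2"]] - 1L)
    }
    if (!is.null(exp_idx)) {
      expected <- paste(exp_idx, collapse = ",")
      expected_satisfied <- all(exp_idx %in% hb$res_index)
    }
  }
  list(hbonds = hb, niche = niche, expected = expected,
       expected_satisfied = expected_satisfied)
}

#' Steric-clash filter against the filter lysine
#'
#' Superposed false-positive peptides collide with the wild-type filter
#' lysine side chain: every peptide atom is tested against the lysine
#' side-chain atoms using van der Waals radii (C 1.70, N 1.55, O 1.52,
#' S 1.80 Angstrom); an overlap (radius sum minus distance) greater than
#' the clash threshold is a serious clash and the peptide is called
#' "blocked".
#'
#' @param peptide `nes_peptide` in the reference frame.
#' @param frame `nes_frame`.
#' @return object of class `nes_clash_report`: list `contacts` (data frame
#'   `res_index`, `resno`, `atom`, `lys_atom`, `distance`, `overlap`),
#'   `worst_overlap`, `clashing`, `verdict`.
#' @export
clash_filter <- function(peptide, frame) {
  th <- frame$thresholds$clash_overlap
  lys <- frame$lysine$atoms
  a <- peptide$atoms
  rows <- list()
  for (j in seq_len(nrow(lys))) {
    lel <- .element_of(rownames(lys)[j])
    d <- sqrt((a$x - lys[j, 1])^2 + (a$y - lys[j, 2])^2 + (a$z - lys[j, 3])^2)
    ov <- .VDW[[lel]] + .VDW[.element_of(a$atom)] - d
    hit <- which(ov > th)
    for (i in hit) {
      rows[[length(rows) + 1L]] <- data.frame(
        res_index = match(paste(a$resno[i], a$ins[i]),
                          paste(residue_table(peptide)$resno,
                                residue_table(peptide)$ins)),
        resno = a$resno[i], atom = a$atom[i],
        lys_atom = rownames(lys)[j], distance = d[i],
        overlap = unname(ov[i]), stringsAsFactors = FALSE)
    }
  }
  contacts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(res_index = integer(), resno = integer(), atom = character(),
               lys_atom = character(), distance = numeric(),
               overlap = numeric(), stringsAsFactors = FALSE)
  clashing <- nrow(contacts) > 0L
  structure(list(contacts = contacts,
                 worst_overlap = if (clashing) max(contacts$overlap) else 0,
                 clashing = clashing,
                 verdict = if (clashing) "blocked by the filter lysine"
                   else "passes the filter-lysine check"),
            class = "nes_clash_report")
}

#' @export
print.nes_clash_report <- function(x, ...) {
  cat(sprintf("Clash filter: %s (worst overlap %.2f A, %d contact(s))\n",
              x$verdict, x$worst_overlap, nrow(x$contacts)))
  invisible(x)
}

#' Three-criterion NES verdict
#'
#' An active NES (1) presents 3-5 hydrophobic anchors into 3-5 groove
#' pockets, (2) has the conserved one turn of helix with its helix-strand
#' transition in the central groove, and (3) has a backbone conformation
#' that hydrogen bonds with the filter lysine - which also implies not
#' clashing with its side chain. Each criterion is reported with its
#' evidence and an overall call is made.
#'
#' @param peptide `nes_peptide` in the reference frame.
#' @param frame `nes_frame`.
#' @param turn `nes_turn` or NULL (computed via [classify_peptide()] when
#'   omitted).
#' @param map optional precomputed `nes_anchor_map`.
#' @param hbonds,clash optional precomputed results.
#' @return object of class `nes_criteria`: list `criteria` (data frame
#'   `criterion`, `pass`, `evidence`), `active` (logical), plus the
#'   component results.
#' @export
nes_criteria_report <- function(peptide, frame, turn = NULL, map = NULL,
                                hbonds = NULL, clash = NULL) {
  if (is.null(map)) map <- assign_anchors(peptide, frame)
  if (is.null(turn)) turn <- classify_peptide(peptide)$turn
  if (is.null(hbonds)) hbonds <- detect_filter_hbonds(peptide, frame)
  if (is.null(clash)) clash <- clash_filter(peptide, frame)
  n_pockets <- sum(map$occupancy)
  c1 <- !map$insufficient && n_pockets >= 3L && n_pockets <= 5L
  c2 <- !is.null(turn)
  c3 <- nrow(hbonds$hbonds) >= 1L && !clash$clashing
  criteria <- data.frame(
    criterion = c("anchors in 3-5 pockets", "conserved one-turn helix",
                  "filter-lysine hydrogen bonding without clash"),
    pass = c(c1, c2, c3),
    evidence = c(
      sprintf("%d pocket(s) occupied (%s), orientation %s", n_pockets,
              paste(names(map$occupancy)[map$occupancy], collapse = ","),
              map$orientation),
      if (c2) sprintf("turn at residues %d-%d (%s), psi %s", turn$span[1],
                      turn$span[4], turn$direction,
                      paste(sprintf("%.1f", turn$psi), collapse = ", "))
      else "no conserved turn located",
      sprintf("%d hydrogen bond(s)%s; %s", nrow(hbonds$hbonds),
              if (!is.null(hbonds$niche))
                paste0(", ", hbonds$niche$type, " motif") else "",
              clash$verdict)),
    stringsAsFactors = FALSE)
  structure(list(criteria = criteria, active = all(criteria$pass),
                 map = map, turn = turn, hbonds = hbonds, clash = clash),
            class = "nes_criteria")
}

#' @export
print.nes_criteria <- function(x, ...) {
  cat("NES criteria:", if (x$active) "ACTIVE NES" else "not an active NES",
      "\n")
  for (i in seq_len(nrow(x$criteria)))
    cat(sprintf("  [%s] %s: %s\n",
                if (x$criteria$pass[i]) "pass" else "FAIL",
                x$criteria$criterion[i], x$criteria$evidence[i]))
  invisible(x)
}
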
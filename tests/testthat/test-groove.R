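mock_and_frame <- function(cl, ...) {
  mock <- build_mock_complex(build_class_template(cl), ...)
  list(mock = mock, frame = build_pocket_frame(mock))
}

test_that("pocket frames carry planted centers and require the lysine NZ", {
  mf <- mock_and_frame("1a")
  expect_equal(nrow(mf$frame$centers), 5L)
  expect_true(all(dist(mf$frame$centers) > 3))
  expect_equal(mf$frame$lysine$resno, 568L)
  broken <- mf$mock
  broken$lysine$atoms <- broken$lysine$atoms["CE", , drop = FALSE]
  expect_error(build_pocket_frame(broken), "NZ")
})

test_that("frames built from full complexes select groove residues and anchors", {
  # assemble a synthetic two-chain complex: template peptide as the NES
  # chain plus a CRM1-like chain holding a lysine near the peptide
  mock <- build_mock_complex(build_class_template("1a"))
  pep <- mock$peptide
  nz <- mock$lysine$atoms["NZ", ]
  ce <- mock$lysine$atoms["CE", ]
  crm <- data.frame(resno = 579L, ins = "", resname = "LYS",
                    atom = c("N", "CA", "C", "O", "CB", "CE", "NZ"),
                    x = c(nz[1] + c(4, 3.5, 4.5, 5), ce[1] + 0.5, ce[1], nz[1]),
                    y = c(nz[2] + c(4, 3.5, 4.5, 5), ce[2] + 0.5, ce[2], nz[2]),
                    z = c(nz[3] + c(4, 3.5, 4.5, 5), ce[3] + 0.5, ce[3], nz[3]),
                    stringsAsFactors = FALSE)
  cx <- structure(list(chains = list(B = pep,
                                     A = peptide_structure("A", crm)),
                       source = "synthetic"), class = "nes_complex")
  a1 <- mock$pocket_anchor_res
  fr <- build_pocket_frame(cx, nes_chain = "B", crm1_chain = "A",
                           anchor_resnos = unname(a1), lysine_resno = 579)
  # the class-1a reference has no Phi0, so P0 carries no reference anchor
  expect_equal(sum(!is.na(fr$centers[, 1])), 4L)
  expect_true(all(is.na(fr$centers["P0", ])))
  expect_true(579 %in% fr$groove_residues)
  expect_error(build_pocket_frame(cx, nes_chain = "B", crm1_chain = "A",
                                  anchor_resnos = c(99, a1[-1]),
                                  lysine_resno = 579), "99")
})

test_that("anchors assign to their planted pockets with plus/minus orientation", {
  mf <- mock_and_frame("1a")
  map <- assign_anchors(mf$mock$peptide, mf$frame)
  expect_equal(map$orientation, "plus")
  expect_false(map$insufficient)
  expect_equal(sum(map$occupancy), 4L)
  expect_true(all(map$assignments$distance < 1e-9))
  mfm <- mock_and_frame("1a-R")
  expect_equal(assign_anchors(mfm$mock$peptide, mfm$frame)$orientation,
               "minus")
  # a peptide translated out of the groove assigns nothing
  far <- mf$mock$peptide
  far$atoms$x <- far$atoms$x + 20
  map_far <- assign_anchors(far, mf$frame)
  expect_equal(nrow(map_far$assignments), 0L)
  expect_true(map_far$insufficient)
})

test_that("anchor assignment is stable under atom-order permutation", {
  mf <- mock_and_frame("2")
  base <- assign_anchors(mf$mock$peptide, mf$frame)$assignments
  shuf <- mf$mock$peptide
  set.seed(1)
  shuf$atoms <- shuf$atoms[sample(nrow(shuf$atoms)), ]
  shuf <- peptide_structure(shuf$chain_id, shuf$atoms)
  perm <- assign_anchors(shuf, mf$frame)$assignments
  expect_equal(perm[order(perm$pocket), ], base[order(base$pocket), ],
               ignore_attr = TRUE)
})

test_that("displacements recover planted translations exactly", {
  mf <- mock_and_frame("1a")
  map <- assign_anchors(mf$mock$peptide, mf$frame)
  d0 <- anchor_displacements(map, mf$mock$peptide, mf$frame)
  expect_true(all(d0$displacement < 1e-9))
  # translate the peptide 1.0 A along x: every displacement becomes 1.0
  moved <- mf$mock$peptide
  moved$atoms$x <- moved$atoms$x + 1.0
  map1 <- assign_anchors(moved, mf$frame)
  d1 <- anchor_displacements(map1, moved, mf$frame)
  expect_equal(d1$displacement, rep(1, nrow(d1)), tolerance = 1e-9)
  # cohort statistics recover a planted mean within numerical precision
  tables <- lapply(c(0.5, 1.0, 1.5), function(dx) {
    m <- mf$mock$peptide; m$atoms$x <- m$atoms$x + dx
    anchor_displacements(assign_anchors(m, mf$frame), m, mf$frame)
  })
  co <- displacement_cohort(tables)
  expect_equal(co$mean, rep(1, nrow(co)), tolerance = 1e-9)
  expect_equal(co$sd, rep(sd(c(0.5, 1, 1.5)), nrow(co)), tolerance = 1e-9)
})

test_that("filter-lysine hydrogen bonds and niche motifs are detected by geometry", {
  mf <- mock_and_frame("1a")
  hb <- detect_filter_hbonds(mf$mock$peptide, mf$frame)
  expect_setequal(hb$hbonds$res_index, mf$mock$hbond_residues)
  expect_equal(hb$niche$type, "niche3")    # donors at spacing 2
  expect_true(all(hb$hbonds$distance <= 3.5))
  expect_true(all(hb$hbonds$angle >= 90))
  # moving the lysine away from the donors breaks the bonds
  fr_far <- mf$frame
  Oc <- atom_coords(mf$mock$peptide, "O")
  omid <- colMeans(Oc[mf$mock$hbond_residues, ])
  u <- fr_far$lysine$atoms["NZ", ] - omid
  u <- u / sqrt(sum(u^2))
  fr_far$lysine$atoms <- sweep(fr_far$lysine$atoms, 2, -1.5 * u)
  hb_far <- detect_filter_hbonds(mf$mock$peptide, fr_far)
  expect_equal(nrow(hb_far$hbonds), 0L)
  # expected donors for a (+) NES are the Phi2+1 and Phi3 carbonyls
  tp <- build_class_template("1a")
  a1 <- sort(attr(tp, "anchors0")) + 1L
  anchors <- c(phi1 = a1[1], phi2 = a1[2], phi3 = a1[3], phi4 = a1[4])
  hb2 <- detect_filter_hbonds(mf$mock$peptide, mf$frame, anchors = anchors,
                              orientation = "plus")
  expect_equal(hb2$expected, paste(c(a1[2] + 1L, a1[3]), collapse = ","))
  expect_true(hb2$expected_satisfied)
  # a class-4 mock coordinates donors at spacing 3: niche4
  mf4 <- mock_and_frame("4")
  expect_equal(detect_filter_hbonds(mf4$mock$peptide, mf4$frame)$niche$type,
               "niche3")
})

test_that("the clash filter separates over-long helices from true NESs", {
  # Hexokinase-2-like: an all-helix peptide one turn longer than the
  # class-3 NES helix, superposed on the shared helix, hits the lysine
  mf3 <- mock_and_frame("3")
  expect_false(clash_filter(mf3$mock$peptide, mf3$frame)$clashing)
  decoy <- make_plus_decoy(mf3$mock)
  rep <- clash_filter(decoy, mf3$frame)
  expect_true(rep$clashing)
  expect_gt(rep$worst_overlap, 0.4)
  expect_true(all(rep$contacts$overlap > 0.4))
  # DEAF1-like: a (-) helix over-extended at its N-terminus
  mfm <- mock_and_frame("1a-R")
  expect_false(clash_filter(mfm$mock$peptide, mfm$frame)$clashing)
  expect_true(clash_filter(make_minus_decoy(mfm$mock), mfm$frame)$clashing)
  # guarded (+) frame: helix-strand true NES clears, continuation clashes
  mfg <- mock_and_frame("1a", guard = TRUE)
  expect_false(clash_filter(mfg$mock$peptide, mfg$frame)$clashing)
  expect_true(clash_filter(make_plus_decoy(mfg$mock), mfg$frame)$clashing)
})

test_that("geometric reports are invariant under joint rigid transforms", {
  set.seed(20)
  mf <- mock_and_frame("1a")
  base_hb <- detect_filter_hbonds(mf$mock$peptide, mf$frame)$hbonds
  base_map <- assign_anchors(mf$mock$peptide, mf$frame)$assignments
  for (i in 1:3) {
    tr <- crmnes:::random_rigid_transform()
    pep <- transform_peptide(mf$mock$peptide, tr)
    fr <- mf$frame
    fr$centers <- apply_transform(fr$centers, tr)
    fr$anchor_ca <- apply_transform(fr$anchor_ca, tr)
    fr$lysine$atoms <- apply_transform(fr$lysine$atoms, tr)
    rownames(fr$lysine$atoms) <- rownames(mf$frame$lysine$atoms)
    hb <- detect_filter_hbonds(pep, fr)$hbonds
    expect_equal(hb$distance, base_hb$distance, tolerance = 1e-6)
    expect_equal(hb$angle, base_hb$angle, tolerance = 1e-6)
    mp <- assign_anchors(pep, fr)$assignments
    expect_equal(mp$pocket, base_map$pocket)
    expect_equal(mp$distance, base_map$distance, tolerance = 1e-6)
  }
})

test_that("the three-criterion report reproduces the active-NES logic", {
  mf <- mock_and_frame("1b")
  crit <- nes_criteria_report(mf$mock$peptide, mf$frame)
  expect_true(crit$active)
  expect_equal(nrow(crit$criteria), 3L)
  expect_true(all(crit$criteria$pass))
  # an all-strand peptide in the same frame fails the turn criterion
  neg <- build_backbone(build_negative_template("strand"))
  critn <- nes_criteria_report(neg, mf$frame)
  expect_false(critn$active)
  expect_false(critn$criteria$pass[2])
  # a decoy fails via the clash in criterion 3
  mf3 <- mock_and_frame("3")
  critd <- nes_criteria_report(make_plus_decoy(mf3$mock), mf3$frame)
  expect_false(critd$active)
  expect_false(critd$criteria$pass[3])
})

test_that("pocket frames survive a JSON round trip", {
  mf <- mock_and_frame("1a")
  tmp <- tempfile(fileext = ".json")
  frame_to_json(mf$frame, tmp)
  back <- frame_from_json(tmp)
  expect_equal(back$centers, mf$frame$centers, tolerance = 1e-9)
  expect_equal(back$lysine$atoms, mf$frame$lysine$atoms, tolerance = 1e-9)
  expect_equal(back$thresholds$hbond_dist, mf$frame$thresholds$hbond_dist)
  hb1 <- detect_filter_hbonds(mf$mock$peptide, mf$frame)$hbonds
  hb2 <- detect_filter_hbonds(mf$mock$peptide, back)$hbonds
  expect_equal(hb1, hb2, tolerance = 1e-9)
})
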
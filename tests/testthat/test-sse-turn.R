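test_that("secondary structure labels match the generating architectures", {
  # all-alpha: interior residues H, with i->i+4 carbonyl contacts short
  p <- build_backbone(backbone_spec(strrep("A", 12), -57, -47))
  d <- compute_dihedrals(p)
  expect_true(all(assign_sse(d, p) == "H"))
  Oc <- atom_coords(p, "O"); Nc <- atom_coords(p, "N")
  expect_lt(sqrt(sum((Oc[3, ] - Nc[7, ])^2)),
            sqrt(sum((Oc[3, ] - Nc[6, ])^2)) + 1)
  # 3-10 helix: G, with the i->i+3 contact short and i->i+4 lost
  p3 <- build_backbone(backbone_spec(strrep("A", 8), -49, -26))
  d3 <- compute_dihedrals(p3)
  expect_true(all(assign_sse(d3, p3) == "G"))
  expect_lt(sqrt(sum((atom_coords(p3, "O")[2, ] -
                        atom_coords(p3, "N")[5, ])^2)), 3.5)
  expect_gt(sqrt(sum((atom_coords(p3, "O")[2, ] -
                        atom_coords(p3, "N")[6, ])^2)), 3.5)
  # strand
  pe <- build_backbone(backbone_spec(strrep("A", 8), -120, 130))
  expect_true(all(assign_sse(compute_dihedrals(pe), pe) == "E"))
})

test_that("a type I beta-turn is labelled T with the CA(i)-CA(i+3) check", {
  sp <- backbone_spec("AAAAAAAA", c(-120, -120, -120, -60, -90, -120, -120, -120),
                      c(130, 130, 130, -30, 0, 130, 130, 130))
  p <- build_backbone(sp)
  sse <- assign_sse(compute_dihedrals(p), p)
  expect_equal(sse[4:5], c("T", "T"))
  ca <- atom_coords(p, "CA")
  expect_lt(sqrt(sum((ca[3, ] - ca[6, ])^2)), 7)
})

test_that("missing O atoms default helix typing to H with a warning flag", {
  p <- build_backbone(backbone_spec(strrep("A", 8), -49, -26))
  p$atoms <- p$atoms[p$atoms$atom != "O", ]
  sse <- assign_sse(compute_dihedrals(p), p)
  expect_true(all(sse == "H"))
  expect_match(attr(sse, "warnings"), "missing O")
})

test_that("SSE assignment is invariant under rigid transforms", {
  set.seed(10)
  p <- build_backbone(build_class_template("4"))
  base <- as.character(assign_sse(compute_dihedrals(p), p))
  for (i in 1:3) {
    q <- transform_peptide(p, crmnes:::random_rigid_transform())
    expect_identical(as.character(assign_sse(compute_dihedrals(q), q)), base)
  }
})

test_that("the turn detector accepts the printed HDAC5 series as a (+) turn", {
  psi <- c(-60, -45, -43.5, -21.7, -1.3, 133.8, 140)
  d <- structure(data.frame(resno = 1:7, ins = "", resname = "ALA",
                            phi = -60, psi = psi, omega = 180),
                 class = c("nes_dihedrals", "data.frame"))
  turn <- find_conserved_turn(d, c(phi2 = 3L, phi3 = 6L))
  expect_false(is.null(turn))
  expect_equal(turn$direction, "plus")
  expect_equal(turn$psi, c(-43.5, -21.7, -1.3, 133.8))
  prog <- psi_progression(turn)
  expect_true(prog$monotone)
})

test_that("the turn detector accepts the printed CPEB4 series as a (-) turn", {
  psi <- c(120, 125, 111.5, 16.5, -31.0, -40.2, -45)
  d <- structure(data.frame(resno = 1:7, ins = "", resname = "ALA",
                            phi = -100, psi = psi, omega = 180),
                 class = c("nes_dihedrals", "data.frame"))
  # chain order runs phi3 ... phi2 for a (-) NES
  turn <- find_conserved_turn(d, c(phi2 = 4L, phi3 = 1L))
  expect_false(is.null(turn))
  expect_equal(turn$direction, "minus")
  expect_equal(turn$psi, c(111.5, 16.5, -31.0, -40.2))
  expect_true(psi_progression(turn)$monotone)
})

test_that("turn detection fails on non-NES architectures and bad anchors", {
  p <- build_backbone(build_negative_template("strand"))
  d <- compute_dihedrals(p)
  expect_null(find_conserved_turn(d, c(phi2 = 4L, phi3 = 8L)))
  p2 <- build_backbone(build_negative_template("loop"))
  expect_null(find_conserved_turn(compute_dihedrals(p2),
                                  c(phi2 = 4L, phi3 = 8L)))
  expect_error(find_conserved_turn(d, c(phi2 = 4L)), "turn undefined")
  # an unbroken ideal helix has no strand transition mid-chain
  ph <- build_backbone(backbone_spec(strrep("A", 14), -57, -47))
  expect_null(find_conserved_turn(compute_dihedrals(ph),
                                  c(phi2 = 4L, phi3 = 7L)))
})

test_that("psi progression allows one small violation and rejects large ones", {
  mk <- function(psi, dir) list(psi = psi, direction = dir)
  expect_true(psi_progression(mk(c(-40, -44, -10, 120), "plus"))$monotone)
  expect_false(psi_progression(mk(c(-40, -60, -10, 120), "plus"))$monotone)
  expect_true(psi_progression(mk(c(120, 10, -30, -45), "minus"))$monotone)
  expect_false(psi_progression(mk(c(120, -45, -30, -45), "minus"))$monotone)
})

test_that("the turn detector accepts every class template in the library", {
  for (cl in nes_classes()$class) {
    res <- classify_peptide(build_backbone(build_class_template(cl)))
    expect_false(is.null(res$turn), label = paste("turn for class", cl))
  }
})
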
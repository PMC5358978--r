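test_that("the pattern library holds the eleven classes with consistent gaps", {
  lib <- nes_classes()
  expect_equal(nrow(lib), 11L)
  expect_setequal(lib$class, c("1a", "1b", "1c", "1d", "2", "3", "4",
                               "1a-R", "1b-R", "1c-R", "1d-R"))
  # spacings printed in the structural literature
  expect_equal(nes_class_gaps("1b")[[1]], c(2L, 2L, 1L))
  expect_equal(nes_class_gaps("2")[[1]], c(1L, 2L, 1L))
  expect_equal(nes_class_gaps("3")[[1]], c(2L, 3L, 2L))
  expect_equal(nes_class_gaps("1d")[[1]], c(2L, 3L, 1L))
  expect_equal(nes_class_gaps("4")[[1]], c(2L, 3L, 2L, 3L))
  # reversed classes carry the forward gaps read backwards
  for (cls in c("1a", "1b", "1c", "1d")) {
    expect_equal(nes_class_gaps(paste0(cls, "-R"))[[1]],
                 rev(nes_class_gaps(cls)[[1]]))
  }
  # symmetry is gap-palindromy; anchors 4-5
  expect_equal(lib$class[lib$symmetric], c("2", "3"))
  expect_true(all(lib$n_anchors %in% 4:5))
  expect_equal(lib$n_anchors, vapply(lib$gaps, length, 1L) + 1L)
})

test_that("printed NES sequences match their assigned classes at the known anchors", {
  # X11L2 matches class 3 and the new class 4 pattern
  m3 <- scan_nes("SSLQELVQQFEALPGDLV", classes = "3")
  expect_equal(m3$anchors, "2,5,9,12")          # L57, L60, F64, L67
  m4 <- scan_nes("SSLQELVQQFEALPGDLV", classes = "4")
  expect_equal(m4$anchors, "2,5,9,12,16")       # ... + L71
  expect_match(m3$alt_labeling, "P4 unused")
  # FMRP class 2 at L430/L432/L435/I437
  mf <- scan_nes("YLKEVDQLRLERLQI", classes = "2")
  expect_true("7,9,12,14" %in% mf$anchors)
  # HDAC5 matches class 1b (but binds as 1a - a structure-level fact)
  mh <- scan_nes("EAETVSAMALLSVG", classes = "1b")
  expect_equal(mh$anchors, "4,7,10,12")         # V1086, M1089, L1092, V1094
  # PKI is the canonical class 1a NES
  mp <- scan_nes("NELALKLAGLDIN", classes = "1a")
  expect_true("2,6,9,11" %in% mp$anchors)
  # DEAF1 false positive matches class 1a-R
  md <- scan_nes("SWLYLEEMVNSLLNTAQQ", classes = "1a-R")
  expect_true("2,4,7,11" %in% md$anchors)
})

test_that("input validation names the offending position and accepts case", {
  expect_error(scan_nes("ACDEFGHIKLMNPQRSTVWYX"), "position 21")
  expect_error(scan_nes("LXXL"), "'X' at position 2")
  expect_error(scan_nes("LAAL*"), "position 5")
  expect_equal(nrow(scan_nes("", classes = "1a")), 0L)
  lower <- scan_nes(tolower("SSLQELVQQFEALPGDLV"), classes = "3")
  upper <- scan_nes("SSLQELVQQFEALPGDLV", classes = "3")
  expect_identical(lower, upper)
  expect_equal(nrow(scan_nes(strrep("A", 30))), 0L)
})

test_that("scanner agrees with the brute-force enumerator on random sequences", {
  set.seed(42)
  for (rep in 1:40) {
    s <- random_aa_seq(sample(12:200, 1))
    got <- scan_nes(s)
    want <- bf_scan(s)
    expect_identical(match_key(got), match_key(want))
  }
})

test_that("reversed-class matches mirror forward matches on the reversed sequence", {
  set.seed(7)
  for (rep in 1:25) {
    s <- random_aa_seq(60)
    direct <- scan_nes(s, classes = c("1a-R", "1b-R", "1c-R", "1d-R"))
    via_rev <- scan_nes_reverse(s, c("1a", "1b", "1c", "1d"))
    expect_identical(match_key(direct), match_key(via_rev))
    # palindromic class 2 is unchanged under reversal
    expect_identical(match_key(scan_nes(s, "2")),
                     match_key(scan_nes_reverse(s, "2")))
  }
  expect_error(scan_nes_reverse("LALALALA", "4"), "no reversed variant")
  expect_error(scan_nes_reverse("LALALALA", "1a-R"), "forward labels")
})

test_that("extending a sequence never removes existing matches", {
  set.seed(11)
  for (rep in 1:15) {
    s <- random_aa_seq(50)
    base <- scan_nes(s)
    ext <- scan_nes(paste0("AAA", s, "AAA"))
    shifted <- base
    if (nrow(shifted)) {
      shifted$start <- shifted$start + 3L
      shifted$anchors <- vapply(strsplit(shifted$anchors, ","), function(a)
        paste(as.integer(a) + 3L, collapse = ","), "")
    }
    expect_true(all(match_key(shifted) %in% match_key(ext)))
  }
})

test_that("amphipathic annotation implements the three helical-face offset templates", {
  # class-3 anchors i, i+3, i+7, i+10 lie on one helix face
  expect_true(is_amphipathic(strsplit("LAALAAALAAL", "")[[1]], c(0, 3, 7, 10)))
  # i, i+4, i+7
  expect_true(is_amphipathic(strsplit("LAAALAALA", "")[[1]], c(0, 4, 7)))
  # class-2 spacing 0,2,5,7 fits no template
  expect_false(is_amphipathic(strsplit("LALAALAL", "")[[1]], c(0, 2, 5, 7)))
  # fewer than 3 positions can never satisfy a template
  expect_false(is_amphipathic(strsplit("LAAL", "")[[1]], c(0, 3)))
  # an extra Phi letter inside the window can complete a face
  expect_true(is_amphipathic(strsplit("LALLAAAL", "")[[1]], c(0, 2, 7)))
})

test_that("overlap control and the best-per-locus reducer follow the documented order", {
  s <- "SSLQELVQQFEALPGDLV"
  all_m <- scan_nes(s, classes = c("3", "4"))
  expect_equal(nrow(all_m), 2L)
  red <- reduce_best_locus(all_m)
  expect_equal(nrow(red), 1L)
  expect_equal(red$class, "4")        # more anchors wins
  # no-overlap mode keeps the earliest window per class
  s2 <- strrep("L", 30)
  with_ov <- scan_nes(s2, classes = "2", allow_overlaps = TRUE)
  no_ov <- scan_nes(s2, classes = "2", allow_overlaps = FALSE)
  expect_gt(nrow(with_ov), nrow(no_ov))
  starts <- no_ov$start
  expect_true(all(diff(starts) >= 8L))  # class-2 window is 8 residues
})

test_that("scanning is deterministic", {
  set.seed(3)
  s <- random_aa_seq(150)
  expect_identical(scan_nes(s), scan_nes(s))
})
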
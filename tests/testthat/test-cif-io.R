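oneAtomCif <- makeCifText(atomRows = "N1 N 0.5 0.5 0.5")

test_that("a one-atom orthogonal-cell file parses to the scaled position", {
  s <- parseCif(oneAtomCif, "one.cif")
  expect_identical(nAtoms(s), 1L)
  at <- atomRecords(s)
  expect_identical(at$identifier, "N1")
  expect_identical(at$symbol, "N")
  expect_identical(at$atomIndex, 1L)
  expect_identical(c(at$x, at$y, at$z), c(5, 5, 5))
  expect_equal(radiusOf("N"), at$radius)
  expect_identical(cellParameters(unitCellOf(s)),
                   c(a = 10, b = 10, c = 10, alpha = 90, beta = 90, gamma = 90))
})

test_that("files without an atom loop or cell items are rejected by name", {
  expect_error(parseCif(c("data_x", "_cell_length_a 10"), "broken.cif"),
               "no positional data.*broken\\.cif")
  noCell <- makeCifText(atomRows = "N1 N 0.5 0.5 0.5")
  noCell <- noCell[!grepl("_cell_length_b", noCell)]
  expect_error(parseCif(noCell, "nocell.cif"),
               "incomplete cell.*_cell_length_b.*nocell\\.cif")
  badNum <- makeCifText(atomRows = "N1 N 0.5 oops 0.5")
  expect_error(parseCif(badNum, "badnum.cif"), "unparseable numeric")
})

test_that("atom count equals the number of loop data rows (no silent drops)", {
  rows <- sprintf("C%d C %.3f 0.1 0.2", 1:7, seq(0.1, 0.7, by = 0.1))
  s <- parseCif(makeCifText(atomRows = rows), "seven.cif")
  expect_identical(nAtoms(s), 7L)
  expect_identical(atomRecords(s)$identifier, paste0("C", 1:7))
})

test_that("standard-uncertainty suffixes and label suffixes are handled", {
  rows <- c("C1A C 0.1234(5) 0.20(1) 0.3",
            "O2 O 0.5 0.6 0.70(2)")
  s <- parseCif(makeCifText(cell = c("10.000(2)", "10.0(1)", 10, 90, 90, "90.00(5)"),
                            atomRows = rows), "su.cif")
  at <- atomRecords(s)
  expect_identical(at$identifier[1], "C1A")   # suffix retained in identifier
  expect_identical(at$symbol[1], "C")         # leading letters
  expect_identical(at$atomIndex[1], 1L)       # first digit run
  expect_equal(at$fx[1], 0.1234)
  expect_equal(at$fz[2], 0.70)
  expect_equal(cellParameters(unitCellOf(s))[["a"]], 10)
})

test_that("loop columns are mapped by tag name in any declared order", {
  reordered <- makeCifText(
    atomRows = "0.5 extra N1 0.25 0.125 N",
    tags = c("_atom_site_fract_z", "_atom_site_disorder_group",
             "_atom_site_label", "_atom_site_fract_x",
             "_atom_site_fract_y", "_atom_site_type_symbol"))
  s <- parseCif(reordered, "reordered.cif")
  at <- atomRecords(s)
  expect_identical(at$identifier, "N1")
  expect_identical(at$symbol, "N")
  expect_identical(c(at$fx, at$fy, at$fz), c(0.25, 0.125, 0.5))
})

test_that("symbol falls back to label letters when type_symbol is absent", {
  noType <- makeCifText(
    atomRows = "Au3 0.1 0.2 0.3",
    tags = c("_atom_site_label", "_atom_site_fract_x",
             "_atom_site_fract_y", "_atom_site_fract_z"))
  s <- parseCif(noType, "notype.cif")
  expect_identical(atomRecords(s)$symbol, "Au")
  expect_identical(atomRecords(s)$atomIndex, 3L)
})

test_that("type_symbol charge annotations are stripped", {
  s <- parseCif(makeCifText(atomRows = "O1 O2- 0.1 0.2 0.3"), "charge.cif")
  expect_identical(atomRecords(s)$symbol, "O")
})

test_that("Cartesian positions are invariant to cell-item header order", {
  rows <- "S1 S 0.3 0.6 0.9"
  s1 <- parseCif(makeCifText(cell = c(9, 10, 11, 80, 95, 110),
                             atomRows = rows, cellOrder = 1:6), "a.cif")
  s2 <- parseCif(makeCifText(cell = c(9, 10, 11, 80, 95, 110),
                             atomRows = rows, cellOrder = c(4, 2, 6, 1, 3, 5)),
                 "b.cif")
  expect_identical(atomRecords(s1)[, c("x", "y", "z")],
                   atomRecords(s2)[, c("x", "y", "z")])
})

test_that("only the first data block with positional data is parsed", {
  two <- c("data_first", "_cell_length_a 10", "_cell_length_b 10",
           "_cell_length_c 10", "_cell_angle_alpha 90", "_cell_angle_beta 90",
           "_cell_angle_gamma 90", "loop_", "_atom_site_label",
           "_atom_site_type_symbol", "_atom_site_fract_x",
           "_atom_site_fract_y", "_atom_site_fract_z", "N1 N 0.5 0.5 0.5", "",
           "data_second", "_cell_length_a 20", "_cell_length_b 20",
           "_cell_length_c 20", "_cell_angle_alpha 90", "_cell_angle_beta 90",
           "_cell_angle_gamma 90", "loop_", "_atom_site_label",
           "_atom_site_type_symbol", "_atom_site_fract_x",
           "_atom_site_fract_y", "_atom_site_fract_z", "O1 O 0.1 0.1 0.1", "")
  s <- parseCif(two, "two.cif")
  expect_identical(atomRecords(s)$identifier, "N1")
  expect_equal(cellParameters(unitCellOf(s))[["a"]], 10)
})

test_that("duplicate Cartesian positions violate the structure invariant", {
  dup <- makeCifText(atomRows = c("N1 N 0.5 0.5 0.5", "N2 N 0.5 0.5 0.5"))
  expect_error(parseCif(dup, "dup.cif"), "same Cartesian position")
})

test_that("element queries respect canonical case and file order", {
  rows <- c("N1 N 0.1 0.1 0.1", "S1 S 0.3 0.3 0.3", "S2 S 0.6 0.6 0.6")
  s <- parseCif(makeCifText(atomRows = rows), "q.cif")
  expect_identical(getElementAtoms(s, "S")$identifier, c("S1", "S2"))
  expect_identical(getElementAtoms(s, "s")$identifier, c("S1", "S2"))
  expect_identical(nrow(getElementAtoms(s, "Au")), 0L)
  expect_true(containsAtom(s, "N"))
  expect_false(containsAtom(s, "Hg"))
  # consistency over the whole element set plus absent ones
  for (el in c(unique(atomRecords(s)$symbol), "Au", "Xx"))
    expect_identical(containsAtom(s, el),
                     nrow(getElementAtoms(s, el)) > 0)
})

test_that("getParticularAtom retrieves by identifier or fails loudly", {
  s <- parseCif(oneAtomCif, "one.cif")
  expect_identical(getParticularAtom(s, "N1")$symbol, "N")
  expect_error(getParticularAtom(s, "N2"), "atom not found")
})

test_that("case-mangled element symbols parse to the same structure", {
  up <- makeCifText(atomRows = c("AU1 AU 0.1 0.1 0.1", "N1 N 0.5 0.5 0.5"))
  s <- parseCif(up, "case.cif")
  expect_identical(getElementAtoms(s, "Au")$identifier, "AU1")
  expect_equal(getElementAtoms(s, "Au")$radius, radiusOf("Au"))
})

test_that("readCif reads from disk and records the source path", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(oneAtomCif, f)
  s <- readCif(f)
  expect_identical(s@sourcePath, f)
  expect_identical(nAtoms(s), 1L)
  expect_error(readCif(file.path(tempdir(), "absent.cif")), "no such file")
})
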
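rN <- radiusOf("N"); rAu <- radiusOf("Au")

test_that("radius search honours the boundary and excludes the target", {
  s <- parseCif(makeCifText(cell = c(20, 20, 20, 90, 90, 90), atomRows = c(
    "N1 N 0 0 0",
    "C1 C 0.15 0 0",     # exactly 3.0 A
    "O1 O 0 0.16 0")),   # 3.2 A
    "radius.cif")
  near <- getAtomsInRadius(s, "N1", 3.0)
  expect_identical(near$identifier, "C1")   # boundary included, O1 excluded
  expect_equal(near$distance, 3.0)
  expect_identical(nrow(getAtomsInRadius(s, "N1", 0)), 0L)
  stranger <- getParticularAtom(s, "N1"); stranger$x <- 99
  expect_error(getAtomsInRadius(s, stranger, 3), "unknown target")
})

test_that("radius search agrees with the brute-force filter on random input", {
  for (seed in c(2, 9, 31)) {
    s <- randomStructure(seed, nAtoms = 40)
    at <- atomRecords(s)
    target <- at$identifier[1]
    got <- sort(getAtomsInRadius(s, target, 3.0)$identifier)
    expect_identical(got, bruteForceRadius(s, target, 3.0))
  }
})

test_that("three-way classification distinguishes bound, present and absent metals", {
  cfg <- quietCoordConfig()
  # bound: Au at r(N)+r(Au)+0.5 from the central N (satisfies the criterion)
  fxB <- buildStructure(fixtureSpec(
    metalContacts = list(list(symbol = "Au", distance = rN + rAu + 0.5)),
    seed = 31))
  mB <- identifyMotifs(fxB$structure)[[1]]
  repB <- classifyMotif(fxB$structure, mB, cfg, checkReach = FALSE)
  expect_identical(reportCategory(repB), "N_BOUND")
  expect_identical(boundMetals(repB)$symbol, "Au")
  expect_equal(boundMetals(repB)$distance, rN + rAu + 0.5, tolerance = 2e-6)
  expect_identical(reportCategory(repB), fxB$ledger$categories)

  # present but unbound: Au 8 A away, outside the 3 A wave
  fxU <- buildStructure(fixtureSpec(
    cell = unitCell(24, 24, 24, 80, 95, 110),
    metalContacts = list(list(symbol = "Au", distance = 8)), seed = 32))
  mU <- identifyMotifs(fxU$structure)[[1]]
  repU <- classifyMotif(fxU$structure, mU, cfg, checkReach = FALSE)
  expect_identical(reportCategory(repU), "METAL_PRESENT_UNBOUND")
  expect_identical(nrow(boundMetals(repU)), 0L)
  expect_identical(reportCategory(repU), fxU$ledger$categories)

  # metal-free
  fxN <- buildStructure(fixtureSpec(decoys = 4, seed = 33))
  mN <- identifyMotifs(fxN$structure)[[1]]
  repN <- classifyMotif(fxN$structure, mN, cfg, checkReach = FALSE)
  expect_identical(reportCategory(repN), "NO_METAL")
  expect_identical(reportCategory(repN), fxN$ledger$categories)
})

test_that("coordination boundary: exactly at r(N)+r(M)+f is bound", {
  d <- rN + rAu + 1      # 3.07 > searchRadius 3, so use a wider wave
  s <- parseCif(makeCifText(cell = c(20, 20, 20, 90, 90, 90), atomRows = c(
    "N1 N 0 0 0",
    "S1 S 0.079 0 0",
    "S2 S 0 0.079 0",
    sprintf("Au1 Au 0 0 %.6f", d / 20))), "bound.cif")
  m <- identifyMotifs(s)[[1]]
  cfg <- quietCoordConfig(searchRadius = 3.5)
  rep <- classifyMotif(s, m, cfg, checkReach = FALSE)
  expect_identical(reportCategory(rep), "N_BOUND")
  expect_equal(boundMetals(rep)$distance, d)
  # a hair beyond: unbound
  s2 <- parseCif(makeCifText(cell = c(20, 20, 20, 90, 90, 90), atomRows = c(
    "N1 N 0 0 0",
    "S1 S 0.079 0 0",
    "S2 S 0 0.079 0",
    sprintf("Au1 Au 0 0 %.6f", (d + 0.001) / 20))), "unbound.cif")
  rep2 <- classifyMotif(s2, identifyMotifs(s2)[[1]], cfg, checkReach = FALSE)
  expect_identical(reportCategory(rep2), "METAL_PRESENT_UNBOUND")
})

test_that("classification is independent of file atom order", {
  rows <- c("N1 N 0 0 0", "S1 S 0.079 0 0", "S2 S 0 0.079 0",
            "Au1 Au 0 0 0.11", "C1 C 0.4 0.4 0.4")
  cfg <- quietCoordConfig()
  cats <- vapply(list(rows, rev(rows), rows[c(3, 5, 1, 4, 2)]), function(r) {
    s <- parseCif(makeCifText(cell = c(20, 20, 20, 90, 90, 90), atomRows = r),
                  "perm.cif")
    reportCategory(classifyMotif(s, identifyMotifs(s)[[1]], cfg,
                                 checkReach = FALSE))
  }, character(1))
  expect_identical(unique(cats), "N_BOUND")
})

test_that("every motif gets exactly one category", {
  d <- file.path(withr::local_tempdir(), "mix")
  led <- generateCorpus(d, 12, seed = 8)
  sm <- suppressWarnings(analyzeDirectory(d))
  cats <- vapply(summaryReports(sm), reportCategory, character(1))
  expect_true(all(cats %in% c("N_BOUND", "METAL_PRESENT_UNBOUND", "NO_METAL")))
  expect_identical(length(cats), nrow(led))
})

test_that("classification counts tally categories and per-metal identities", {
  cfg <- quietCoordConfig()
  mk <- function(symbol, bound, seed) {
    contacts <- if (!is.null(symbol))
      list(list(symbol = symbol, distance = if (bound) 2.2 else 7)) else list()
    fx <- buildStructure(fixtureSpec(
      cell = unitCell(24, 24, 24, 80, 95, 110),
      metalContacts = contacts, seed = seed))
    classifyMotif(fx$structure, identifyMotifs(fx$structure)[[1]], cfg,
                  checkReach = FALSE)
  }
  reports <- list(mk("Au", TRUE, 1), mk(NULL, FALSE, 2), mk(NULL, FALSE, 3))
  cc <- classificationCounts(reports)
  expect_identical(cc$categories,
                   c(N_BOUND = 1L, METAL_PRESENT_UNBOUND = 0L, NO_METAL = 2L))
  expect_identical(cc$perMetal, c(Au = 1L))
  empty <- classificationCounts(list())
  expect_identical(sum(empty$categories), 0L)
  expect_length(empty$perMetal, 0L)
})

test_that("the truncation warning names metals whose reach exceeds the wave", {
  cfg <- quietCoordConfig()   # default 3 A radius, f = 1
  tm <- truncatedMetals(cfg, "N")
  expect_true(all(c("Fr", "Cs") %in% tm))   # r(N)+2.60+1, r(N)+2.44+1 > 3
  expect_false("Ni" %in% tm)                # r(N)+1.24+1 = 2.95 <= 3
  fx <- buildStructure(fixtureSpec(seed = 2))
  m <- identifyMotifs(fx$structure)[[1]]
  expect_warning(classifyMotif(fx$structure, m, cfg),
                 class = "cifmotif_reach_warning")
  # a generous wave silences it
  wide <- quietCoordConfig(searchRadius = 5)
  expect_silent(classifyMotif(fx$structure, m, wide))
})

test_that("structure-level counting marks a file N-bound if any motif is", {
  d <- file.path(withr::local_tempdir(), "struct")
  led <- generateCorpus(d, 20, seed = 14)
  sm <- suppressWarnings(analyzeDirectory(d))
  sc <- structureCounts(summaryReports(sm))
  byFile <- split(led$category, led$file)
  expect_identical(unname(sc[["files"]]), length(byFile))
  expect_identical(unname(sc[["nBound"]]),
                   sum(vapply(byFile, function(x) any(x == "N_BOUND"),
                              logical(1))))
  expect_identical(unname(sc[["metalPresent"]]),
                   sum(vapply(byFile, function(x) any(x != "NO_METAL"),
                              logical(1))))
})
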
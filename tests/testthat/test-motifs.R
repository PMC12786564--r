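# structures here are built from exact coordinates on orthogonal cells so
# bond-criterion boundaries are hit exactly

structFromRows <- function(rows, cell = c(20, 20, 20, 90, 90, 90)) {
  parseCif(makeCifText(cell = cell, atomRows = rows), "inline.cif")
}

rN <- radiusOf("N"); rS <- radiusOf("S")

test_that("bond criterion includes the boundary and excludes just beyond", {
  dBound <- rN + rS + 1          # 2.76 exactly, representable at 6 decimals
  s <- structFromRows(c(
    sprintf("N1 N 0 0 0"),
    sprintf("S1 S %.6f 0 0", dBound / 20),
    sprintf("S2 S 0 %.6f 0", (dBound + 0.001) / 20)))
  pairs <- findBondedPairs(s, motifConfig("N", "S", tau = 1))
  expect_identical(pairs$edge, "S1")
  expect_equal(pairs$distance, dBound)
})

test_that("planted occurrence pattern: 2 N with 2+1 bonded S", {
  s <- structFromRows(c(
    "N1 N 0 0 0",
    "S1 S 0.08 0 0",       # 1.6 A from N1
    "S2 S 0 0.08 0",       # 1.6 A from N1
    "N2 N 0.5 0.5 0.5",
    "S3 S 0.58 0.5 0.5"))  # 1.6 A from N2 only
  pairs <- findBondedPairs(s)
  expect_identical(nrow(pairs), 3L)
  occ <- bondOccurrences(pairs)
  expect_identical(occ, c(N1 = 2L, N2 = 1L))
  motifs <- identifyMotifs(s)
  expect_length(motifs, 1L)            # N2 has only one bonded S
  expect_identical(motifCentral(motifs[[1]])$identifier, "N1")
})

test_that("planted TFSI-like motif recovers its geometry", {
  fx <- buildStructure(fixtureSpec(seed = 21))
  m <- identifyMotifs(fx$structure)
  expect_length(m, 1L)
  expect_equal(motifAngle(m[[1]]), fx$ledger$angles, tolerance = 1e-9)
  expect_equal(motifLengthAverage(m[[1]]), fx$ledger$averages,
               tolerance = 1e-9)
  expect_equal(motifAngle(m[[1]]), 125, tolerance = 1e-3)
  expect_equal(motifLengthAverage(m[[1]]), 1.58, tolerance = 1e-3)
})

test_that("isolated central atoms and empty structures yield no motifs", {
  s <- structFromRows("N1 N 0.5 0.5 0.5")
  expect_length(identifyMotifs(s), 0L)
  expect_identical(nrow(findBondedPairs(s)), 0L)
})

test_that("two independent planted motifs in one cell are both found", {
  fx <- buildStructure(fixtureSpec(
    cell = unitCell(26, 27, 28, 80, 95, 110),
    motifs = list(
      list(d = c(1.58, 1.58), angle = 125, offset = c(6, 6, 6)),
      list(d = c(1.60, 1.56), angle = 118, offset = c(16, 16, 16))),
    seed = 5))
  m <- identifyMotifs(fx$structure)
  expect_length(m, 2L)
  expect_equal(sort(vapply(m, motifAngle, numeric(1))),
               sort(fx$ledger$angles), tolerance = 1e-9)
})

test_that("a central atom with three bonded edges keeps the nearest two", {
  s <- structFromRows(c(
    "N1 N 0 0 0",
    "S1 S 0.075 0 0",     # 1.5
    "S2 S 0 0.08 0",      # 1.6
    "S3 S 0 0 0.0825"))   # 1.65 (still bonded; farthest)
  m <- identifyMotifs(s)
  expect_length(m, 1L)
  expect_identical(sort(motifEdges(m[[1]])$identifier), c("S1", "S2"))
  expect_equal(sort(motifBondDistances(m[[1]])), c(1.5, 1.6))
})

test_that("bridging edge atoms may serve two motifs", {
  s <- structFromRows(c(
    "N1 N 0 0 0",
    "S1 S 0.075 0 0",        # bonded to both N1 and N2
    "N2 N 0.15 0 0",
    "S2 S 0 0.08 0",         # N1's second S
    "S3 S 0.15 0.08 0"))     # N2's second S
  m <- identifyMotifs(s)
  expect_length(m, 2L)
  edges <- lapply(m, function(g) sort(motifEdges(g)$identifier))
  expect_true(all(vapply(edges, function(e) "S1" %in% e, logical(1))))
})

test_that("motif graphs are acyclic, undirected and idempotent under addBond", {
  fx <- buildStructure(fixtureSpec(seed = 9))
  g <- identifyMotifs(fx$structure)[[1]]
  adj <- g@adjacency
  ctr <- g@centralKey
  expect_setequal(adj[[ctr]], g@edgeKeys)
  for (e in g@edgeKeys) expect_identical(adj[[e]], ctr)  # S-S not adjacent
  # re-adding an existing bond leaves adjacency unchanged
  g2 <- addBond(g, motifCentral(g), motifEdges(g)[1, ],
                motifBondDistances(g)[1])
  expect_identical(g2@adjacency, g@adjacency)
  # unknown anchor is an error
  stranger <- motifCentral(g); stranger$x <- stranger$x + 99
  expect_error(addBond(g, stranger, motifEdges(g)[1, ], 1), "unknown anchor")
})

test_that("returnAtoms filters graph nodes by element", {
  fx <- buildStructure(fixtureSpec(seed = 13))
  g <- identifyMotifs(fx$structure)[[1]]
  expect_identical(nrow(returnAtoms(g, "S")), 2L)
  expect_identical(nrow(returnAtoms(g, "N")), 1L)
  expect_identical(nrow(returnAtoms(g, "O")), 0L)
})

test_that("motif detection matches the brute-force oracle on random structures", {
  for (seed in 1:20) {
    s <- randomStructure(seed, nAtoms = 40)
    got <- motifDigest(identifyMotifs(s, motifConfig("N", "S", 1)))
    want <- bruteForceMotifs(s, motifConfig("N", "S", 1))
    byCentral <- function(l) l[order(vapply(l, `[[`, character(1), "central"))]
    expect_equal(byCentral(got), byCentral(want), tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("bonded-pair sets are nested in tau and motif count is monotone", {
  s <- randomStructure(77, nAtoms = 45)
  taus <- seq(0, 3, by = 0.5)
  prevPairs <- NULL; prevCount <- -1L
  for (tau in taus) {
    cfg <- motifConfig("N", "S", tau)
    pk <- with(findBondedPairs(s, cfg), paste(central, edge))
    if (!is.null(prevPairs)) expect_true(all(prevPairs %in% pk))
    cnt <- length(identifyMotifs(s, cfg))
    expect_gte(cnt, prevCount)
    prevPairs <- pk; prevCount <- cnt
  }
})

test_that("planted angles over 90..170 degrees are recovered", {
  for (ang in seq(90, 170, by = 10)) {
    fx <- buildStructure(fixtureSpec(
      motifs = list(list(d = c(1.58, 1.58), angle = ang)), seed = ang))
    m <- identifyMotifs(fx$structure)
    expect_length(m, 1L)
    expect_equal(motifAngle(m[[1]]), fx$ledger$angles, tolerance = 1e-6)
    expect_equal(motifAngle(m[[1]]), ang, tolerance = 1e-3)
  }
})

test_that("Eq-consistency: average equals the mean of the two distances", {
  s <- randomStructure(5, nAtoms = 50)
  for (m in identifyMotifs(s))
    expect_lt(abs(motifLengthAverage(m) - mean(motifBondDistances(m))), 1e-9)
})

test_that("alternative element pairs configure the same machinery", {
  # F-C-F core planted via the generator
  fx <- buildStructure(fixtureSpec(
    motifs = list(list(central = "C", edge = "F", d = c(1.33, 1.33),
                       angle = 108)),
    decoyElements = c("H", "O"), seed = 4))
  m <- identifyMotifs(fx$structure, motifConfig("C", "F", 1))
  expect_length(m, 1L)
  expect_equal(motifAngle(m[[1]]), fx$ledger$angles, tolerance = 1e-9)
  expect_identical(motifCentral(m[[1]])$symbol, "C")
  # no S-N-S motifs in an F-C-F structure
  expect_length(identifyMotifs(fx$structure, motifConfig("N", "S", 1)), 0L)
})
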
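# Independent brute-force oracles and tiny CIF builders used across tests.
# The oracles use plain elementwise loops, deliberately sharing no code path
# with the vectorized implementations they check.

# O(n^2) all-pairs bonded-set + nearest-two motif assembly by direct loops
bruteForceMotifs <- function(structure, config = motifConfig()) {
  at <- atomRecords(structure)
  tau <- config@tau
  ctr <- which(at$symbol == config@centralSymbol)
  edg <- which(at$symbol == config@edgeSymbol)
  out <- list()
  for (i in ctr) {
    hits <- integer(); dists <- numeric()
    for (j in edg) {
      if (i == j) next
      d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                  (at$z[i] - at$z[j])^2)
      if (d <= at$radius[i] + at$radius[j] + tau) {
        hits <- c(hits, j); dists <- c(dists, d)
      }
    }
    if (length(hits) < 2) next
    ord <- order(dists, hits)[1:2]
    v1 <- c(at$x[hits[ord[1]]] - at$x[i], at$y[hits[ord[1]]] - at$y[i],
            at$z[hits[ord[1]]] - at$z[i])
    v2 <- c(at$x[hits[ord[2]]] - at$x[i], at$y[hits[ord[2]]] - at$y[i],
            at$z[hits[ord[2]]] - at$z[i])
    ang <- acos(max(-1, min(1, sum(v1 * v2) /
                              (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
    out[[length(out) + 1L]] <- list(
      central = at$identifier[i],
      edges = sort(at$identifier[hits[ord]]),
      distances = sort(dists[ord]),
      average = mean(dists[ord]),
      angle = ang)
  }
  out
}

# summarize package motifs into the same comparable shape
motifDigest <- function(motifs) {
  lapply(motifs, function(m) {
    list(central = motifCentral(m)$identifier,
         edges = sort(motifEdges(m)$identifier),
         distances = sort(motifBondDistances(m)),
         average = motifLengthAverage(m),
         angle = motifAngle(m))
  })
}

# O(n) loop oracle for the fixed-radius neighbour search
bruteForceRadius <- function(structure, identifier, radius) {
  at <- atomRecords(structure)
  t <- which(at$identifier == identifier)[1]
  keep <- logical(nrow(at))
  for (j in seq_len(nrow(at))) {
    if (j == t) next
    d <- sqrt((at$x[t] - at$x[j])^2 + (at$y[t] - at$y[j])^2 +
                (at$z[t] - at$z[j])^2)
    keep[j] <- d <= radius
  }
  sort(at$identifier[keep])
}

# minimal hand-rolled CIF text (tagged loop) for parser tests
makeCifText <- function(cell = c(10, 10, 10, 90, 90, 90),
                        atomRows = character(),
                        cellOrder = 1:6, extraHeader = character(),
                        tags = c("_atom_site_label", "_atom_site_type_symbol",
                                 "_atom_site_fract_x", "_atom_site_fract_y",
                                 "_atom_site_fract_z")) {
  items <- c(paste("_cell_length_a", cell[1]),
             paste("_cell_length_b", cell[2]),
             paste("_cell_length_c", cell[3]),
             paste("_cell_angle_alpha", cell[4]),
             paste("_cell_angle_beta", cell[5]),
             paste("_cell_angle_gamma", cell[6]))
  c("data_test", extraHeader, items[cellOrder], "loop_", tags, atomRows, "")
}

# random structure with N/S/C atoms in a triclinic cell; used by the oracle
# equivalence checks. Coordinates are drawn in fractional space.
randomStructure <- function(seed, nAtoms = 40,
                            cell = unitCell(11, 12, 13, 85, 95, 105)) {
  set.seed(seed)
  syms <- sample(c("N", "S", "C", "O"), nAtoms, replace = TRUE,
                 prob = c(0.3, 0.4, 0.2, 0.1))
  frac <- matrix(runif(3 * nAtoms), ncol = 3)
  idx <- stats::ave(seq_along(syms), syms, FUN = seq_along)
  rows <- sprintf("%s%d %s %.6f %.6f %.6f", syms, idx, syms,
                  frac[, 1], frac[, 2], frac[, 3])
  txt <- makeCifText(cell = cellParameters(cell), atomRows = rows)
  # duplicate positions would violate the structure invariant; regenerate
  tryCatch(parseCif(txt, sprintf("random-%d.cif", seed)),
           error = function(e) randomStructure(seed + 100003, nAtoms, cell))
}

quietCoordConfig <- function(...) suppressWarnings(coordinationConfig(...))
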
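#' @include cif-parse.R
NULL

#' Motif detection configuration
#'
#' Defines the R-X-R motif to search for: the central element X, the edge
#' element R, and the additive bond tolerance tau (Angstrom) of the
#' covalent-radius criterion: a central-edge pair is bonded when
#' \eqn{d \le r(X) + r(R) + \tau}, boundary included. Defaults are the S-N-S
#' core of the TFSI anion at tau = 1; other triatomic motifs (C-N-C, F-C-F,
#' the FSI core, ...) need only different symbols.
#'
#' @param centralSymbol Central element (default `"N"`).
#' @param edgeSymbol Edge element (default `"S"`).
#' @param tau Bond tolerance, Angstrom, >= 0 (default 1.0).
#' @return A [MotifConfig].
#' @export
motifConfig <- function(centralSymbol = "N", edgeSymbol = "S", tau = 1.0) {
  new("MotifConfig", centralSymbol = canonicalSymbol(centralSymbol),
      edgeSymbol = canonicalSymbol(edgeSymbol), tau = as.numeric(tau))
}

#' Enumerate bonded central-edge pairs
#'
#' Brute-force search over all (central, edge) atom pairs of the structure; a
#' pair is bonded iff its Euclidean distance is at most the sum of the two
#' covalent radii plus `tau` (equality counts as bonded). Radii come from the
#' annotation stored on the parsed atoms, so elements missing from the radius
#' table (radius 0) are treated maximally conservatively.
#'
#' @param structure A [CifStructure].
#' @param config A [MotifConfig].
#' @return Data frame with columns `central`, `edge` (atom identifiers),
#'   `centralRow`, `edgeRow` (row numbers in the structure's atom table) and
#'   `distance` (Angstrom); zero rows if either element is absent.
#' @seealso [bondOccurrences()] for the per-central-atom bond counts.
#' @export
findBondedPairs <- function(structure, config = motifConfig()) {
  stopifnot(is(structure, "CifStructure"), is(config, "MotifConfig"))
  at <- structure@atoms
  ci <- which(at$symbol == config@centralSymbol)
  ei <- which(at$symbol == config@edgeSymbol)
  empty <- data.frame(central = character(), edge = character(),
                      centralRow = integer(), edgeRow = integer(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (!length(ci) || !length(ei)) return(empty)
  cm <- as.matrix(at[ci, c("x", "y", "z")])
  em <- as.matrix(at[ei, c("x", "y", "z")])
  ## n_central x n_edge distance matrix
  d2 <- outer(rowSums(cm^2), rowSums(em^2), "+") - 2 * cm %*% t(em)
  d <- sqrt(pmax(d2, 0))
  thr <- outer(at$radius[ci], at$radius[ei], "+") + config@tau
  hit <- which(d <= thr, arr.ind = TRUE)
  if (config@centralSymbol == config@edgeSymbol && nrow(hit)) {
    ## same-element motifs: an atom is never bonded to itself
    hit <- hit[ci[hit[, 1]] != ei[hit[, 2]], , drop = FALSE]
  }
  if (!nrow(hit)) return(empty)
  ord <- order(hit[, 1], hit[, 2])
  hit <- hit[ord, , drop = FALSE]
  data.frame(central = at$identifier[ci[hit[, 1]]],
             edge = at$identifier[ei[hit[, 2]]],
             centralRow = ci[hit[, 1]], edgeRow = ei[hit[, 2]],
             distance = d[hit], stringsAsFactors = FALSE)
}

#' Bond counts per central atom
#'
#' @param pairs Result of [findBondedPairs()].
#' @return Named integer vector: central identifier -> number of bonded edge
#'   atoms.
#' @export
bondOccurrences <- function(pairs) {
  if (!nrow(pairs)) return(stats::setNames(integer(), character()))
  tab <- table(pairs$central)
  stats::setNames(as.integer(tab), names(tab))
}

## assemble one MotifGraph from a central atom row and two edge atom rows
.makeMotifGraph <- function(at, centralRow, edgeRows, dists) {
  rows <- at[c(centralRow, edgeRows), , drop = FALSE]
  keys <- .posKey(rows)
  g <- new("MotifGraph",
           adjacency = stats::setNames(list(character()), keys[1]),
           atoms = rows[1, , drop = FALSE],
           centralKey = keys[1], edgeKeys = character(),
           bondAngle = numeric(), bondDistances = numeric(),
           bondLengthAverage = numeric())
  g <- addBond(g, rows[1, , drop = FALSE], rows[2, , drop = FALSE], dists[1])
  g <- addBond(g, rows[1, , drop = FALSE], rows[3, , drop = FALSE], dists[2])
  g@edgeKeys <- keys[2:3]
  g@bondDistances <- dists
  g@bondLengthAverage <- mean(dists)
  g@bondAngle <- angleAtVertex(
    c(rows$x[1], rows$y[1], rows$z[1]),
    c(rows$x[2], rows$y[2], rows$z[2]),
    c(rows$x[3], rows$y[3], rows$z[3]))
  validObject(g)
  g
}

#' Identify every R-X-R motif in a structure
#'
#' Runs [findBondedPairs()] and emits one [MotifGraph] per central atom
#' bonded to at least two edge atoms. A central atom bonded to more than two
#' edge atoms contributes one motif built from its two nearest edges (ties
#' broken by file order). Two central atoms may share an edge atom (a
#' bridging edge); both motifs are reported.
#'
#' @param structure A [CifStructure].
#' @param config A [MotifConfig].
#' @return List of [MotifGraph] objects, ordered by the central atom's file
#'   position; empty list when no motif is present.
#' @examples
#' \dontrun{
#' s <- readCif("structure.cif")
#' motifs <- identifyMotifs(s, motifConfig("N", "S", tau = 1))
#' }
#' @export
identifyMotifs <- function(structure, config = motifConfig()) {
  pairs <- findBondedPairs(structure, config)
  if (!nrow(pairs)) return(list())
  at <- structure@atoms
  out <- list()
  for (crow in sort(unique(pairs$centralRow))) {
    sub <- pairs[pairs$centralRow == crow, , drop = FALSE]
    if (nrow(sub) < 2) next
    ## nearest two edges; stable order breaks distance ties by file order
    sub <- sub[order(sub$distance, sub$edgeRow), , drop = FALSE]
    out[[length(out) + 1L]] <-
      .makeMotifGraph(at, crow, sub$edgeRow[1:2], sub$distance[1:2])
  }
  out
}

#' @rdname addBond
setMethod("addBond", "MotifGraph", function(graph, existing, new, dist) {
  ekey <- .posKey(existing)
  nkey <- .posKey(new)
  if (!ekey %in% names(graph@adjacency))
    stop("unknown anchor atom: ", existing$identifier)
  if (!nkey %in% names(graph@adjacency)) {
    graph@adjacency[[nkey]] <- character()
    graph@atoms <- rbind(graph@atoms, new)
  }
  ## idempotent: re-adding an identical bond changes nothing
  if (!nkey %in% graph@adjacency[[ekey]]) {
    graph@adjacency[[ekey]] <- c(graph@adjacency[[ekey]], nkey)
    graph@adjacency[[nkey]] <- c(graph@adjacency[[nkey]], ekey)
  }
  graph
})

#' @rdname returnAtoms
setMethod("returnAtoms", "MotifGraph", function(graph, symbol) {
  at <- graph@atoms
  at[at$symbol == canonicalSymbol(symbol), , drop = FALSE]
})
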
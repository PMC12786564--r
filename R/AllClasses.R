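#' @include AllGenerics.R
NULL

## Atom records are kept as a plain data.frame (one row per atom-site row of
## the file) rather than one S4 object per atom: batch runs touch hundreds of
## files and per-atom objects would dominate runtime. Column contract:
##   identifier  chr  label as written (suffixes retained, e.g. "C1A")
##   symbol      chr  canonical element symbol ("Au", not "AU")
##   atomIndex   int  first digit run of the label (NA if none)
##   fx, fy, fz  dbl  fractional coordinates
##   x, y, z     dbl  Cartesian coordinates, Angstrom, rounded to 6 decimals
##   radius      dbl  covalent radius, Angstrom (0 for unknown elements)
.atomColumns <- c("identifier", "symbol", "atomIndex",
                  "fx", "fy", "fz", "x", "y", "z", "radius")

.emptyAtomTable <- function() {
  data.frame(identifier = character(), symbol = character(),
             atomIndex = integer(),
             fx = numeric(), fy = numeric(), fz = numeric(),
             x = numeric(), y = numeric(), z = numeric(),
             radius = numeric(), stringsAsFactors = FALSE)
}

## Position triples are the identity key for atoms: two atoms are the same
## atom iff their (rounded) Cartesian triples coincide.
.posKey <- function(atoms) paste(atoms$x, atoms$y, atoms$z, sep = "|")

#' Crystallographic unit cell
#'
#' Six cell parameters defining the crystal lattice: edge lengths `a`, `b`,
#' `c` in Angstroms and inter-axial angles `alpha`, `beta`, `gamma` in
#' degrees. The cell is the sole input to the fractional-to-Cartesian
#' conversion matrix.
#'
#' @slot a,b,c Cell edge lengths, Angstrom (positive).
#' @slot alpha,beta,gamma Cell angles, degrees (strictly between 0 and 180).
#' @seealso [unitCell()], [buildConversionMatrix()]
#' @export
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric"),
  validity = function(object) {
    len <- c(a = object@a, b = object@b, c = object@c)
    ang <- c(alpha = object@alpha, beta = object@beta, gamma = object@gamma)
    if (any(!is.finite(len)) || any(len <= 0))
      return("cell lengths a, b, c must be finite and > 0")
    if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
      return("cell angles must lie strictly between 0 and 180 degrees")
    TRUE
  })

#' Construct a unit cell
#'
#' @param a,b,c Edge lengths, Angstrom.
#' @param alpha,beta,gamma Angles, degrees.
#' @return A [UnitCell] object.
#' @examples
#' unitCell(10, 10, 10, 90, 90, 90)
#' @export
unitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  new("UnitCell", a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      gamma = as.numeric(gamma))
}

#' Fractional-to-Cartesian conversion matrix
#'
#' Upper-triangular 3x3 matrix mapping fractional cell coordinates to
#' Cartesian Angstrom coordinates, with `a` along x and `b` in the xy plane.
#' `cosAlphaStar` stores the cosine of the reciprocal-like auxiliary angle
#' used in the lower-right block.
#'
#' @slot entries 3x3 numeric matrix, Angstrom per fractional unit.
#' @slot cosAlphaStar Cosine of the auxiliary angle:
#'   (cos alpha - cos beta cos gamma) / (sin beta sin gamma).
#' @seealso [buildConversionMatrix()], [fracToCartesian()]
#' @export
setClass("ConversionMatrix",
  representation(entries = "matrix", cosAlphaStar = "numeric"),
  validity = function(object) {
    m <- object@entries
    if (!is.numeric(m) || !identical(dim(m), c(3L, 3L)))
      return("entries must be a numeric 3x3 matrix")
    if (any(m[lower.tri(m)] != 0))
      return("conversion matrix must be upper triangular")
    if (!is.finite(det(m)) || det(m) <= 0)
      return("conversion matrix must be invertible with positive determinant")
    TRUE
  })

#' Parsed crystallographic structure
#'
#' One parsed CIF data block: the header metadata, the unit cell, and the
#' ordered atom-site table with both fractional and derived Cartesian
#' coordinates. Atom order equals file order. Atom identity is the Cartesian
#' position triple; no two atoms may share one.
#'
#' @slot sourcePath Path the structure was read from ("" if parsed from text).
#' @slot metadata Named character vector of `_tag value` items found before
#'   the atom-site loop (includes all `_cell_*` items).
#' @slot cell A [UnitCell].
#' @slot atoms Atom-record data frame (see [atomRecords()]).
#' @seealso [parseCif()], [readCif()]
#' @export
setClass("CifStructure",
  representation(sourcePath = "character", metadata = "character",
                 cell = "UnitCell", atoms = "data.frame"),
  validity = function(object) {
    at <- object@atoms
    if (!all(.atomColumns %in% names(at)))
      return(paste("atoms table must have columns:",
                   paste(.atomColumns, collapse = ", ")))
    if (nrow(at) > 0 && anyDuplicated(.posKey(at)))
      return("two atoms share the same Cartesian position triple")
    TRUE
  })

#' Detected triatomic motif as an acyclic undirected graph
#'
#' One R-X-R moiety (default S-N-S): the central atom bonded to exactly two
#' edge atoms, the edge atoms not bonded to each other. Adjacency is keyed by
#' the atoms' position triples and is kept symmetric. The central bond angle
#' (degrees) and the mean of the two central-edge bond distances (Angstrom)
#' are stored on the graph.
#'
#' @slot adjacency Named list: position key -> character vector of bonded
#'   position keys (symmetric, no self edges, no duplicates).
#' @slot atoms Data frame of the member atom records (central first).
#' @slot centralKey,edgeKeys Position keys of the central atom and the two
#'   edge atoms.
#' @slot bondAngle Central angle, degrees, in (0, 180].
#' @slot bondDistances The two central-edge distances, Angstrom.
#' @slot bondLengthAverage Mean of `bondDistances`, Angstrom.
#' @export
setClass("MotifGraph",
  representation(adjacency = "list", atoms = "data.frame",
                 centralKey = "character", edgeKeys = "character",
                 bondAngle = "numeric", bondDistances = "numeric",
                 bondLengthAverage = "numeric"),
  validity = function(object) {
    adj <- object@adjacency
    for (k in names(adj)) {
      for (nb in adj[[k]]) {
        if (!nb %in% names(adj) || !k %in% adj[[nb]])
          return("adjacency is not symmetric")
      }
      if (anyDuplicated(adj[[k]])) return("duplicate adjacency entries")
      if (k %in% adj[[k]]) return("self edge in adjacency")
    }
    if (length(object@edgeKeys) == 2 && length(object@centralKey) == 1) {
      if (object@edgeKeys[1] %in% adj[[object@edgeKeys[2]]])
        return("edge atoms must not be adjacent (graph must stay acyclic)")
      if (!all(object@edgeKeys %in% adj[[object@centralKey]]))
        return("central atom must be adjacent to both edge atoms")
    }
    if (length(object@bondAngle) == 1 &&
        (object@bondAngle <= 0 || object@bondAngle > 180))
      return("bond angle must lie in (0, 180]")
    if (length(object@bondDistances) == 2 &&
        length(object@bondLengthAverage) == 1 &&
        abs(object@bondLengthAverage - mean(object@bondDistances)) > 1e-9)
      return("bondLengthAverage must equal the mean of bondDistances")
    TRUE
  })

#' Per-motif coordination classification record
#'
#' @slot sourcePath File the motif came from.
#' @slot motif The classified [MotifGraph].
#' @slot category One of `"N_BOUND"` (a metal of interest is within the
#'   covalent-radius coordination criterion of the central atom),
#'   `"METAL_PRESENT_UNBOUND"` (the structure contains a metal of interest
#'   but none is bound), or `"NO_METAL"`.
#' @slot boundMetals Data frame (identifier, symbol, distance) of every metal
#'   satisfying the coordination criterion; zero rows unless `N_BOUND`.
#' @export
setClass("MotifReport",
  representation(sourcePath = "character", motif = "MotifGraph",
                 category = "character", boundMetals = "data.frame"),
  validity = function(object) {
    cats <- c("N_BOUND", "METAL_PRESENT_UNBOUND", "NO_METAL")
    if (length(object@category) != 1 || !object@category %in% cats)
      return(paste("category must be one of:", paste(cats, collapse = ", ")))
    if ((object@category == "N_BOUND") != (nrow(object@boundMetals) > 0))
      return("category is N_BOUND iff boundMetals is non-empty")
    TRUE
  })

#' Motif detection configuration
#'
#' @slot centralSymbol Element at the motif centre (X of R-X-R; default "N").
#' @slot edgeSymbol Element at the motif edges (R; default "S").
#' @slot tau Additive bond tolerance, Angstrom: atoms are bonded when their
#'   separation is at most the sum of covalent radii plus `tau`.
#' @export
setClass("MotifConfig",
  representation(centralSymbol = "character", edgeSymbol = "character",
                 tau = "numeric"),
  validity = function(object) {
    if (length(object@tau) != 1 || !is.finite(object@tau) || object@tau < 0)
      return("tau must be a single non-negative number")
    TRUE
  })

#' Coordination classification configuration
#'
#' @slot searchRadius Radius, Angstrom, of the spherical neighbour search
#'   around the central atom (default 3).
#' @slot fudge Additive tolerance f, Angstrom, of the coordination criterion
#'   distance <= r(X) + r(M) + f (default 1, matching the bond tolerance).
#' @slot metals Character vector of element symbols treated as metals of
#'   interest.
#' @slot radii Named numeric covalent-radius table used for the criterion.
#' @export
setClass("CoordinationConfig",
  representation(searchRadius = "numeric", fudge = "numeric",
                 metals = "character", radii = "numeric"),
  validity = function(object) {
    if (object@searchRadius <= 0) return("searchRadius must be > 0")
    if (object@fudge < 0) return("fudge must be >= 0")
    r <- object@radii[canonicalSymbol(object@metals)]
    if (any(is.na(r) | r <= 0))
      return("every metal of interest must have a positive covalent radius")
    TRUE
  })

#' Aggregated results of a batch run
#'
#' @slot angles Central bond angle of every detected motif, degrees.
#' @slot lengthAverages Mean central-edge bond length of every motif, Angstrom.
#' @slot reports List of [MotifReport] objects (one per motif, parallel to
#'   `angles`/`lengthAverages`).
#' @slot fileErrors Data frame (path, message) of files that failed to parse;
#'   failures never abort the batch.
#' @slot tauUsed Bond tolerance the run used, Angstrom.
#' @export
setClass("BatchSummary",
  representation(angles = "numeric", lengthAverages = "numeric",
                 reports = "list", fileErrors = "data.frame",
                 tauUsed = "numeric"),
  validity = function(object) {
    if (length(object@angles) != length(object@lengthAverages) ||
        length(object@angles) != length(object@reports))
      return("angles, lengthAverages and reports must be parallel")
    TRUE
  })

#' Bond-tolerance sensitivity sweep result
#'
#' @slot tauGrid Strictly increasing tolerance grid, Angstrom.
#' @slot counts Data frame with one row per grid value and columns `tau`,
#'   `N_BOUND`, `METAL_PRESENT_UNBOUND`, `NO_METAL`, `total`.
#' @export
setClass("TauSweepResult",
  representation(tauGrid = "numeric", counts = "data.frame"),
  validity = function(object) {
    if (is.unsorted(object@tauGrid, strictly = TRUE))
      return("tauGrid must be strictly increasing")
    if (nrow(object@counts) != length(object@tauGrid))
      return("counts must have one row per grid value")
    if (is.unsorted(object@counts$N_BOUND))
      return("N_BOUND count must be non-decreasing in tau")
    TRUE
  })

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell: a=%.4f b=%.4f c=%.4f A  alpha=%.3f beta=%.3f gamma=%.3f deg\n",
              object@a, object@b, object@c,
              object@alpha, object@beta, object@gamma))
})

setMethod("show", "CifStructure", function(object) {
  cat(sprintf("CifStructure: %d atoms (%s)\n", nrow(object@atoms),
              if (nzchar(object@sourcePath)) object@sourcePath else "from text"))
  show(object@cell)
  els <- sort(table(object@atoms$symbol), decreasing = TRUE)
  if (length(els))
    cat("  elements:", paste(sprintf("%s(%d)", names(els), els), collapse = " "), "\n")
})

setMethod("show", "MotifGraph", function(object) {
  ed <- object@atoms$identifier[match(object@edgeKeys, .posKey(object@atoms))]
  ce <- object@atoms$identifier[match(object@centralKey, .posKey(object@atoms))]
  cat(sprintf("MotifGraph: %s-%s-%s  angle=%.3f deg  mean bond=%.4f A\n",
              ed[1], ce, ed[2], object@bondAngle, object@bondLengthAverage))
})

setMethod("show", "MotifReport", function(object) {
  show(object@motif)
  cat("  category:", object@category, "\n")
  if (nrow(object@boundMetals))
    cat("  bound metals:",
        paste(sprintf("%s (%.3f A)", object@boundMetals$identifier,
                      object@boundMetals$distance), collapse = ", "), "\n")
})

setMethod("show", "BatchSummary", function(object) {
  cat(sprintf("BatchSummary: %d motifs, %d file errors, tau=%.2f A\n",
              length(object@angles), nrow(object@fileErrors), object@tauUsed))
  if (length(object@angles)) {
    cc <- classificationCounts(object@reports)
    cat("  categories:",
        paste(sprintf("%s=%d", names(cc$categories), cc$categories),
              collapse = " "), "\n")
    cat(sprintf("  angle: mean %.2f deg; mean bond length: %.4f A\n",
                mean(object@angles), mean(object@lengthAverages)))
  }
})

setMethod("show", "TauSweepResult", function(object) {
  cat(sprintf("TauSweepResult: %d grid values, tau in [%.2f, %.2f] A\n",
              length(object@tauGrid), min(object@tauGrid), max(object@tauGrid)))
})

## -- simple accessors ------------------------------------------------------

#' @rdname nAtoms
setMethod("nAtoms", "CifStructure", function(x) nrow(x@atoms))
#' @rdname nAtoms
setMethod("nAtoms", "MotifGraph", function(x) nrow(x@atoms))

#' @rdname unitCellOf
setMethod("unitCellOf", "CifStructure", function(x) x@cell)

#' @rdname atomRecords
setMethod("atomRecords", "CifStructure", function(x) x@atoms)
#' @rdname atomRecords
setMethod("atomRecords", "MotifGraph", function(x) x@atoms)

#' @rdname cifMetadata
setMethod("cifMetadata", "CifStructure", function(x) x@metadata)

#' Cell parameters as a named vector
#' @param cell A [UnitCell].
#' @return Named numeric vector `a, b, c, alpha, beta, gamma`.
#' @export
cellParameters <- function(cell) {
  stopifnot(is(cell, "UnitCell"))
  c(a = cell@a, b = cell@b, c = cell@c,
    alpha = cell@alpha, beta = cell@beta, gamma = cell@gamma)
}

#' Motif accessors
#'
#' `motifAngle()` returns the central bond angle in degrees;
#' `motifLengthAverage()` the mean of the two central-edge bond distances in
#' Angstrom; `motifBondDistances()` the two distances themselves;
#' `motifCentral()` and `motifEdges()` the central / edge atom records.
#'
#' @param graph A [MotifGraph].
#' @return See description.
#' @export
motifAngle <- function(graph) graph@bondAngle

#' @rdname motifAngle
#' @export
motifLengthAverage <- function(graph) graph@bondLengthAverage

#' @rdname motifAngle
#' @export
motifBondDistances <- function(graph) graph@bondDistances

#' @rdname motifAngle
#' @export
motifCentral <- function(graph)
  graph@atoms[match(graph@centralKey, .posKey(graph@atoms)), , drop = FALSE]

#' @rdname motifAngle
#' @export
motifEdges <- function(graph)
  graph@atoms[match(graph@edgeKeys, .posKey(graph@atoms)), , drop = FALSE]

#' Report accessors
#'
#' @param report A [MotifReport].
#' @return `reportCategory()`: the category string; `boundMetals()`: data
#'   frame of metals satisfying the coordination criterion;
#'   `reportMotif()`: the underlying [MotifGraph].
#' @export
reportCategory <- function(report) report@category

#' @rdname reportCategory
#' @export
boundMetals <- function(report) report@boundMetals

#' @rdname reportCategory
#' @export
reportMotif <- function(report) report@motif

#' Batch summary accessors
#' @param summary A [BatchSummary].
#' @return `summaryAngles()` / `summaryLengthAverages()`: numeric vectors,
#'   one entry per motif; `summaryReports()`: list of [MotifReport];
#'   `summaryFileErrors()`: data frame (path, message).
#' @export
summaryAngles <- function(summary) summary@angles

#' @rdname summaryAngles
#' @export
summaryLengthAverages <- function(summary) summary@lengthAverages

#' @rdname summaryAngles
#' @export
summaryReports <- function(summary) summary@reports

#' @rdname summaryAngles
#' @export
summaryFileErrors <- function(summary) summary@fileErrors
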
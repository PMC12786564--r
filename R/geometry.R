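#' @include AllClasses.R
NULL

.deg2rad <- function(x) x * pi / 180

#' Build the fractional-to-Cartesian conversion matrix
#'
#' Constructs the upper-triangular cell matrix
#' \deqn{CM = \begin{pmatrix} a & b\cos\gamma & c\cos\beta \\
#'   0 & b\sin\gamma & c\sin\beta\cos\alpha^{*} \\
#'   0 & 0 & c\sin\beta\sin\alpha^{*} \end{pmatrix}}
#' with \eqn{\cos\alpha^{*} = (\cos\alpha - \cos\beta\cos\gamma) /
#' (\sin\beta\sin\gamma)}. The convention places `a` along x and `b` in the
#' xy plane; for an orthogonal cell the matrix is `diag(a, b, c)`, and its
#' determinant equals the cell volume
#' \eqn{abc\sqrt{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma +
#' 2\cos\alpha\cos\beta\cos\gamma}}.
#'
#' The matrix is built once per structure and applied to every atom of that
#' structure, since the cell parameters are a property of the file, not of
#' individual atoms.
#'
#' @param cell A [UnitCell].
#' @return A [ConversionMatrix].
#' @examples
#' cm <- buildConversionMatrix(unitCell(10, 10, 10, 90, 90, 90))
#' conversionEntries(cm)     # diag(10, 10, 10)
#' @export
buildConversionMatrix <- function(cell) {
  stopifnot(is(cell, "UnitCell"))
  p <- cellParameters(cell)
  ## cospi/sinpi are exact at right angles, so an orthogonal cell yields an
  ## exactly diagonal matrix (no 1e-16 trigonometric residue)
  ca <- cospi(p[["alpha"]] / 180); cb <- cospi(p[["beta"]] / 180)
  cg <- cospi(p[["gamma"]] / 180)
  sb <- sinpi(p[["beta"]] / 180); sg <- sinpi(p[["gamma"]] / 180)
  if (abs(sb) < 1e-12 || abs(sg) < 1e-12)
    stop("degenerate cell: sin(beta) or sin(gamma) is zero")
  cosAlphaStar <- (ca - cb * cg) / (sb * sg)
  sin2 <- 1 - cosAlphaStar^2
  if (sin2 <= 1e-24)
    stop("degenerate cell: cell angles admit no three-dimensional lattice")
  sinAlphaStar <- sqrt(sin2)
  a <- p[["a"]]; b <- p[["b"]]; cc <- p[["c"]]
  m <- matrix(c(a, b * cg, cc * cb,
                0, b * sg, cc * sb * cosAlphaStar,
                0, 0,      cc * sb * sinAlphaStar),
              nrow = 3, byrow = TRUE)
  new("ConversionMatrix", entries = m, cosAlphaStar = cosAlphaStar)
}

#' @rdname buildConversionMatrix
#' @param cm A [ConversionMatrix].
#' @export
conversionEntries <- function(cm) cm@entries

#' @rdname buildConversionMatrix
#' @export
cosAlphaStar <- function(cm) cm@cosAlphaStar

#' Convert fractional coordinates to Cartesian
#'
#' Applies the conversion matrix to one fractional triple or to an n-by-3
#' matrix of triples. Each Cartesian component is rounded to six decimal
#' places at creation (once, not after every later arithmetic step), which
#' tames floating-point noise in downstream comparisons and makes the
#' position triple usable as an identity key.
#'
#' @param frac Numeric length-3 vector or n-by-3 matrix of fractional
#'   coordinates.
#' @param cm A [ConversionMatrix].
#' @return Cartesian coordinates, Angstrom, same shape as the input.
#' @examples
#' cm <- buildConversionMatrix(unitCell(10, 10, 10, 90, 90, 90))
#' fracToCartesian(c(0.5, 0.5, 0.5), cm)   # 5 5 5
#' @export
fracToCartesian <- function(frac, cm) {
  stopifnot(is(cm, "ConversionMatrix"))
  if (is.matrix(frac)) {
    stopifnot(ncol(frac) == 3)
    round(frac %*% t(cm@entries), 6)
  } else {
    stopifnot(length(frac) == 3)
    round(as.numeric(cm@entries %*% frac), 6)
  }
}

#' Invert the conversion (Cartesian to fractional)
#'
#' Used by the fixture generator to express exactly planted Cartesian
#' geometry in the fractional coordinates a CIF stores.
#'
#' @param cart Numeric length-3 vector or n-by-3 matrix, Angstrom.
#' @param cm A [ConversionMatrix].
#' @return Fractional coordinates, same shape as input (not rounded).
#' @export
cartesianToFrac <- function(cart, cm) {
  stopifnot(is(cm, "ConversionMatrix"))
  inv <- solve(cm@entries)
  if (is.matrix(cart)) cart %*% t(inv) else as.numeric(inv %*% cart)
}

#' Euclidean distance between two points
#'
#' @param p,q Numeric length-3 Cartesian coordinates, Angstrom.
#' @return Distance in Angstrom.
#' @examples
#' atomDistance(c(0, 0, 0), c(3, 4, 0))   # 5
#' @export
atomDistance <- function(p, q) {
  sqrt(sum((as.numeric(p) - as.numeric(q))^2))
}

## distances from one point to each row of an n-by-3 matrix
.distToAll <- function(p, m) {
  sqrt((m[, 1] - p[1])^2 + (m[, 2] - p[2])^2 + (m[, 3] - p[3])^2)
}

#' Angle at a vertex, in degrees
#'
#' Forms the two arm vectors from `vertex` to `end1` and `end2` and returns
#' the angle between them via the dot product,
#' \eqn{\theta = \arccos(v_1 \cdot v_2 / (\lVert v_1\rVert\,\lVert v_2\rVert))}.
#' The cosine argument is clamped to \[-1, 1\] before `acos`: rounding can
#' push a genuinely collinear configuration a few ulp outside the domain.
#'
#' @param vertex,end1,end2 Numeric length-3 Cartesian coordinates.
#' @return Angle in degrees, in \[0, 180\].
#' @examples
#' angleAtVertex(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))   # 90
#' @export
angleAtVertex <- function(vertex, end1, end2) {
  v1 <- as.numeric(end1) - as.numeric(vertex)
  v2 <- as.numeric(end2) - as.numeric(vertex)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    stop("degenerate angle: an arm has zero length")
  cosv <- sum(v1 * v2) / (n1 * n2)
  acos(max(-1, min(1, cosv))) * 180 / pi
}
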
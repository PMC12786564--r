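#' @include geometry.R
NULL

#' Canonicalize an element symbol
#'
#' First letter upper-case, remainder lower-case, so `"AU"`, `"au"` and
#' `"Au"` all compare equal. Applied before every symbol comparison in the
#' package.
#'
#' @param symbol Character vector of element symbols.
#' @return Canonicalized character vector.
#' @export
canonicalSymbol <- function(symbol) {
  s <- as.character(symbol)
  out <- paste0(toupper(substr(s, 1, 1)), tolower(substring(s, 2)))
  out[is.na(s)] <- NA_character_
  out
}

#' Covalent-radius lookup table
#'
#' Single-bond covalent radii (Angstrom) for 96 elements, transcribed from
#' the 2008 comprehensive review of recommended covalent radii. Where that
#' review lists several values for one element, the sp3 value is used for
#' carbon and the high-spin value for Mn, Fe and Co — the larger, more
#' inclusive radii, in keeping with the deliberately inclusive bond
#' criterion.
#'
#' The table ships as an editable two-column text file
#' (`extdata/covalent_radii.csv`), so analyses of other motifs can extend or
#' override it via `file`.
#'
#' @param file Optional path to an alternative `element,radius` CSV.
#' @return Named numeric vector: canonical element symbol -> radius, Angstrom.
#' @examples
#' covalentRadii()[["N"]]   # 0.71
#' @export
covalentRadii <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "covalent_radii.csv", package = "cifmotif",
                        mustWork = TRUE)
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("element", "radius") %in% names(tab)))
    stop("radius table must have columns 'element' and 'radius': ", file)
  r <- as.numeric(tab$radius)
  if (any(!is.finite(r) | r <= 0 | r >= 3))
    stop("covalent radii must lie in (0, 3) Angstrom: ", file)
  stats::setNames(r, canonicalSymbol(tab$element))
}

#' Radius of one element
#'
#' Total lookup: an element absent from the table gets radius 0 exactly
#' (never an error), so that non-tabulated species simply cannot satisfy any
#' radius-sum bond criterion on their own.
#'
#' @param symbol Element symbol (any case).
#' @param table Named radius vector, default [covalentRadii()].
#' @return Radius in Angstrom; 0 for unknown symbols.
#' @examples
#' radiusOf("N")    # 0.71
#' radiusOf("Xx")   # 0
#' @export
radiusOf <- function(symbol, table = covalentRadii()) {
  r <- unname(table[canonicalSymbol(symbol)])
  r[is.na(r)] <- 0
  r
}

#' Default set of metals of interest
#'
#' All elements conventionally classified as metals: alkali, alkaline-earth,
#' transition, post-transition, lanthanide and actinide series (metalloids
#' excluded). Every member has a positive covalent radius in the default
#' table. Ships as an editable one-symbol-per-line file
#' (`extdata/metal_symbols.txt`).
#'
#' @param file Optional path to an alternative symbol list.
#' @return Character vector of canonical element symbols.
#' @examples
#' "Au" %in% defaultMetalSet()   # TRUE
#' "C" %in% defaultMetalSet()    # FALSE
#' @export
defaultMetalSet <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "metal_symbols.txt", package = "cifmotif",
                        mustWork = TRUE)
  syms <- canonicalSymbol(readLines(file, warn = FALSE))
  syms[nzchar(syms)]
}
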
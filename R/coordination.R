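#' @include motifs.R
NULL

#' Coordination classification configuration
#'
#' Parameters of the two-stage metal-coordination check: a spherical
#' neighbour search of `searchRadius` Angstrom around the motif's central
#' atom, followed by the covalent-radius coordination criterion
#' \eqn{d \le r(X) + r(M) + f} on every metal of interest found inside the
#' sphere. `fudge` (f) defaults to the same value as the bond tolerance tau,
#' since both express one sliding stringency; the sensitivity sweep varies
#' them jointly.
#'
#' @param searchRadius Neighbour-search radius, Angstrom (default 3).
#' @param fudge Additive coordination tolerance f, Angstrom (default 1).
#' @param metals Character vector of metal symbols (default
#'   [defaultMetalSet()]).
#' @param radii Named covalent-radius table (default [covalentRadii()]).
#' @return A [CoordinationConfig].
#' @export
coordinationConfig <- function(searchRadius = 3.0, fudge = 1.0,
                               metals = defaultMetalSet(),
                               radii = covalentRadii()) {
  new("CoordinationConfig", searchRadius = as.numeric(searchRadius),
      fudge = as.numeric(fudge), metals = canonicalSymbol(metals),
      radii = radii)
}

#' Metals whose coordination reach exceeds the search radius
#'
#' For a metal M, the coordination criterion nominally reaches
#' r(X) + r(M) + f; if that exceeds `searchRadius`, the neighbour search
#' truncates the criterion for that metal (a contact between `searchRadius`
#' and the nominal reach would be missed). With the default radii and f = 1
#' this affects the largest metals (e.g. Cs, Fr). Classification functions
#' warn (class `"cifmotif_reach_warning"`) rather than silently truncating.
#'
#' @param config A [CoordinationConfig].
#' @param centralSymbol Central element X of the motif.
#' @return Character vector of affected metal symbols (possibly empty).
#' @export
truncatedMetals <- function(config, centralSymbol) {
  rx <- radiusOf(centralSymbol, config@radii)
  reach <- rx + radiusOf(config@metals, config@radii) + config@fudge
  config@metals[reach > config@searchRadius]
}

.warnReach <- function(config, centralSymbol) {
  tm <- truncatedMetals(config, centralSymbol)
  if (length(tm))
    warning(warningCondition(
      paste0("search radius ", format(config@searchRadius),
             " A truncates the coordination criterion for: ",
             paste(tm, collapse = ", "),
             " (r(", centralSymbol, ") + r(M) + f exceeds it)"),
      class = "cifmotif_reach_warning"))
  invisible(tm)
}

#' Classify one motif by metal coordination
#'
#' Stage 1: collect all atoms within `searchRadius` of the central atom; any
#' metal of interest among them whose distance satisfies
#' \eqn{d \le r(X) + r(M) + f} marks the motif `N_BOUND`, with every
#' qualifying metal recorded. Stage 2: otherwise, if the structure contains
#' any metal of interest anywhere, the motif is `METAL_PRESENT_UNBOUND`.
#' Stage 3: otherwise `NO_METAL`. Exactly one category always applies, and
#' the result does not depend on the atom order of the file.
#'
#' @param structure The [CifStructure] the motif was detected in.
#' @param motif A [MotifGraph] from [identifyMotifs()].
#' @param config A [CoordinationConfig].
#' @param checkReach Emit the reach-truncation warning (see
#'   [truncatedMetals()])? Batch drivers do the check once per run and pass
#'   `FALSE` here.
#' @return A [MotifReport].
#' @export
classifyMotif <- function(structure, motif, config = coordinationConfig(),
                          checkReach = TRUE) {
  stopifnot(is(structure, "CifStructure"), is(motif, "MotifGraph"),
            is(config, "CoordinationConfig"))
  central <- motifCentral(motif)
  if (checkReach) .warnReach(config, central$symbol)
  near <- getAtomsInRadius(structure, central, config@searchRadius)
  isMetal <- near$symbol %in% config@metals
  cand <- near[isMetal, , drop = FALSE]
  bound <- .emptyBoundMetals()
  if (nrow(cand)) {
    thr <- radiusOf(central$symbol, config@radii) +
      radiusOf(cand$symbol, config@radii) + config@fudge
    ok <- cand$distance <= thr
    if (any(ok)) {
      sel <- cand[ok, , drop = FALSE]
      sel <- sel[order(sel$distance, match(sel$identifier, structure@atoms$identifier)), ,
                 drop = FALSE]
      bound <- data.frame(identifier = sel$identifier, symbol = sel$symbol,
                          distance = sel$distance, stringsAsFactors = FALSE)
    }
  }
  category <- if (nrow(bound)) "N_BOUND"
  else if (any(structure@atoms$symbol %in% config@metals)) "METAL_PRESENT_UNBOUND"
  else "NO_METAL"
  new("MotifReport", sourcePath = structure@sourcePath, motif = motif,
      category = category, boundMetals = bound)
}

.emptyBoundMetals <- function() {
  data.frame(identifier = character(), symbol = character(),
             distance = numeric(), stringsAsFactors = FALSE)
}

.categoryLevels <- c("N_BOUND", "METAL_PRESENT_UNBOUND", "NO_METAL")

#' Tally classifications over motif reports
#'
#' @param reports List of [MotifReport] objects.
#' @return List with `categories` (named integer vector over the three
#'   categories, zeros included) and `perMetal` (named integer vector of
#'   N-bound counts by metal element; each motif counts once per distinct
#'   bound metal element).
#' @export
classificationCounts <- function(reports) {
  cats <- vapply(reports, reportCategory, character(1))
  categories <- stats::setNames(
    vapply(.categoryLevels, function(l) sum(cats == l), integer(1)),
    .categoryLevels)
  metalHits <- unlist(lapply(reports, function(r)
    unique(boundMetals(r)$symbol)), use.names = FALSE)
  perMetal <- if (length(metalHits)) {
    tab <- sort(table(metalHits), decreasing = TRUE)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(), character())
  list(categories = categories, perMetal = perMetal)
}

#' Tally classifications per structure (file) rather than per motif
#'
#' A file counts as metal-containing when any of its motifs saw a metal in
#' the structure, and as N-bound when any of its motifs is `N_BOUND`.
#'
#' @param reports List of [MotifReport] objects.
#' @return Named integer vector: `files` (distinct files with motifs),
#'   `metalPresent`, `nBound`.
#' @export
structureCounts <- function(reports) {
  if (!length(reports))
    return(c(files = 0L, metalPresent = 0L, nBound = 0L))
  paths <- vapply(reports, function(r) r@sourcePath, character(1))
  cats <- vapply(reports, reportCategory, character(1))
  metal <- tapply(cats != "NO_METAL", paths, any)
  nb <- tapply(cats == "N_BOUND", paths, any)
  c(files = length(unique(paths)),
    metalPresent = sum(metal), nBound = sum(nb))
}
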
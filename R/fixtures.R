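#' @include batch.R
NULL

## run expr with a deterministic RNG state, then restore the caller's state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  expr
}

.randomUnit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

## unit vector perpendicular to u
.perpUnit <- function(u) {
  repeat {
    w <- .randomUnit()
    w <- w - sum(w * u) * u
    n <- sqrt(sum(w^2))
    if (n > 1e-6) return(w / n)
  }
}

#' Specification of a synthetic structure with planted geometry
#'
#' Describes exactly what [buildStructure()] should plant: the unit cell, a
#' list of R-X-R motifs (each with its two bond lengths, central angle, and
#' the Cartesian placement of the central atom), optional metal contacts at
#' exact distances from a motif's central atom, and a count of random decoy
#' atoms guaranteed not to interact with anything planted. Construction is
#' fully reproducible from `seed`.
#'
#' @param cell A [UnitCell]; default a non-orthogonal cell so that the
#'   conversion matrix is exercised non-trivially.
#' @param motifs List of motif descriptions; each a list with elements
#'   `central` (element, default "N"), `edge` (element, default "S"),
#'   `d` (two bond lengths, Angstrom), `angle` (degrees), `offset`
#'   (Cartesian placement of the central atom; default cell centre).
#' @param metalContacts List of contact descriptions; each a list with
#'   `symbol` (metal element), `distance` (Angstrom from the central atom)
#'   and `motif` (index of the motif it attaches to, default 1).
#' @param decoys Number of random non-interacting atoms (default 0).
#' @param decoyElements Elements drawn on for decoys; motif elements and
#'   metals are excluded automatically.
#' @param seed Integer seed controlling all random directions.
#' @return An object of class `FixtureSpec` (a validated list).
#' @export
fixtureSpec <- function(cell = unitCell(12, 13, 14, 80, 95, 110),
                        motifs = list(list(d = c(1.58, 1.58), angle = 125)),
                        metalContacts = list(), decoys = 0,
                        decoyElements = c("C", "H", "O", "F"),
                        seed = 1L) {
  stopifnot(is(cell, "UnitCell"))
  cm <- buildConversionMatrix(cell)
  centreCart <- as.numeric(conversionEntries(cm) %*% c(0.5, 0.5, 0.5))
  motifs <- lapply(motifs, function(m) {
    m$central <- canonicalSymbol(if (is.null(m$central)) "N" else m$central)
    m$edge <- canonicalSymbol(if (is.null(m$edge)) "S" else m$edge)
    if (is.null(m$d)) m$d <- c(1.58, 1.58)
    if (is.null(m$angle)) m$angle <- 125
    if (is.null(m$offset)) m$offset <- centreCart
    stopifnot(length(m$d) == 2, all(m$d > 0), m$angle > 0, m$angle <= 180,
              length(m$offset) == 3)
    m
  })
  metalContacts <- lapply(metalContacts, function(ct) {
    ct$symbol <- canonicalSymbol(ct$symbol)
    if (is.null(ct$motif)) ct$motif <- 1L
    stopifnot(ct$distance > 0, ct$motif >= 1, ct$motif <= length(motifs))
    ct
  })
  structure(list(cell = cell, motifs = motifs,
                 metalContacts = metalContacts,
                 decoys = as.integer(decoys),
                 decoyElements = canonicalSymbol(decoyElements),
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

#' Build a synthetic structure and its ground-truth ledger
#'
#' Constructs the planted Cartesian geometry exactly: each motif's central
#' atom at its placement, the two edge atoms at the planted distances with
#' the planted inter-arm angle (random seeded orientation), metal contacts
#' at their exact distances along directions that keep them clear of every
#' other atom, and decoy atoms placed at least `clearance` Angstroms from
#' all planted atoms so they can never change an outcome. Cartesian
#' positions are inverse-transformed through the conversion matrix to the
#' fractional coordinates a CIF stores.
#'
#' Stored Cartesian coordinates are by contract rounded to six decimals, so
#' the planted positions are first snapped to that representable grid; the
#' returned ledger records every planted quantity (motif count, angles,
#' bond-length averages, expected classification categories at the given
#' tolerances, and bound-metal identities) as realized on the grid — within
#' about 1e-4 of the nominal request — computed by the generator's own
#' inline arithmetic, not by running the detection pipeline.
#'
#' @param spec A [fixtureSpec()].
#' @param radii Covalent-radius table (used for the ledger's expected
#'   categories and for the accidental-contact checks).
#' @param tau,fudge,searchRadius Tolerances assumed by the ledger's expected
#'   categories (defaults match the analysis defaults).
#' @param metals Metal set assumed by the ledger.
#' @param clearance Minimum separation, Angstrom, between a decoy and any
#'   planted atom (default 5, beyond any radius-sum bond criterion at the
#'   default tolerance plus margin).
#' @return List with elements `structure` (a [CifStructure]) and `ledger`
#'   (list: `nMotifs`, `angles`, `averages`, `d1`, `d2`, `categories`,
#'   `boundMetals`).
#' @examples
#' fx <- buildStructure(fixtureSpec(seed = 7))
#' fx$ledger$angles      # 125
#' @export
buildStructure <- function(spec, radii = covalentRadii(), tau = 1.0,
                           fudge = 1.0, searchRadius = 3.0,
                           metals = defaultMetalSet(), clearance = 5.0) {
  stopifnot(inherits(spec, "FixtureSpec"))
  cm <- buildConversionMatrix(spec$cell)
  .withSeed(spec$seed, {
    sym <- character(); pos <- NULL
    motifOf <- integer()            # which motif each atom belongs to (0 = none)
    role <- character()             # "central", "edge", "metal", "decoy"
    addAtom <- function(s, p, mi, ro) {
      sym <<- c(sym, s); pos <<- rbind(pos, as.numeric(p))
      motifOf <<- c(motifOf, mi); role <<- c(role, ro)
    }
    for (i in seq_along(spec$motifs)) {
      m <- spec$motifs[[i]]
      u <- .randomUnit(); w <- .perpUnit(u)
      th <- .deg2rad(m$angle)
      addAtom(m$central, m$offset, i, "central")
      addAtom(m$edge, m$offset + m$d[1] * u, i, "edge")
      addAtom(m$edge, m$offset + m$d[2] * (cos(th) * u + sin(th) * w), i, "edge")
    }
    for (ct in spec$metalContacts) {
      m <- spec$motifs[[ct$motif]]
      centre <- as.numeric(pos[which(motifOf == ct$motif & role == "central"), ])
      placed <- FALSE
      for (try in 1:200) {
        p <- centre + ct$distance * .randomUnit()
        dOther <- .distToAll(p, pos)
        ## only metal-to-central distances influence any outcome: stay clear
        ## of every *other* central atom's search sphere, and keep physical
        ## separation from everything else
        lim <- rep(0.6, length(sym))
        lim[role == "central"] <- searchRadius + 0.5
        ok <- dOther >= lim
        ok[motifOf == ct$motif & role == "central"] <- TRUE
        if (all(ok)) { addAtom(ct$symbol, p, ct$motif, "metal"); placed <- TRUE; break }
      }
      if (!placed)
        stop("accidental contact: cannot place ", ct$symbol,
             " at ", ct$distance, " A without an unplanted close approach")
    }
    decoyPool <- setdiff(spec$decoyElements,
                         c(vapply(spec$motifs, `[[`, character(1), "central"),
                           vapply(spec$motifs, `[[`, character(1), "edge"),
                           canonicalSymbol(metals)))
    if (spec$decoys > 0 && !length(decoyPool))
      stop("no decoy elements left after excluding motif elements and metals")
    for (k in seq_len(spec$decoys)) {
      placed <- FALSE
      for (try in 1:500) {
        f <- stats::runif(3, 0.05, 0.95)
        p <- as.numeric(conversionEntries(cm) %*% f)
        if (all(.distToAll(p, pos) >= ifelse(role == "decoy", 0.6, clearance))) {
          addAtom(sample(decoyPool, 1), p, 0L, "decoy"); placed <- TRUE; break
        }
      }
      if (!placed) stop("accidental contact: cannot place decoy ", k,
                        " with ", clearance, " A clearance")
    }

    ## any unplanted pair closer than 0.5 A is a construction failure, as is
    ## an unplanted central-edge pair inside the bond criterion at tau
    if (nrow(pos) > 1) {
      dd <- as.matrix(stats::dist(pos))
      diag(dd) <- Inf
      if (min(dd) < 0.5) stop("accidental contact: two unrelated atoms within 0.5 A")
      ci <- which(role == "central"); ei <- which(role == "edge")
      for (i in ci) for (j in ei) {
        if (motifOf[i] == motifOf[j]) next
        if (dd[i, j] <= radiusOf(sym[i], radii) + radiusOf(sym[j], radii) + tau)
          stop("accidental contact: central atom of motif ", motifOf[i],
               " bonds an edge atom of motif ", motifOf[j])
      }
    }

    ## snap the planted positions to the six-decimal representable grid:
    ## stored Cartesian coordinates are rounded to six decimals by contract,
    ## so the ledger records the geometry as actually realized on that grid
    ## (within ~1e-4 of the nominal request), keeping pipeline recovery
    ## exact instead of limited by quantization noise
    pos <- round(pos, 6)
    frac <- cartesianToFrac(pos, cm)
    if (any(frac < 0 | frac >= 1))
      stop("placement leaves fractional coordinates outside [0, 1); ",
           "use a larger cell or move the offsets")
    cart <- fracToCartesian(frac, cm)
    pos <- cart   # ledger geometry = the stored grid positions, exactly

    ## element-wise running labels: N1, S1, S2, Au1, ...
    idx <- stats::ave(seq_along(sym), sym, FUN = seq_along)
    labels <- paste0(sym, idx)
    atoms <- data.frame(identifier = labels, symbol = sym, atomIndex = idx,
                        fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
                        x = cart[, 1], y = cart[, 2], z = cart[, 3],
                        radius = radiusOf(sym, radii), stringsAsFactors = FALSE)
    struct <- new("CifStructure", sourcePath = "", metadata = character(),
                  cell = spec$cell, atoms = atoms)

    ## ---- analytic ledger (never runs the detection pipeline) ----
    ## geometry is recomputed inline from the realized grid positions
    metalsCanon <- canonicalSymbol(metals)
    anyMetalInStructure <- any(sym %in% metalsCanon)
    nM <- length(spec$motifs)
    eu <- function(i, j) sqrt(sum((pos[i, ] - pos[j, ])^2))
    angles <- numeric(nM); d1 <- numeric(nM); d2 <- numeric(nM)
    categories <- character(nM)
    boundList <- vector("list", nM)
    for (i in seq_len(nM)) {
      ic <- which(motifOf == i & role == "central")
      ie <- which(motifOf == i & role == "edge")
      d1[i] <- eu(ic, ie[1]); d2[i] <- eu(ic, ie[2])
      v1 <- pos[ie[1], ] - pos[ic, ]; v2 <- pos[ie[2], ] - pos[ic, ]
      angles[i] <- acos(max(-1, min(1, sum(v1 * v2) /
                                      (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      ctr <- spec$motifs[[i]]$central
      bound <- character()
      im <- which(motifOf == i & role == "metal")
      for (k in im) {
        reach <- radiusOf(ctr, radii) + radiusOf(sym[k], radii) + fudge
        dk <- eu(ic, k)
        if (dk <= reach && dk <= searchRadius) bound <- c(bound, sym[k])
      }
      categories[i] <- if (length(bound)) "N_BOUND"
      else if (anyMetalInStructure) "METAL_PRESENT_UNBOUND"
      else "NO_METAL"
      boundList[[i]] <- unique(bound)
    }
    list(structure = struct,
         ledger = list(nMotifs = nM, angles = angles,
                       averages = (d1 + d2) / 2, d1 = d1, d2 = d2,
                       categories = categories, boundMetals = boundList))
  })
}

#' Serialize a structure as CIF text
#'
#' Emits a minimal but standard-conforming data block: the six cell items
#' (plus any further stored metadata), then the atom-site loop. With
#' `tagged = TRUE` (default) the loop declares its columns with
#' `_atom_site_*` header tags; with `tagged = FALSE` it emits the bare
#' five-column dialect (a lone `_atom_site_fract_z` marker followed by
#' `label symbol x y z` rows), exercising the parser's positional fallback.
#' Fractional coordinates are written with nine decimals so that the stored
#' six-decimal Cartesian grid positions survive a round trip exactly.
#'
#' @param structure A [CifStructure].
#' @param path Optional file path; when given, the text is written there.
#' @param tagged Emit loop header tags? Default `TRUE`.
#' @param blockName Name after `data_` (default "synthetic").
#' @return Invisibly, the character vector of lines.
#' @export
writeCif <- function(structure, path = NULL, tagged = TRUE,
                     blockName = "synthetic") {
  stopifnot(is(structure, "CifStructure"))
  p <- cellParameters(structure@cell)
  fmtCell <- function(v) formatC(v, format = "fg", digits = 10)
  lines <- c(paste0("data_", blockName),
             "_audit_creation_method 'cifmotif synthetic fixture generator'",
             paste("_cell_length_a", fmtCell(p[["a"]])),
             paste("_cell_length_b", fmtCell(p[["b"]])),
             paste("_cell_length_c", fmtCell(p[["c"]])),
             paste("_cell_angle_alpha", fmtCell(p[["alpha"]])),
             paste("_cell_angle_beta", fmtCell(p[["beta"]])),
             paste("_cell_angle_gamma", fmtCell(p[["gamma"]])))
  extra <- structure@metadata
  extra <- extra[!grepl("^_cell_(length|angle)_", names(extra))]
  if (length(extra)) lines <- c(lines, paste(names(extra), extra))
  at <- structure@atoms
  rows <- sprintf("%s %s %.9f %.9f %.9f",
                  at$identifier, at$symbol, at$fx, at$fy, at$fz)
  if (tagged) {
    lines <- c(lines, "loop_",
               "_atom_site_label", "_atom_site_type_symbol",
               "_atom_site_fract_x", "_atom_site_fract_y",
               "_atom_site_fract_z", rows)
  } else {
    lines <- c(lines, "_atom_site_fract_z", rows)
  }
  lines <- c(lines, "")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

## study-condition defaults for the synthetic corpus: per-motif category mix,
## per-file motif multiplicity and bound-metal identities follow the observed
## TFSI survey composition (about 1.7 motifs per structure; roughly 64% of
## files metal-free, 28% with an unbound metal, 8% with an N-bound metal;
## bound metals dominated by Au, then Ag and Cu); geometry centred on the
## TFSI-typical 125 degree angle and 1.58 A mean S-N bond.
.corpusDefaults <- list(
  motifCountProbs = c(`1` = 0.45, `2` = 0.40, `3` = 0.15),
  fileTypeProbs = c(nBound = 0.083, metalUnbound = 0.278, noMetal = 0.639),
  extraBoundProb = 0.25,
  boundMetalProbs = c(Au = 43, Ag = 11, Cu = 8, Hg = 2, Pd = 2,
                      Fe = 1, Pt = 1, Ru = 1) / 69,
  angleMean = 125, angleSd = 4, angleMin = 100, angleMax = 150,
  lengthMean = 1.58, lengthSd = 0.01,
  boundLengthMean = 1.625, boundLengthSd = 0.01)

#' Generate a seeded corpus of synthetic CIF files
#'
#' Writes `n` CIF files with planted S-N-S motifs into `dir` and returns the
#' ground-truth ledger. The composition emulates the surveyed TFSI
#' population: about 1.7 motifs per file; most files metal-free, about a
#' quarter containing an unbound metal, and a small fraction with a metal
#' N-bound to a motif (bound metals drawn Au-heavy, then Ag, Cu and traces
#' of Hg, Pd, Fe, Pt, Ru); angles around 125 degrees and mean bond lengths
#' around 1.58 Angstrom (slightly longer for metal-bound motifs). The same
#' seed always yields byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param n Number of files.
#' @param seed Integer seed.
#' @param cell Unit cell used for every file; the default is large enough to
#'   hold three well-separated motifs plus contacts.
#' @param composition Overrides for entries of the internal composition list
#'   (see source for names); partial lists are merged over the defaults.
#' @param tagged Write tagged loops (default) or the bare dialect.
#' @return Data frame ledger: one row per planted motif with `file`,
#'   `motif`, `angle`, `average`, `d1`, `d2`, `category`, `boundMetal`.
#'   Also written alongside the corpus as `ledger.csv`.
#' @export
generateCorpus <- function(dir, n, seed = 1L,
                           cell = unitCell(22, 23, 24, 80, 95, 110),
                           composition = list(), tagged = TRUE) {
  cfg <- utils::modifyList(.corpusDefaults, composition)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- buildConversionMatrix(cell)
  anchors <- list(c(0.32, 0.32, 0.32), c(0.68, 0.68, 0.30), c(0.32, 0.68, 0.70))
  rows <- list()
  .withSeed(seed, {
    for (fi in seq_len(n)) {
      nM <- sample(as.integer(names(cfg$motifCountProbs)), 1,
                   prob = cfg$motifCountProbs)
      ftype <- sample(names(cfg$fileTypeProbs), 1, prob = cfg$fileTypeProbs)
      boundFlags <- rep(FALSE, nM)
      if (ftype == "nBound") {
        boundFlags[1] <- TRUE
        if (nM > 1)
          boundFlags[2:nM] <- stats::runif(nM - 1) < cfg$extraBoundProb
      }
      motifs <- vector("list", nM)
      contacts <- list()
      for (mi in seq_len(nM)) {
        angle <- min(cfg$angleMax,
                     max(cfg$angleMin, stats::rnorm(1, cfg$angleMean, cfg$angleSd)))
        if (boundFlags[mi]) {
          metal <- sample(names(cfg$boundMetalProbs), 1,
                          prob = cfg$boundMetalProbs)
          d <- stats::rnorm(2, cfg$boundLengthMean, cfg$boundLengthSd)
          contacts[[length(contacts) + 1L]] <- list(
            symbol = metal,
            distance = radiusOf("N") + radiusOf(metal) +
              stats::runif(1, 0.1, 0.9),
            motif = mi)
        } else {
          d <- stats::rnorm(2, cfg$lengthMean, cfg$lengthSd)
        }
        motifs[[mi]] <- list(central = "N", edge = "S", d = pmax(d, 1.2),
                             angle = angle,
                             offset = as.numeric(conversionEntries(cm) %*%
                                                   anchors[[mi]]))
      }
      if (ftype == "metalUnbound") {
        ## metal present in the structure but beyond the search radius
        contacts[[length(contacts) + 1L]] <- list(
          symbol = sample(names(cfg$boundMetalProbs), 1,
                          prob = cfg$boundMetalProbs),
          distance = stats::runif(1, 3.8, 5.5), motif = 1L)
      }
      spec <- fixtureSpec(cell = cell, motifs = motifs,
                          metalContacts = contacts,
                          decoys = sample(3:8, 1),
                          seed = sample.int(.Machine$integer.max, 1))
      fx <- buildStructure(spec)
      fname <- sprintf("synthetic_%04d.cif", fi)
      writeCif(fx$structure, file.path(dir, fname), tagged = tagged,
               blockName = sprintf("synthetic_%04d", fi))
      led <- fx$ledger
      rows[[length(rows) + 1L]] <- data.frame(
        file = fname, motif = seq_len(led$nMotifs),
        angle = led$angles, average = led$averages,
        d1 = led$d1, d2 = led$d2, category = led$categories,
        boundMetal = vapply(led$boundMetals, function(b)
          if (length(b)) paste(b, collapse = ";") else "", character(1)),
        stringsAsFactors = FALSE)
    }
  })
  ledger <- if (length(rows)) do.call(rbind, rows)
  else data.frame(file = character(), motif = integer(), angle = numeric(),
                  average = numeric(), d1 = numeric(), d2 = numeric(),
                  category = character(), boundMetal = character(),
                  stringsAsFactors = FALSE)
  utils::write.csv(ledger, file.path(dir, "ledger.csv"), row.names = FALSE)
  invisible(ledger)
}
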
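#' @include radii.R
NULL

## "0.1234(5)" -> 0.1234 : standard-uncertainty suffixes are informational
.stripSu <- function(x) sub("\\([0-9]+\\)\\s*$", "", x)

.cifNumeric <- function(x, context) {
  v <- suppressWarnings(as.numeric(.stripSu(x)))
  if (any(is.na(v)))
    stop("unparseable numeric field '", x[which(is.na(v))[1]], "' in ", context)
  v
}

## leading letters of a label ("C1A" -> "C"); first digit run -> index
.labelSymbol <- function(label) sub("^([A-Za-z]+).*$", "\\1", label)
.labelIndex <- function(label) {
  m <- regmatches(label, regexpr("[0-9]+", label))
  idx <- suppressWarnings(as.integer(vapply(label, function(l) {
    mm <- regmatches(l, regexpr("[0-9]+", l))
    if (length(mm)) mm else NA_character_
  }, character(1))))
  unname(idx)
}

#' Parse CIF text into a structure object
#'
#' Splits the file at the atom-site loop (located via the
#' `_atom_site_fract_z` tag, whose presence validates that the file carries
#' positional data at all). Everything before the loop is scanned for
#' `_tag value` items into the metadata map, from which the six cell items
#' are required; every data row of the loop becomes one atom record. The
#' fractional-to-Cartesian conversion matrix is built once per file and
#' applied to all atoms.
#'
#' Loop columns are mapped by their `_atom_site_*` header tags in whatever
#' order the file declares them; when the loop carries no header tags (the
#' bare five-column dialect), the columns are taken positionally as label,
#' symbol, x, y, z. When `_atom_site_type_symbol` is absent, the element is
#' derived from the leading letters of the label. Standard-uncertainty
#' suffixes like `0.1234(5)` are stripped. Only the first data block
#' containing positional data is parsed. Occupancy and displacement columns,
#' if present, are ignored; input is assumed disorder-free.
#'
#' @param text CIF content: a single string or a character vector of lines.
#' @param sourcePath Label used in error messages and stored on the result.
#' @param radii Covalent-radius table used to annotate atoms
#'   (default [covalentRadii()]); elements absent from it get radius 0.
#' @return A [CifStructure].
#' @seealso [readCif()] to parse from a file path.
#' @export
parseCif <- function(text, sourcePath = "", radii = covalentRadii()) {
  if (length(text) == 0 || !any(nzchar(text)))
    stop("empty CIF text: ", sourcePath)
  lines <- if (length(text) == 1 && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else as.character(text)
  label <- if (nzchar(sourcePath)) sourcePath else "<text>"

  zhits <- grep("^\\s*_atom_site_fract_z\\s*$", lines)
  if (!length(zhits)) {
    zhits <- which(trimws(lines) == "_atom_site_fract_z")
  }
  if (!length(zhits))
    stop("no positional data (missing _atom_site_fract_z): ", label)

  ## restrict to the first data block containing positional data
  blockStarts <- grep("^\\s*data_", lines)
  zidx <- zhits[1]
  if (length(blockStarts) > 1) {
    myBlock <- max(c(1L, blockStarts[blockStarts <= zidx]))
    nextBlock <- blockStarts[blockStarts > myBlock]
    blockEnd <- if (length(nextBlock)) nextBlock[1] - 1L else length(lines)
    lines <- lines[seq(myBlock, blockEnd)]
    zidx <- grep("^\\s*_atom_site_fract_z\\s*$", lines)[1]
  }

  ## collect the contiguous run of _atom_site_* tags around the fract_z line
  tagStart <- zidx
  while (tagStart > 1 && grepl("^\\s*_atom_site", lines[tagStart - 1]))
    tagStart <- tagStart - 1
  tagEnd <- zidx
  while (tagEnd < length(lines) && grepl("^\\s*_atom_site", lines[tagEnd + 1]))
    tagEnd <- tagEnd + 1
  tags <- trimws(lines[tagStart:tagEnd])
  ## a lone _atom_site_fract_z marker denotes the bare five-column dialect
  bare <- !any(tags == "_atom_site_label")

  ## metadata: every simple "_tag value" pair before the loop
  headLines <- lines[seq_len(tagStart - 1)]
  kv <- regmatches(headLines,
                   regexec("^[[:space:]]*(_[^[:space:]]+)[[:space:]]+(.*[^[:space:]])[[:space:]]*$",
                           headLines))
  kv <- kv[lengths(kv) == 3]
  metadata <- stats::setNames(vapply(kv, `[`, character(1), 3),
                              vapply(kv, `[`, character(1), 2))

  cellTags <- c("_cell_length_a", "_cell_length_b", "_cell_length_c",
                "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma")
  missingCell <- setdiff(cellTags, names(metadata))
  if (length(missingCell))
    stop("incomplete cell (missing ", paste(missingCell, collapse = ", "),
         "): ", label)
  cv <- vapply(cellTags, function(tg)
    .cifNumeric(metadata[[tg]], paste0("line '", tg, " ", metadata[[tg]], "' of ", label)),
    numeric(1))
  cell <- unitCell(cv[1], cv[2], cv[3], cv[4], cv[5], cv[6])

  ## data rows run until a blank line or the next CIF token
  body <- if (tagEnd < length(lines)) lines[(tagEnd + 1):length(lines)] else character()
  stopAt <- grep("^\\s*$|^\\s*(_|loop_|#|data_|;)", body)
  if (length(stopAt)) body <- body[seq_len(stopAt[1] - 1L)]
  rows <- strsplit(trimws(body), "\\s+")

  cm <- buildConversionMatrix(cell)
  atoms <- .emptyAtomTable()
  if (length(rows)) {
    if (bare) {
      cols <- list(label = 1L, symbol = 2L, x = 3L, y = 4L, z = 5L)
      need <- 5L
    } else {
      pick <- function(tg) { i <- match(tg, tags); i }
      cols <- list(label = pick("_atom_site_label"),
                   symbol = pick("_atom_site_type_symbol"),
                   x = pick("_atom_site_fract_x"),
                   y = pick("_atom_site_fract_y"),
                   z = pick("_atom_site_fract_z"))
      if (any(is.na(unlist(cols[c("label", "x", "y", "z")]))))
        stop("atom loop lacks label or fractional-coordinate tags: ", label)
      need <- length(tags)
    }
    bad <- which(lengths(rows) != need)
    if (length(bad))
      stop("malformed atom row '", body[bad[1]], "' in ", label)
    getcol <- function(i) vapply(rows, `[`, character(1), i)
    labels <- getcol(cols$label)
    symbol <- if (!is.null(cols$symbol) && !is.na(cols$symbol)) {
      ## type_symbol may carry charge annotations, e.g. "O2-": keep letters
      canonicalSymbol(sub("^([A-Za-z]+).*$", "\\1", getcol(cols$symbol)))
    } else canonicalSymbol(.labelSymbol(labels))
    frac <- cbind(
      .cifNumeric(getcol(cols$x), label),
      .cifNumeric(getcol(cols$y), label),
      .cifNumeric(getcol(cols$z), label))
    cart <- fracToCartesian(frac, cm)
    atoms <- data.frame(identifier = labels, symbol = symbol,
                        atomIndex = .labelIndex(labels),
                        fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
                        x = cart[, 1], y = cart[, 2], z = cart[, 3],
                        radius = radiusOf(symbol, radii),
                        stringsAsFactors = FALSE)
  }
  new("CifStructure", sourcePath = sourcePath, metadata = metadata,
      cell = cell, atoms = atoms)
}

#' Read and parse a CIF file
#'
#' @param path Path to a CIF file.
#' @inheritParams parseCif
#' @return A [CifStructure].
#' @export
readCif <- function(path, radii = covalentRadii()) {
  if (!file.exists(path)) stop("no such file: ", path)
  parseCif(readLines(path, warn = FALSE), sourcePath = path, radii = radii)
}

#' @rdname getElementAtoms
setMethod("getElementAtoms", "CifStructure", function(x, symbol) {
  at <- x@atoms
  at[at$symbol == canonicalSymbol(symbol), , drop = FALSE]
})

#' @rdname containsAtom
setMethod("containsAtom", "CifStructure", function(x, symbol) {
  canonicalSymbol(symbol) %in% x@atoms$symbol
})

#' @rdname getParticularAtom
setMethod("getParticularAtom", "CifStructure", function(x, identifier) {
  hit <- which(x@atoms$identifier == identifier)
  if (!length(hit)) stop("atom not found: ", identifier)
  x@atoms[hit[1], , drop = FALSE]
})

#' @rdname getAtomsInRadius
setMethod("getAtomsInRadius", "CifStructure", function(x, target, radius) {
  at <- x@atoms
  if (is.character(target)) target <- getParticularAtom(x, target)
  stopifnot(is.data.frame(target), nrow(target) == 1)
  tkey <- .posKey(target)
  keys <- .posKey(at)
  if (!tkey %in% keys) stop("unknown target atom (not in structure)")
  d <- .distToAll(c(target$x, target$y, target$z),
                  as.matrix(at[, c("x", "y", "z")]))
  keep <- d <= radius & keys != tkey
  out <- at[keep, , drop = FALSE]
  out$distance <- d[keep]
  out
})
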
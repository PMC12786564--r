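#' @include coordination.R
NULL

.listCifs <- function(path, recursive = FALSE) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- list.files(path, pattern = "\\.[cC][iI][fF]$", full.names = TRUE,
                      recursive = recursive)
  ## radix sort is locale-independent: iteration order (hence output order)
  ## must not depend on the session locale
  files[order(basename(files), method = "radix")]
}

#' Analyze a directory of CIF files
#'
#' Parses every `.cif` file (lexicographic filename order), identifies all
#' R-X-R motifs, classifies each by metal coordination, and accumulates
#' angle and bond-length distributions plus the classification reports.
#' Files that fail to parse are recorded in the summary's `fileErrors` table
#' and never abort the run.
#'
#' @param path Directory containing CIF files.
#' @param motifConfig A [MotifConfig] (default S-N-S at tau = 1).
#' @param coordConfig A [CoordinationConfig] (default 3 Angstrom search,
#'   f = 1, all conventional metals).
#' @param recursive Also descend into subdirectories? Default `FALSE`.
#' @param radii Covalent-radius table used when parsing atoms.
#' @return A [BatchSummary].
#' @examples
#' \dontrun{
#' summary <- analyzeDirectory("cifs/", motifConfig("N", "S", 1.0))
#' classificationCounts(summaryReports(summary))
#' }
#' @export
analyzeDirectory <- function(path, motifConfig = cifmotif::motifConfig(),
                             coordConfig = coordinationConfig(),
                             recursive = FALSE, radii = covalentRadii()) {
  files <- .listCifs(path, recursive)
  .warnReach(coordConfig, motifConfig@centralSymbol)
  angles <- numeric(); lengths <- numeric(); reports <- list()
  errPath <- character(); errMsg <- character()
  for (f in files) {
    res <- tryCatch({
      s <- readCif(f, radii = radii)
      motifs <- identifyMotifs(s, motifConfig)
      lapply(motifs, classifyMotif, structure = s, config = coordConfig,
             checkReach = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errPath <- c(errPath, f); errMsg <- c(errMsg, conditionMessage(res))
    } else if (length(res)) {
      angles <- c(angles, vapply(res, function(r) motifAngle(reportMotif(r)),
                                 numeric(1)))
      lengths <- c(lengths, vapply(res, function(r)
        motifLengthAverage(reportMotif(r)), numeric(1)))
      reports <- c(reports, res)
    }
  }
  new("BatchSummary", angles = angles, lengthAverages = lengths,
      reports = reports,
      fileErrors = data.frame(path = errPath, message = errMsg,
                              stringsAsFactors = FALSE),
      tauUsed = motifConfig@tau)
}

#' Bond-tolerance sensitivity sweep
#'
#' Re-runs detection and classification over the directory at each tolerance
#' of the grid, applying the value jointly as the bond tolerance tau
#' (detection) and the coordination tolerance f (classification), and
#' records the category counts per grid value. Because the bond criterion is
#' monotone in the tolerance, the bonded-pair set is nested along the grid
#' and the N-bound count is non-decreasing.
#'
#' @inheritParams analyzeDirectory
#' @param grid Strictly increasing tolerance grid, Angstrom (default 0 to 3
#'   in 0.1 steps).
#' @return A [TauSweepResult].
#' @export
tauSweep <- function(path, motifConfig = cifmotif::motifConfig(),
                     coordConfig = coordinationConfig(),
                     grid = seq(0, 3, by = 0.1), recursive = FALSE,
                     radii = covalentRadii()) {
  stopifnot(length(grid) > 0, all(grid >= 0))
  grid <- as.numeric(grid)
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    mc <- motifConfig; mc@tau <- grid[i]
    cc <- coordConfig; cc@fudge <- grid[i]
    summary <- suppressWarnings(
      analyzeDirectory(path, mc, cc, recursive = recursive, radii = radii))
    counts <- classificationCounts(summary@reports)$categories
    rows[[i]] <- data.frame(tau = grid[i], t(counts),
                            total = length(summary@angles))
  }
  counts <- do.call(rbind, rows)
  new("TauSweepResult", tauGrid = grid, counts = counts)
}

#' @rdname tauSweep
#' @param sweep A [TauSweepResult].
#' @return `sweepCounts()`: the per-tolerance count table (data frame).
#' @export
sweepCounts <- function(sweep) sweep@counts

#' Per-motif result table
#'
#' The canonical tabular output of a batch run: one row per detected motif
#' with its provenance, member identifiers, the two bond distances, their
#' average, the central angle, the classification category, and any bound
#' metals as `identifier:distance` pairs separated by `;`.
#'
#' @param summary A [BatchSummary].
#' @return Data frame with columns `file`, `central`, `edge1`, `edge2`,
#'   `d1`, `d2`, `average`, `angle`, `category`, `boundMetals`.
#' @export
motifTable <- function(summary) {
  stopifnot(is(summary, "BatchSummary"))
  rows <- lapply(summary@reports, function(r) {
    m <- reportMotif(r)
    ed <- motifEdges(m)
    bm <- boundMetals(r)
    data.frame(file = basename(r@sourcePath),
               central = motifCentral(m)$identifier,
               edge1 = ed$identifier[1], edge2 = ed$identifier[2],
               d1 = motifBondDistances(m)[1], d2 = motifBondDistances(m)[2],
               average = motifLengthAverage(m), angle = motifAngle(m),
               category = reportCategory(r),
               boundMetals = if (nrow(bm))
                 paste(sprintf("%s:%.6f", bm$identifier, bm$distance),
                       collapse = ";") else "",
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(file = character(), central = character(),
                      edge1 = character(), edge2 = character(),
                      d1 = numeric(), d2 = numeric(), average = numeric(),
                      angle = numeric(), category = character(),
                      boundMetals = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

## fixed 6-decimal, '.'-separated formatting for numeric columns
.formatTable <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- formatC(df[[nm]], format = "f", digits = 6, decimal.mark = ".")
  df
}

#' Export batch results as tables
#'
#' Writes (1) the per-motif table, (2) the category and per-metal count
#' table, and (3) optionally the tolerance-sweep table, as CSV files
#' (`<prefix>_motifs.csv`, `<prefix>_counts.csv`, `<prefix>_tausweep.csv`).
#' Non-integer numeric values are written with exactly six decimal places,
#' `.` decimal separator, no thousands separator; output is byte-identical
#' across repeated runs on the same inputs.
#'
#' @param summary A [BatchSummary].
#' @param outPrefix Path prefix for the output files.
#' @param format Output format; `"csv"` is implemented.
#' @param sweep Optional [TauSweepResult] to export alongside.
#' @return Invisibly, the character vector of files written.
#' @export
exportTables <- function(summary, outPrefix, format = c("csv", "xlsx"),
                         sweep = NULL) {
  format <- match.arg(format)
  if (format == "xlsx")
    stop("xlsx export requires a spreadsheet-writing package; ",
         "use format = \"csv\"")
  dir.create(dirname(outPrefix), showWarnings = FALSE, recursive = TRUE)
  written <- character()
  wr <- function(df, suffix) {
    f <- paste0(outPrefix, "_", suffix, ".csv")
    utils::write.csv(.formatTable(df), f, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8", eol = "\n")
    written <<- c(written, f)
  }
  wr(motifTable(summary), "motifs")
  cc <- classificationCounts(summary@reports)
  sc <- structureCounts(summary@reports)
  countDf <- rbind(
    data.frame(kind = "category", name = names(cc$categories),
               count = as.integer(cc$categories), stringsAsFactors = FALSE),
    if (length(cc$perMetal))
      data.frame(kind = "metal", name = names(cc$perMetal),
                 count = as.integer(cc$perMetal), stringsAsFactors = FALSE),
    data.frame(kind = "structure", name = names(sc), count = as.integer(sc),
               stringsAsFactors = FALSE))
  wr(countDf, "counts")
  if (!is.null(sweep)) wr(sweepCounts(sweep), "tausweep")
  invisible(written)
}
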
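#' @include fixtures.R
NULL

#' Scatter plot of motif geometry coloured by classification
#'
#' Review aid over the exported tables: mean central-edge bond length (x)
#' against central angle (y), one point per motif, coloured by coordination
#' category. The tables, not the image, are the canonical output.
#'
#' @param summary A [BatchSummary].
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, the plotted data frame.
#' @export
motifScatter <- function(summary, ...) {
  tab <- motifTable(summary)
  if (!nrow(tab)) {
    warning("no motifs to plot")
    return(invisible(tab))
  }
  cols <- c(N_BOUND = "#D55E00", METAL_PRESENT_UNBOUND = "#009E73",
            NO_METAL = "grey50")
  graphics::plot(tab$average, tab$angle, col = cols[tab$category], pch = 19,
                 xlab = "mean central-edge bond length (Å)",
                 ylab = "central angle (°)", ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   bty = "n", cex = 0.8)
  invisible(tab)
}

#' Histogram of motif central angles
#'
#' @param summary A [BatchSummary].
#' @param breaks Passed to [graphics::hist()].
#' @param ... Further arguments passed to [graphics::hist()].
#' @return Invisibly, the histogram object.
#' @export
angleHistogram <- function(summary, breaks = 30, ...) {
  invisible(graphics::hist(summaryAngles(summary), breaks = breaks,
                           xlab = "central angle (°)",
                           main = "Motif central angles", ...))
}
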
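## Observers: time-series statistics, the lineage ledger, grid snapshots.

#' Compute one time-series sample from a world
#'
#' Means are taken over living cells (per-genome counts of essential, TE and
#' non-coding elements, genome length, fitness) and over all cellular TEs
#' (mean phi); the eDNA pool is summarised by its fragment and TE counts.
#' An empty population yields \code{nCells = 0} with the means \code{NA}.
#' This function recomputes the sample directly from the world state in R;
#' the engine appends identical rows while running.
#'
#' @param world a [TEWorld-class].
#' @return a one-row \code{data.frame} with columns \code{t}, \code{nCells},
#'   \code{meanEssential}, \code{meanTE}, \code{meanNonCoding},
#'   \code{meanLength}, \code{meanPhi}, \code{meanFitness},
#'   \code{nFragments}, \code{poolTE}.
#' @export
recordTimeSeries <- function(world) {
  occ <- !vapply(world@cells, is.null, logical(1))
  n <- sum(occ)
  fp <- world@config@fitness
  if (n > 0L) {
    gs <- world@cells[occ]
    nTE <- vapply(gs, function(g) sum(g < -0.5), numeric(1))
    nEss <- vapply(gs, function(g) sum(g > 0.5), numeric(1))
    len <- lengths(gs)
    phis <- unlist(lapply(gs, function(g) -g[g < -0.5] - 1), use.names = FALSE)
    fit <- vapply(gs, cpp_fitness, numeric(1), c = fp@c,
                  nFunctions = fp@nFunctions)
    mEss <- mean(nEss); mTE <- mean(nTE); mNC <- mean(len - nTE - nEss)
    mLen <- mean(len); mFit <- mean(fit)
    mPhi <- if (length(phis)) mean(phis) else NA_real_
  } else {
    mEss <- mTE <- mNC <- mLen <- mFit <- mPhi <- NA_real_
  }
  data.frame(t = world@t, nCells = n,
             meanEssential = mEss, meanTE = mTE, meanNonCoding = mNC,
             meanLength = mLen, meanPhi = mPhi, meanFitness = mFit,
             nFragments = length(world@fragSite),
             poolTE = sum(vapply(world@fragElements,
                                 function(f) sum(f < -0.5), numeric(1))))
}

#' Lineage-extinction records
#'
#' A lineage starts when a previously uninfected cell first acquires a TE
#' (infection marks the lineage, not the cell: uninfected descendants stay
#' in the record) and closes when its last member dies.  Each closed record
#' carries the infection and extinction timesteps, the greatest number of
#' generations (replication events along a line of descent) reached since
#' infection, and the cumulative number of TE copies the lineage released
#' into the eDNA pool by lysis.
#'
#' @param world a [TEWorld-class].
#' @param includeOpen also return still-open (living) infected lineages,
#'   as attribute \code{"open"}.
#' @return \code{data.frame} of closed records with columns \code{id},
#'   \code{tInfected}, \code{tExtinct}, \code{generations},
#'   \code{teProduced}.
#' @export
lineageRecords <- function(world, includeOpen = FALSE) {
  out <- world@closedLineages
  if (includeOpen) attr(out, "open") <- world@openLineages
  out
}

#' Export a grid snapshot
#'
#' Renders one channel of the world as a \code{height x width} numeric
#' matrix (empty sites are \code{NA}, displayed black in images) and
#' optionally writes it as a plain-text matrix and/or a raster image.  The
#' \code{te_count} channel is drawn on a log scale (blue to green to yellow
#' for increasing TE load).
#'
#' @param world a [TEWorld-class].
#' @param channel \code{"te_count"}, \code{"occupancy"} or
#'   \code{"genome_length"}.
#' @param file optional path for the plain-text numeric matrix.
#' @param imageFile optional path for a PNG rendering.
#' @return the matrix, invisibly.
#' @export
exportSnapshot <- function(world,
                           channel = c("te_count", "occupancy", "genome_length"),
                           file = NULL, imageFile = NULL) {
  channel <- match.arg(channel)
  vals <- vapply(world@cells, function(g) {
    if (is.null(g)) return(NA_real_)
    switch(channel,
           te_count = sum(g < -0.5),
           occupancy = 1,
           genome_length = length(g))
  }, numeric(1))
  m <- matrix(vals, nrow = world@height, ncol = world@width, byrow = TRUE)
  if (!is.null(file))
    utils::write.table(m, file, row.names = FALSE, col.names = FALSE)
  if (!is.null(imageFile)) {
    grDevices::png(imageFile, width = world@width * 4, height = world@height * 4)
    op <- graphics::par(mar = c(0, 0, 0, 0))
    z <- if (channel == "te_count") log10(1 + m) else m
    pal <- grDevices::hcl.colors(64, "viridis")
    zr <- range(z, na.rm = TRUE)
    if (!all(is.finite(zr)) || zr[1] == zr[2]) zr <- c(0, max(1, zr[2]))
    graphics::image(t(z[nrow(z):1, , drop = FALSE]), col = pal, zlim = zr,
                    axes = FALSE, useRaster = TRUE)
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(m)
}
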
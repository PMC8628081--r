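## Checkpointing: full world state to a self-describing JSON archive,
## including the RNG state so a resumed run continues the exact trajectory.

#' Save and restore a world
#'
#' \code{saveWorld} writes the complete state — configuration, every genome
#' (full numeric precision), the eDNA pool, lineage ledger, time series and
#' the current R RNG state — to a single self-describing JSON file.
#' \code{loadWorld} rebuilds the world; with \code{restoreRNG = TRUE} (the
#' default) it also restores the RNG state, so
#' run--save--load--run reproduces an uninterrupted run exactly.
#'
#' @param world a [TEWorld-class].
#' @param file path to the JSON archive.
#' @param restoreRNG restore the saved RNG state into the session.
#' @return \code{loadWorld}: the restored [TEWorld-class].
#' @export
saveWorld <- function(world, file) {
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  x <- list(
    format = "TEcoevo-world", version = 1L,
    config = configToList(world@config),
    t = world@t, width = world@width, height = world@height,
    cells = world@cells,
    lineageId = world@lineageId, depth = world@depth,
    infectedSince = world@infectedSince,
    fragElements = world@fragElements, fragSite = world@fragSite,
    nextLineage = world@nextLineage,
    openLineages = world@openLineages,
    closedLineages = world@closedLineages,
    timeSeries = world@timeSeries,
    rngState = rng)
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(x, file, digits = I(17), null = "null", na = "null",
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(file)
}

#' @rdname saveWorld
#' @export
loadWorld <- function(file, restoreRNG = TRUE) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  if (!identical(x$format, "TEcoevo-world"))
    stop("not a TEcoevo world archive: ", file)
  cfg <- configFromList(x$config)
  n <- cfg@width * cfg@height
  cells <- lapply(x$cells, function(g)
    if (is.null(g)) NULL else as.numeric(unlist(g)))
  length(cells) <- n
  asDF <- function(l, intCols) {
    d <- as.data.frame(lapply(l, unlist), stringsAsFactors = FALSE)
    if (!nrow(d)) return(d)
    for (cc in intCols) d[[cc]] <- as.integer(d[[cc]])
    d
  }
  intOrEmpty <- function(v) if (is.null(v)) integer(0) else as.integer(v)
  ol <- x$openLineages
  olDF <- if (length(ol$id)) asDF(ol, c("id", "tInfected", "members",
                                        "maxDepth")) else
    emptyLineageFrame(TRUE)
  clDF <- if (length(x$closedLineages$id))
    asDF(x$closedLineages, c("id", "tInfected", "tExtinct", "generations"))
  else emptyLineageFrame(FALSE)
  tsDF <- as.data.frame(lapply(x$timeSeries, function(col)
    unlist(lapply(col, function(v) if (is.null(v)) NA else v))))
  w <- new("TEWorld", width = cfg@width, height = cfg@height,
           t = as.integer(x$t), cells = cells,
           lineageId = intOrEmpty(x$lineageId),
           depth = intOrEmpty(x$depth),
           infectedSince = {
             v <- x$infectedSince
             as.integer(unlist(lapply(v, function(z) if (is.null(z)) NA else z)))
           },
           fragElements = lapply(x$fragElements,
                                 function(f) as.numeric(unlist(f))),
           fragSite = intOrEmpty(x$fragSite),
           nextLineage = as.integer(x$nextLineage),
           openLineages = olDF, closedLineages = clDF,
           timeSeries = tsDF, config = cfg)
  if (restoreRNG && !is.null(x$rngState))
    assign(".Random.seed", as.integer(unlist(x$rngState)),
           envir = globalenv())
  w
}
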
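## The toroidal world: configuration, initial populations, TE inoculation,
## local competition, reproduction modes, and the timestep loop.

#' Competition-parameter constructor
#'
#' @param epsilon competition regulariser.
#' @param d baseline death probability.
#' @param mode interaction mode (\code{"spatial"}, \code{"mixed_cells"},
#'   \code{"mixed_edna"}).
#' @param reproduction \code{"asexual_hgt"}, \code{"sexual"} or
#'   \code{"clonal"}.
#' @return a [CompetitionParams-class].
#' @export
competitionParams <- function(epsilon = 1.0, d = 0.02, mode = "spatial",
                              reproduction = "asexual_hgt") {
  new("CompetitionParams", epsilon = epsilon, d = d, mode = mode,
      reproduction = reproduction)
}

#' Simulation-configuration constructor
#'
#' Flat constructor over all model parameters; defaults are the standard
#' parameterisation (150 x 150 torus, c = 0.005, d = 0.02, u = 0.01,
#' j = 0.01, D = 0.01, q = 0.02, phi = 0.9, b = 1, all structural mutation
#' rates 0.001 per position, phi-mutation 0.01 with step 0.1).
#'
#' @param width,height grid dimensions.
#' @param nFunctions number of essential gene types.
#' @param c per-TE fitness penalty.
#' @param d baseline death probability.
#' @param u,D,q eDNA uptake, diffusion and degradation probabilities.
#' @param j transposition-event rate.
#' @param phi transposition rate of inoculated TEs.
#' @param b insertion damage probability.
#' @param epsilon competition regulariser.
#' @param mode,reproduction see [competitionParams()].
#' @param rates a [MutationRates-class].
#' @param initEssential,initNonCoding founding genome composition.
#' @param inoculumSize side of the central inoculation block.
#' @param uptakeMode eDNA uptake scheduling: \code{"per_fragment"} (every
#'   local fragment offered at rate u per step; the default),
#'   \code{"per_cell"} (each cell takes up at most one local fragment per
#'   step) or \code{"at_birth"} (per-fragment uptake for newborn daughters
#'   only).
#' @param sampleEvery,snapshotEvery observer intervals (steps).
#' @return a [SimConfig-class].
#' @export
simConfig <- function(width = 150, height = 150, nFunctions = 10,
                      c = 0.005, d = 0.02, u = 0.01, D = 0.01, q = 0.02,
                      j = 0.01, phi = 0.9, b = 1.0, epsilon = 1.0,
                      mode = "spatial", reproduction = "asexual_hgt",
                      rates = mutationRates(),
                      initEssential = 10, initNonCoding = 30,
                      inoculumSize = 5, uptakeMode = "per_fragment",
                      sampleEvery = 50, snapshotEvery = 1000) {
  new("SimConfig", width = as.integer(width), height = as.integer(height),
      fitness = fitnessParams(c = c, nFunctions = nFunctions),
      rates = rates,
      transposition = transpositionParams(j = j, b = b),
      edna = ednaParams(u = u, D = D, q = q),
      competition = competitionParams(epsilon = epsilon, d = d, mode = mode,
                                      reproduction = reproduction),
      initEssential = as.integer(initEssential),
      initNonCoding = as.integer(initNonCoding),
      initPhi = phi, inoculumSize = as.integer(inoculumSize),
      uptakeMode = uptakeMode,
      sampleEvery = as.integer(sampleEvery),
      snapshotEvery = as.integer(snapshotEvery))
}

## flat list consumed by the compiled engine
engineConfig <- function(config) {
  list(width = config@width, height = config@height,
       nFunctions = config@fitness@nFunctions, c = config@fitness@c,
       d = config@competition@d, u = config@edna@u, j = config@transposition@j,
       D = config@edna@D, q = config@edna@q, b = config@transposition@b,
       epsilon = config@competition@epsilon,
       modeCode = match(config@competition@mode,
                        c("spatial", "mixed_cells", "mixed_edna")) - 1L,
       reproCode = match(config@competition@reproduction,
                         c("asexual_hgt", "sexual", "clonal")) - 1L,
       uptakeCode = match(config@uptakeMode,
                          c("per_cell", "per_fragment", "at_birth")) - 1L,
       sampleEvery = config@sampleEvery,
       rates = ratesList(config@rates))
}

emptyLineageFrame <- function(open = TRUE) {
  if (open)
    data.frame(id = integer(0), tInfected = integer(0), members = integer(0),
               teProduced = numeric(0), maxDepth = integer(0))
  else
    data.frame(id = integer(0), tInfected = integer(0), tExtinct = integer(0),
               generations = integer(0), teProduced = numeric(0))
}

#' Create a world
#'
#' Builds a fully occupied grid (every site holds an identical founding
#' genome of \code{initEssential} essential genes and \code{initNonCoding}
#' non-coding positions) with an empty eDNA pool at timestep 0.  The
#' initial time-series sample is recorded.
#'
#' @param config a [SimConfig-class].
#' @param fill occupy every site (\code{TRUE}, the default) or start empty.
#' @return a [TEWorld-class].
#' @export
newWorld <- function(config = simConfig(), fill = TRUE) {
  n <- config@width * config@height
  founder <- as.numeric(standardGenome(config@initEssential,
                                       config@initNonCoding,
                                       config@fitness@nFunctions))
  cells <- if (fill) rep(list(founder), n) else vector("list", n)
  w <- new("TEWorld", width = config@width, height = config@height, t = 0L,
           cells = cells, lineageId = integer(n), depth = integer(n),
           infectedSince = rep(NA_integer_, n),
           fragElements = list(), fragSite = integer(0),
           nextLineage = 1L,
           openLineages = emptyLineageFrame(TRUE),
           closedLineages = emptyLineageFrame(FALSE),
           timeSeries = data.frame(), config = config)
  w@timeSeries <- recordTimeSeries(w)
  w
}

#' Inoculate a world with TEs
#'
#' Adds one TE (transposition rate \code{phi}) at a uniformly random genome
#' position to every cell in a \code{size} x \code{size} block at the grid
#' centre.  Inoculation models the arrival of an established infection, so
#' insertion is damage-free; each inoculated cell founds its own tracked
#' lineage.
#'
#' @param world a [TEWorld-class].
#' @param phi transposition rate of the inoculated TEs (default: the
#'   configuration's \code{initPhi}).
#' @param size block side (default: the configuration's
#'   \code{inoculumSize}).
#' @return the inoculated [TEWorld-class].
#' @export
inoculate <- function(world, phi = world@config@initPhi,
                      size = world@config@inoculumSize) {
  W <- world@width; H <- world@height
  r0 <- (H - size) %/% 2L
  c0 <- (W - size) %/% 2L
  rows <- r0 + seq_len(size); cols <- c0 + seq_len(size)
  openAdd <- list()
  for (r in rows) for (cc in cols) {
    s <- (r - 1L) * W + cc
    g <- world@cells[[s]]
    if (is.null(g)) next
    pos <- sample.int(length(g) + 1L, 1L)
    world@cells[[s]] <- append(g, teElement(phi), after = pos - 1L)
    id <- world@nextLineage
    world@nextLineage <- id + 1L
    world@lineageId[s] <- id
    world@depth[s] <- 0L
    world@infectedSince[s] <- world@t
    openAdd[[length(openAdd) + 1L]] <-
      data.frame(id = id, tInfected = world@t, members = 1L,
                 teProduced = 0, maxDepth = 0L)
  }
  if (length(openAdd))
    world@openLineages <- rbind(world@openLineages, do.call(rbind, openAdd))
  world
}

#' Advance a world
#'
#' Runs the compiled engine for \code{steps} timesteps.  Each timestep
#' applies, in fixed order: (1) death and lysis of non-viable plus randomly
#' drawn cells; (2) eDNA degradation and diffusion; (3) synchronous
#' fitness-proportional competition for every empty site from the pre-phase
#' occupancy, with asexual, sexual or clonal reproduction; (4) eDNA uptake
#' and TE integration (asexual-HGT mode only); (5) within-genome
#' transposition; (6) viability refresh (cells made inviable die in the
#' next death phase); (7) the mixing control, if any; (8) observers.
#' Time-series samples and lineage-extinction records accumulate on the
#' returned world.
#'
#' @param world a [TEWorld-class].
#' @param steps number of timesteps to run.
#' @return the advanced [TEWorld-class].
#' @examples
#' cfg <- simConfig(width = 20, height = 20, sampleEvery = 10)
#' set.seed(7)
#' w <- inoculate(newWorld(cfg))
#' w <- runWorld(w, 20)
#' timeSeries(w)
#' @export
runWorld <- function(world, steps) {
  steps <- as.integer(steps)
  if (steps < 1L) return(world)
  state <- list(cells = world@cells, lineageId = world@lineageId,
                depth = world@depth, infectedSince = world@infectedSince,
                fragElements = world@fragElements, fragSite = world@fragSite,
                t = world@t, nextLineage = world@nextLineage,
                openLineages = as.list(world@openLineages))
  res <- cpp_run(state, engineConfig(world@config), steps)
  world@cells <- res$cells
  world@lineageId <- res$lineageId
  world@depth <- res$depth
  world@infectedSince <- res$infectedSince
  world@fragElements <- res$fragElements
  world@fragSite <- res$fragSite
  world@t <- res$t
  world@nextLineage <- res$nextLineage
  world@openLineages <- as.data.frame(res$openLineages)
  newClosed <- as.data.frame(res$closedLineages)
  if (nrow(newClosed))
    world@closedLineages <- rbind(world@closedLineages, newClosed)
  newTS <- as.data.frame(res$timeSeries)
  if (nrow(newTS))
    world@timeSeries <- rbind(world@timeSeries, newTS)
  world
}

#' @rdname runWorld
#' @export
stepWorld <- function(world) runWorld(world, 1L)

#' Fitness-proportional competition for an empty site
#'
#' Draws the winner among up to eight Moore-neighbourhood competitors with
#' probability \eqn{f_i / (\sum_j f_j + \varepsilon)}; with probability
#' \eqn{\varepsilon / (\sum_j f_j + \varepsilon)} nobody wins and the site
#' stays empty.
#'
#' @param fitness numeric vector of competitor fitnesses (length 0 allowed).
#' @param params a [CompetitionParams-class], or a single numeric taken as
#'   epsilon.
#' @return 1-based index of the winner, or \code{NA} if nobody wins.
#' @export
compete <- function(fitness, params = competitionParams()) {
  eps <- if (is(params, "CompetitionParams")) params@epsilon else as.numeric(params)
  if (!length(fitness)) return(NA_integer_)
  w <- cpp_compete(as.numeric(fitness), eps)
  if (w < 0L) NA_integer_ else w + 1L
}

#' Reproduction operators
#'
#' \code{reproduceAsexual} replicates a parent genome through the mutation
#' scan.  \code{crossoverGenomes} performs the sexual-mode recombination: a
#' single cross-over in the middle of the two genomes, taking the left
#' \code{floor(L1 / 2)} elements of the first parent and the right
#' \code{L2 - floor(L2 / 2)} elements of the second.
#' \code{reproduceSexual} recombines then mutates, exactly as the engine
#' does for a sexually produced daughter.
#'
#' @param parent,parent1,parent2 parental [Genome-class] objects.
#' @param rates a [MutationRates-class].
#' @return the daughter [Genome-class].
#' @examples
#' length(reproduceSexual(Genome(1:10), Genome(1:12), zero <- mutationRates(0,0,0,0,0)))
#' @export
reproduceAsexual <- function(parent, rates = mutationRates()) {
  mutateGenome(parent, rates)
}

#' @rdname reproduceAsexual
#' @export
crossoverGenomes <- function(parent1, parent2) {
  Genome(cpp_crossover(as.numeric(parent1), as.numeric(parent2)))
}

#' @rdname reproduceAsexual
#' @export
reproduceSexual <- function(parent1, parent2, rates = mutationRates()) {
  mutateGenome(crossoverGenomes(parent1, parent2), rates)
}

## ---------------------------------------------------------------- accessors

#' World accessors
#'
#' \code{nCells} counts living cells; \code{teAbundance} counts TE copies in
#' cellular genomes and in the eDNA pool; \code{meanFitness} averages over
#' living cells; \code{genomes} extracts occupied-site genomes;
#' \code{timeSeries} and \code{lineageRecords} return the accumulated
#' observer output.
#'
#' @param world a [TEWorld-class].
#' @return see individual descriptions.
#' @export
nCells <- function(world) {
  sum(!vapply(world@cells, is.null, logical(1)))
}

#' @rdname nCells
#' @export
teAbundance <- function(world) {
  cellular <- sum(vapply(world@cells, function(g)
    if (is.null(g)) 0L else sum(g < -0.5), integer(1)))
  pool <- sum(vapply(world@fragElements, function(f) sum(f < -0.5), integer(1)))
  c(cellular = cellular, pool = pool, total = cellular + pool)
}

#' @rdname nCells
#' @export
meanFitness <- function(world) {
  occ <- !vapply(world@cells, is.null, logical(1))
  if (!any(occ)) return(NA_real_)
  fp <- world@config@fitness
  mean(vapply(world@cells[occ], cpp_fitness, numeric(1), c = fp@c,
              nFunctions = fp@nFunctions))
}

#' @rdname nCells
#' @export
genomes <- function(world) {
  occ <- !vapply(world@cells, is.null, logical(1))
  lapply(world@cells[occ], Genome)
}

#' @rdname nCells
#' @export
timeSeries <- function(world) world@timeSeries

#' @describeIn TEWorld-class grid dimensions as \code{c(height, width)}.
#' @param x a \code{TEWorld}.
#' @export
setMethod("dim", "TEWorld", function(x) c(x@height, x@width))

#' @describeIn TEWorld-class one-glance summary of a world.
#' @param object a \code{TEWorld}.
#' @export
setMethod("show", "TEWorld", function(object) {
  te <- teAbundance(object)
  cat(sprintf("TEWorld %dx%d (toroidal), t = %d\n",
              object@width, object@height, object@t))
  cat(sprintf("  cells: %d / %d sites occupied\n", nCells(object),
              object@width * object@height))
  cat(sprintf("  TEs: %d cellular, %d in eDNA pool (%d fragments)\n",
              te[["cellular"]], te[["pool"]], length(object@fragSite)))
  cat(sprintf("  lineages: %d infected alive, %d extinct on record\n",
              nrow(object@openLineages), nrow(object@closedLineages)))
  cat(sprintf("  mode: %s / %s\n", object@config@competition@mode,
              object@config@competition@reproduction))
  invisible(object)
})

#' @describeIn SimConfig-class parameter summary.
#' @param object a \code{SimConfig}.
#' @export
setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %dx%d grid, %d essential functions\n",
              object@width, object@height, object@fitness@nFunctions))
  cat(sprintf("  c=%g d=%g u=%g j=%g D=%g q=%g b=%g phi0=%g eps=%g\n",
              object@fitness@c, object@competition@d, object@edna@u,
              object@transposition@j, object@edna@D, object@edna@q,
              object@transposition@b, object@initPhi,
              object@competition@epsilon))
  r <- object@rates
  cat(sprintf("  rates: dup=%g del=%g inact=%g large=%g phiMut=%g step=%g\n",
              r@singleDup, r@singleDel, r@inactivation, r@largeScale,
              r@phiMut, r@phiStep))
  cat(sprintf("  init genome: %d essential + %d non-coding; mode %s / %s\n",
              object@initEssential, object@initNonCoding,
              object@competition@mode, object@competition@reproduction))
  invisible(object)
})
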
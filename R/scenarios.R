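## Canned scenario runners, outcome classification, configuration files.

scenarioNames <- c("ecology_sweep", "evolve", "evolve_mixed",
                   "sexual_compare", "b_sweep", "no_hgt")

## desk-scale defaults: a 75x75 torus keeps local extinctions, infection
## wavefronts and multiple strains simultaneously possible while staying
## tractable; run lengths are chosen per scenario so the phenomenon under
## study has time to complete (see the package vignette).
scenarioDefaults <- function(name) {
  base <- list(width = 75, height = 75, nSeeds = 5,
               phi = 0.9, b = 1.0, mode = "spatial",
               initNonCoding = 30, sampleEvery = 50)
  extra <- switch(name,
    ecology_sweep = list(steps = 5000, nonCodingValues = c(0, 10, 30, 90),
                         mutations = FALSE),
    evolve = list(steps = 20000, mutations = TRUE),
    evolve_mixed = list(steps = 20000, mutations = TRUE,
                        mode = "mixed_cells", initNonCoding = 10),
    sexual_compare = list(steps = 10000, mutations = TRUE,
                          reproductionValues = c("asexual_hgt", "sexual",
                                                 "clonal")),
    b_sweep = list(steps = 20000, mutations = TRUE, bValues = c(0, 1)),
    no_hgt = list(steps = 10000, mutations = TRUE, reproduction = "clonal"),
    stop("unknown scenario: ", name))
  modifyList(base, extra)
}

scenarioRunConfig <- function(p, nonCoding, b, mode, reproduction) {
  rates <- if (isTRUE(p$mutations)) mutationRates() else zeroRates()
  simConfig(width = p$width, height = p$height, phi = p$phi, b = b,
            mode = mode, reproduction = reproduction, rates = rates,
            initNonCoding = nonCoding, sampleEvery = p$sampleEvery)
}

#' Run a canned scenario
#'
#' Mirrors the model's main experiments at desk scale (75 x 75 grid,
#' multiple seeds): \code{"ecology_sweep"} fixes all mutation rates to zero
#' and sweeps the founding non-coding content at fixed phi, classifying each
#' run as host extinction, TE extinction or coexistence;
#' \code{"evolve"} runs the full evolutionary model from 10 essential + 30
#' non-coding founders with a central TE inoculum; \code{"evolve_mixed"}
#' repeats it with cells shuffled every step; \code{"sexual_compare"} runs
#' asexual-with-HGT, sexual and strictly clonal populations side by side;
#' \code{"b_sweep"} varies the insertion-damage probability b (including the
#' damage-free b = 0 control); \code{"no_hgt"} disables DNA uptake.
#'
#' Every run is reproducible from \code{seed}: per-run seeds are derived
#' once, and rerunning with the same seed gives byte-identical outputs.
#'
#' @param name scenario name (see above).
#' @param seed master seed.
#' @param outDir optional output directory; when given, the configuration
#'   (YAML), per-run time series and lineage records (CSV), a summary table
#'   (CSV) and a final snapshot per condition are written there.
#' @param overrides named list overriding scenario parameters
#'   (\code{width}, \code{height}, \code{steps}, \code{nSeeds}, \code{phi},
#'   \code{b}, \code{mode}, \code{nonCodingValues}, \code{bValues},
#'   \code{reproductionValues}, \code{initNonCoding}, \code{sampleEvery}).
#' @param keepWorlds keep the final [TEWorld-class] of every run in the
#'   result (memory-heavy; default \code{FALSE}).
#' @return a list with \code{name}, \code{summary} (one row per run:
#'   condition, seed, outcome and final statistics), \code{timeSeries} and
#'   \code{lineages} (named lists, one per run), and \code{outDir}.
#' @export
runScenario <- function(name = scenarioNames, seed = 1, outDir = NULL,
                        overrides = list(), keepWorlds = FALSE) {
  name <- match.arg(name)
  p <- modifyList(scenarioDefaults(name), overrides)

  conditions <- switch(name,
    ecology_sweep = data.frame(nonCoding = p$nonCodingValues),
    b_sweep = data.frame(b = p$bValues),
    sexual_compare = data.frame(reproduction = p$reproductionValues,
                                stringsAsFactors = FALSE),
    data.frame(dummy = 1))
  nCond <- nrow(conditions)
  nRuns <- nCond * p$nSeeds

  set.seed(seed)
  runSeeds <- sample.int(.Machine$integer.max - 1L, nRuns)

  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  summary <- NULL
  tsList <- list()
  linList <- list()
  worlds <- list()
  run <- 0L
  for (ci in seq_len(nCond)) {
    nc <- if (!is.null(conditions$nonCoding)) conditions$nonCoding[ci] else
      p$initNonCoding
    b <- if (!is.null(conditions$b)) conditions$b[ci] else p$b
    repro <- if (!is.null(conditions$reproduction))
      conditions$reproduction[ci] else
        if (!is.null(p$reproduction)) p$reproduction else "asexual_hgt"
    cfg <- scenarioRunConfig(p, nc, b, p$mode, repro)
    condLabel <- switch(name,
      ecology_sweep = sprintf("nc%d", nc),
      b_sweep = sprintf("b%g", b),
      sexual_compare = repro,
      name)
    for (si in seq_len(p$nSeeds)) {
      run <- run + 1L
      set.seed(runSeeds[run])
      w <- inoculate(newWorld(cfg))
      w <- runWorld(w, p$steps)
      ts <- timeSeries(w)
      outcome <- classifyOutcome(ts)
      last <- ts[nrow(ts), ]
      label <- sprintf("%s_seed%d", condLabel, si)
      tsList[[label]] <- ts
      linList[[label]] <- lineageRecords(w)
      if (keepWorlds) worlds[[label]] <- w
      summary <- rbind(summary, data.frame(
        run = label, condition = condLabel, seed = runSeeds[run],
        outcome = outcome, nCells = last$nCells,
        teCellular = ifelse(last$nCells > 0, last$meanTE * last$nCells, 0),
        tePool = last$poolTE, meanLength = last$meanLength,
        meanNonCoding = last$meanNonCoding, meanPhi = last$meanPhi,
        meanFitness = last$meanFitness, stringsAsFactors = FALSE))
      if (!is.null(outDir)) {
        write.csv(ts, file.path(outDir, paste0("timeseries_", label, ".csv")),
                  row.names = FALSE)
        write.csv(linList[[label]],
                  file.path(outDir, paste0("lineages_", label, ".csv")),
                  row.names = FALSE)
        if (si == 1L)
          exportSnapshot(w, "te_count",
                         file = file.path(outDir,
                                          paste0("snapshot_", condLabel, ".txt")),
                         imageFile = file.path(outDir,
                                               paste0("snapshot_", condLabel,
                                                      ".png")))
      }
    }
    if (!is.null(outDir) && ci == 1L)
      writeSimConfig(cfg, file.path(outDir, "config.yaml"))
  }
  rownames(summary) <- NULL
  if (!is.null(outDir))
    write.csv(summary, file.path(outDir, "summary.csv"), row.names = FALSE)
  out <- list(name = name, summary = summary, timeSeries = tsList,
              lineages = linList, seed = seed, outDir = outDir)
  if (keepWorlds) out$worlds <- worlds
  out
}

#' Classify the outcome of a completed run
#'
#' \code{hosts_extinct} if no living cells remain; \code{tes_extinct} if
#' hosts live but no TE copy remains in cells or the eDNA pool;
#' \code{coexistence} if both persist and TE abundance is non-trending over
#' the final quarter of the time series; \code{undecided} if both persist
#' but the final-quarter trend is still strong (apparent coexistence that
#' has not reached a steady state).  The trend test fits a linear slope to
#' total TE abundance over the final quarter and calls the run undecided
#' when the fitted change exceeds half the window mean at p < 0.01.
#'
#' @param ts a time-series \code{data.frame} as returned by [timeSeries()].
#' @return one of \code{"hosts_extinct"}, \code{"tes_extinct"},
#'   \code{"coexistence"}, \code{"undecided"}.
#' @export
classifyOutcome <- function(ts) {
  stopifnot(nrow(ts) >= 1)
  teTot <- ifelse(ts$nCells > 0, ts$meanTE * ts$nCells, 0) + ts$poolTE
  last <- nrow(ts)
  if (ts$nCells[last] == 0) return("hosts_extinct")
  if (teTot[last] == 0) return("tes_extinct")
  qi <- ts$t >= ts$t[last] - (ts$t[last] - ts$t[1]) / 4
  t4 <- ts$t[qi]; te4 <- teTot[qi]
  if (length(t4) < 3 || stats::var(te4) == 0) return("coexistence")
  fit <- stats::lm(te4 ~ t4)
  sl <- suppressWarnings(summary(fit)$coefficients)
  change <- abs(coef(fit)[2] * (max(t4) - min(t4)))
  p <- if (nrow(sl) >= 2) sl[2, 4] else NA_real_
  # an NaN p-value means a perfect linear fit: certainly trending
  if (change > 0.5 * mean(te4) && (is.na(p) || p < 0.01))
    "undecided"
  else
    "coexistence"
}

## ---------------------------------------------------------- config files

configToList <- function(config) {
  list(width = config@width, height = config@height,
       nFunctions = config@fitness@nFunctions, c = config@fitness@c,
       d = config@competition@d, u = config@edna@u, D = config@edna@D,
       q = config@edna@q, j = config@transposition@j, phi = config@initPhi,
       b = config@transposition@b, epsilon = config@competition@epsilon,
       mode = config@competition@mode,
       reproduction = config@competition@reproduction,
       rates = ratesList(config@rates),
       initEssential = config@initEssential,
       initNonCoding = config@initNonCoding,
       inoculumSize = config@inoculumSize,
       uptakeMode = config@uptakeMode,
       sampleEvery = config@sampleEvery,
       snapshotEvery = config@snapshotEvery)
}

configFromList <- function(x) {
  r <- x$rates
  simConfig(width = x$width, height = x$height, nFunctions = x$nFunctions,
            c = x$c, d = x$d, u = x$u, D = x$D, q = x$q, j = x$j,
            phi = x$phi, b = x$b, epsilon = x$epsilon, mode = x$mode,
            reproduction = x$reproduction,
            rates = mutationRates(r$singleDup, r$singleDel, r$inactivation,
                                  r$largeScale, r$phiMut, r$phiStep),
            initEssential = x$initEssential,
            initNonCoding = x$initNonCoding,
            inoculumSize = x$inoculumSize,
            uptakeMode = if (is.null(x$uptakeMode)) "per_fragment" else
              x$uptakeMode,
            sampleEvery = x$sampleEvery,
            snapshotEvery = x$snapshotEvery)
}

#' Configuration files
#'
#' Round-trip a [SimConfig-class] through a YAML key-value file, so that a
#' run directory fully documents (and can reproduce) its parameters.
#'
#' @param config a [SimConfig-class].
#' @param file path to the YAML file.
#' @return \code{readSimConfig}: a [SimConfig-class].
#' @export
writeSimConfig <- function(config, file) {
  yaml::write_yaml(configToList(config), file)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(file) {
  configFromList(yaml::read_yaml(file))
}
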
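## S4 classes for genomes, parameter blocks, configurations and worlds.
##
## Genetic elements are encoded in a single numeric value:
##   0              non-coding DNA
##   k in 1..26     essential gene of type k (letter 'a' = 1, 'b' = 2, ...)
##   v in [-2, -1]  transposable element with transposition rate phi = -v - 1
## The encoding keeps a genome a plain numeric vector, which the compiled
## engine consumes directly.

#' Linear genome of genetic elements
#'
#' A \code{Genome} is an ordered, possibly empty, linear sequence of genetic
#' elements: essential genes (types \code{a}--\code{j} by default),
#' transposable elements each carrying its own transposition rate
#' \eqn{\varphi \in [0,1]}, and non-coding positions.  Order is meaningful:
#' mutation operators and cross-over act positionally.  Internally the class
#' extends \code{numeric} with one encoded value per element.
#'
#' @slot .Data numeric vector of encoded elements.
#' @seealso [teElement()], [essentialElement()], [nonCodingElement()],
#'   [standardGenome()], [genomeFromString()]
#' @export
setClass("Genome", contains = "numeric")

setValidity("Genome", function(object) {
  v <- object@.Data
  ok <- (v >= -2 & v <= -1) | v == 0 |
    (v >= 1 & v <= 26 & abs(v - round(v)) < 1e-9)
  if (all(ok)) TRUE else
    sprintf("%d element(s) outside the valid encoding", sum(!ok))
})

#' Fitness parameters
#'
#' @slot c per-TE fitness penalty (default 0.005).
#' @slot nFunctions number of distinct essential gene types a viable genome
#'   must carry (default 10, i.e. the minimal viable genome has 10 elements).
#' @export
setClass("FitnessParams",
  representation(c = "numeric", nFunctions = "integer"))

setValidity("FitnessParams", function(object) {
  if (object@c < 0) return("c must be >= 0")
  if (object@nFunctions < 1L || object@nFunctions > 26L)
    return("nFunctions must be in 1..26")
  TRUE
})

#' Replication-time mutation rates
#'
#' Per-position probabilities applied in a single left-to-right scan of the
#' genome at every replication, plus the TE transposition-rate mutation.
#'
#' @slot singleDup per-position probability of a tandem single-element
#'   duplication (default 0.001).
#' @slot singleDel per-position probability of a single-element deletion
#'   (default 0.001).
#' @slot inactivation per-position probability that the element becomes
#'   non-coding (default 0.001).
#' @slot largeScale per-position probability of seeding a large-scale
#'   duplication, deletion or inversion, each equally likely (default 0.001).
#'   The affected segment covers on average a quarter of the genome.
#' @slot phiMut probability per TE replication that its transposition rate
#'   phi changes (default 0.01).
#' @slot phiStep magnitude of the phi change, applied up or down with equal
#'   probability and clamped to \[0, 1\] (default 0.1).
#' @export
setClass("MutationRates",
  representation(singleDup = "numeric", singleDel = "numeric",
                 inactivation = "numeric", largeScale = "numeric",
                 phiMut = "numeric", phiStep = "numeric"))

setValidity("MutationRates", function(object) {
  p <- c(object@singleDup, object@singleDel, object@inactivation,
         object@largeScale, object@phiMut)
  if (any(p < 0 | p > 1)) return("all rates must be probabilities in [0,1]")
  if (object@phiStep <= 0) return("phiStep must be > 0")
  TRUE
})

#' Within-genome transposition parameters
#'
#' @slot j per-timestep probability of a transposition opportunity per TE
#'   (default 0.01); a TE with rate phi then replicates with probability
#'   phi * j.
#' @slot b probability that an insertion inactivates the coding element at
#'   the insertion site (default 1).  With \code{b = 0} TEs insert between
#'   elements and never cause damage.
#' @export
setClass("TranspositionParams",
  representation(j = "numeric", b = "numeric"))

setValidity("TranspositionParams", function(object) {
  if (object@j < 0 || object@j > 1) return("j must be in [0,1]")
  if (object@b < 0 || object@b > 1) return("b must be in [0,1]")
  TRUE
})

#' Extracellular-DNA pool parameters
#'
#' @slot u per-fragment uptake probability by a co-located living cell
#'   (default 0.01).
#' @slot D per-fragment probability of diffusing to a random Moore neighbour
#'   each step (default 0.01).
#' @slot q per-fragment degradation probability each step (default 0.02),
#'   giving a mean fragment lifetime of 1/q steps.
#' @export
setClass("EdnaParams",
  representation(u = "numeric", D = "numeric", q = "numeric"))

setValidity("EdnaParams", function(object) {
  p <- c(object@u, object@D, object@q)
  if (any(p < 0 | p > 1)) return("u, D, q must be in [0,1]") else TRUE
})

#' Competition, death and reproduction-mode parameters
#'
#' @slot epsilon regulariser added to the summed fitness of the competitors
#'   for an empty site; with probability epsilon / (sum(f) + epsilon) nobody
#'   wins, so a lone unfit individual does not reproduce by default
#'   (default 1).
#' @slot d baseline per-step death probability of viable cells (default 0.02).
#' @slot mode \code{"spatial"} (local interactions), \code{"mixed_cells"}
#'   (cells shuffled to random sites after each replication round) or
#'   \code{"mixed_edna"} (only the eDNA pool is shuffled).
#' @slot reproduction \code{"asexual_hgt"} (clonal reproduction plus eDNA
#'   uptake), \code{"sexual"} (two fitness-sampled parents, single mid-genome
#'   cross-over, no eDNA uptake) or \code{"clonal"} (no uptake, no sex).
#' @export
setClass("CompetitionParams",
  representation(epsilon = "numeric", d = "numeric", mode = "character",
                 reproduction = "character"))

setValidity("CompetitionParams", function(object) {
  if (object@epsilon < 0) return("epsilon must be >= 0")
  if (object@d < 0 || object@d > 1) return("d must be in [0,1]")
  if (!object@mode %in% c("spatial", "mixed_cells", "mixed_edna"))
    return("unknown mode")
  if (!object@reproduction %in% c("asexual_hgt", "sexual", "clonal"))
    return("unknown reproduction mode")
  TRUE
})

#' Full simulation configuration
#'
#' Aggregates every model parameter plus the initial genome composition,
#' TE inoculation spec, and observer sampling intervals.  Defaults reproduce
#' the standard parameterisation of the model.
#'
#' @slot width,height grid dimensions (toroidal).
#' @slot fitness a [FitnessParams-class].
#' @slot rates a [MutationRates-class].
#' @slot transposition a [TranspositionParams-class].
#' @slot edna an [EdnaParams-class].
#' @slot competition a [CompetitionParams-class].
#' @slot initEssential,initNonCoding composition of the founding genome:
#'   number of essential genes (cycling through the gene types) and of
#'   non-coding positions, interleaved evenly.
#' @slot initPhi transposition rate of inoculated TEs (default 0.9).
#' @slot inoculumSize side of the central square block of cells that receive
#'   one TE each at inoculation (default 5).
#' @slot uptakeMode how uptake of local eDNA is scheduled.
#'   \code{"per_fragment"} (the default): every co-located fragment is
#'   offered to the resident cell with probability \code{u} each step.
#'   \code{"per_cell"}: each living cell takes up, with probability
#'   \code{u} per step, at most one fragment, uniformly chosen from its own
#'   site and Moore neighbourhood.
#'   \code{"at_birth"}: as \code{"per_fragment"}, but only daughters are
#'   competent, in the step of their birth.
#' @slot sampleEvery time-series sampling interval in steps (default 50).
#' @slot snapshotEvery grid-snapshot interval in steps (default 1000).
#' @export
setClass("SimConfig",
  representation(width = "integer", height = "integer",
                 fitness = "FitnessParams", rates = "MutationRates",
                 transposition = "TranspositionParams", edna = "EdnaParams",
                 competition = "CompetitionParams",
                 initEssential = "integer", initNonCoding = "integer",
                 initPhi = "numeric", inoculumSize = "integer",
                 uptakeMode = "character",
                 sampleEvery = "integer", snapshotEvery = "integer"))

setValidity("SimConfig", function(object) {
  if (object@width < 1L || object@height < 1L)
    return("grid dimensions must be positive")
  if (object@initPhi < 0 || object@initPhi > 1)
    return("initPhi must be in [0,1]")
  if (object@initEssential < 0L || object@initNonCoding < 0L)
    return("initial composition counts must be >= 0")
  if (object@sampleEvery < 1L) return("sampleEvery must be >= 1")
  if (!object@uptakeMode %in% c("per_cell", "per_fragment", "at_birth"))
    return("unknown uptakeMode")
  TRUE
})

#' A simulated world
#'
#' The complete state of one simulation: a toroidal grid of sites, each
#' holding at most one cell (a genome plus lineage bookkeeping) and a
#' multiset of extracellular DNA fragments, together with the configuration,
#' the accumulated time series and the lineage ledger.  Worlds are value
#' objects: [runWorld()] returns an advanced copy.
#'
#' @slot width,height grid dimensions.
#' @slot t current timestep.
#' @slot cells list of length \code{width * height}; \code{NULL} for an empty
#'   site, otherwise the encoded genome (possibly of length zero).
#' @slot lineageId,depth,infectedSince per-site lineage bookkeeping; lineage
#'   id 0 means the cell belongs to no TE-infected lineage.
#' @slot fragElements,fragSite the eDNA pool: encoded fragments and their
#'   1-based site indices.
#' @slot nextLineage next unused lineage identifier.
#' @slot openLineages,closedLineages lineage ledger: infected lineages still
#'   alive, and records closed at lineage extinction (see [lineageRecords()]).
#' @slot timeSeries accumulated time-series samples (see [timeSeries()]).
#' @slot config the [SimConfig-class] the world runs under.
#' @export
setClass("TEWorld",
  representation(width = "integer", height = "integer", t = "integer",
                 cells = "list", lineageId = "integer", depth = "integer",
                 infectedSince = "integer", fragElements = "list",
                 fragSite = "integer", nextLineage = "integer",
                 openLineages = "data.frame", closedLineages = "data.frame",
                 timeSeries = "data.frame", config = "SimConfig"))

setValidity("TEWorld", function(object) {
  n <- object@width * object@height
  if (length(object@cells) != n) return("cells list does not match grid size")
  if (length(object@lineageId) != n || length(object@depth) != n ||
      length(object@infectedSince) != n)
    return("per-site vectors do not match grid size")
  if (length(object@fragElements) != length(object@fragSite))
    return("fragment elements and sites differ in length")
  if (length(object@fragSite) && (any(object@fragSite < 1L) ||
      any(object@fragSite > n)))
    return("fragment site index out of range")
  TRUE
})
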
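## Death-and-lysis fragmentation, the grid-resident eDNA pool, and uptake
## with TE integration.

#' eDNA-parameter constructor
#'
#' @param u per-fragment uptake probability.
#' @param D per-fragment diffusion probability (to a random Moore neighbour).
#' @param q per-fragment degradation probability.
#' @return an [EdnaParams-class].
#' @export
ednaParams <- function(u = 0.01, D = 0.01, q = 0.02) {
  new("EdnaParams", u = u, D = D, q = q)
}

#' Fragment a dead cell's genome
#'
#' The genome is partitioned left to right into contiguous fragments whose
#' lengths are drawn iid uniform on 3..8 elements; a final remainder shorter
#' than its draw is kept as its own (possibly short) fragment so that the
#' fragments always partition the genome exactly.
#'
#' @param genome a [Genome-class].
#' @return list of [Genome-class] fragments (empty list for an empty
#'   genome).
#' @examples
#' set.seed(1)
#' frags <- lyse(standardGenome())
#' sum(lengths(frags))  # 40: conservation
#' @export
lyse <- function(genome) {
  lapply(cpp_lyse(as.numeric(genome)), Genome)
}

#' One step of eDNA pool dynamics
#'
#' Independently per fragment: removed with probability \code{q}; each
#' survivor then moves to a uniformly chosen Moore neighbour on the torus
#' with probability \code{D}, else stays put.
#'
#' @param pool a list with components \code{elements} (list of encoded
#'   fragments) and \code{site} (1-based site indices).
#' @param params an [EdnaParams-class].
#' @param width,height grid dimensions.
#' @return the updated pool in the same form.
#' @export
stepEdna <- function(pool, params = ednaParams(), width, height) {
  res <- cpp_step_edna(pool$elements, as.integer(pool$site),
                       as.integer(width), as.integer(height),
                       params@D, params@q)
  list(elements = res$elements, site = res$site)
}

#' Uptake of co-located eDNA with TE integration
#'
#' Each fragment is taken up with probability \code{u}.  For every TE in a
#' taken-up fragment, with probability equal to that TE's own phi it
#' integrates into the genome at a uniformly random position, with insertion
#' damage \code{b}; integrated copies are offered a phi-mutation (uptake
#' integration is a TE replication).  Non-TE fragment content and
#' non-integrating TEs are inert and lost: with no sequence homology there
#' is no recombination route for essential or non-coding eDNA.
#'
#' @param genome the living cell's [Genome-class].
#' @param fragments list of encoded fragments co-located with the cell.
#' @param params an [EdnaParams-class] (only \code{u} is used here).
#' @param b insertion damage probability.
#' @param rates a [MutationRates-class].
#' @return list: \code{genome} (updated), \code{consumed} (logical per
#'   fragment), \code{integrated} (number of TE copies integrated).
#' @export
uptakeAndIntegrate <- function(genome, fragments, params = ednaParams(),
                               b = 1.0, rates = mutationRates()) {
  res <- cpp_uptake(as.numeric(genome), lapply(fragments, as.numeric),
                    params@u, b, ratesList(rates))
  list(genome = Genome(res$genome), consumed = res$consumed,
       integrated = res$integrated)
}
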
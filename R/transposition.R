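## Within-genome TE replication and the insertion / damage semantics.

#' Transposition-parameter constructor
#'
#' @param j per-timestep probability of a transposition opportunity per TE.
#' @param b probability that insertion inactivates the coding element at the
#'   insertion site; \code{b = 0} models TEs that insert cleanly between
#'   elements.
#' @return a [TranspositionParams-class].
#' @export
transpositionParams <- function(j = 0.01, b = 1.0) {
  new("TranspositionParams", j = j, b = b)
}

#' Insert a TE into a genome
#'
#' The TE is inserted so that it occupies position \code{pos}
#' (\code{pos = length + 1} appends).  If an element is displaced and it is
#' coding (an essential gene or another TE), it is inactivated — converted
#' to a non-coding element, staying in the genome — with probability
#' \code{b}.  Non-coding targets are never damaged.  Genome length always
#' grows by exactly one.
#'
#' @param genome a [Genome-class].
#' @param te encoded TE element to insert (see [teElement()]).
#' @param pos 1-based insertion position in \code{1..length(genome) + 1}.
#' @param b damage probability.
#' @return a list: \code{genome} (the new [Genome-class]), \code{damaged}
#'   (was any coding element inactivated) and \code{damagedEssential}
#'   (was it an essential gene).
#' @examples
#' res <- insertTE(minimalGenome(), teElement(0.9), 3, b = 1)
#' res$damagedEssential         # TRUE: gene 'c' lost
#' isViable(res$genome)         # FALSE
#' @export
insertTE <- function(genome, te, pos, b = 1.0) {
  v <- as.numeric(genome)
  stopifnot(pos >= 1, pos <= length(v) + 1L, te < -0.5)
  res <- cpp_insert_te(v, -as.numeric(te) - 1, as.integer(pos) - 1L, b)
  list(genome = Genome(res$genome),
       damaged = res$damage > 0L,
       damagedEssential = res$damage == 2L)
}

#' One timestep of within-genome transposition
#'
#' Each TE present at entry gets one opportunity to replicate, firing with
#' probability \eqn{\varphi j} (its own transposition rate times the global
#' event rate).  Replication is copy-and-paste: the original stays in place
#' and the new copy is inserted at a uniformly random position (damage per
#' \code{b}); the new copy is offered a phi-mutation, as every TE
#' replication is.  Copies created during the step do not themselves
#' replicate in the same step.
#'
#' @param genome a [Genome-class].
#' @param params a [TranspositionParams-class].
#' @param rates a [MutationRates-class] (for the phi-mutation of new copies).
#' @return the updated [Genome-class].
#' @export
lifetimeTransposition <- function(genome, params = transpositionParams(),
                                  rates = mutationRates()) {
  Genome(cpp_lifetime_transposition(as.numeric(genome), params@j, params@b,
                                    ratesList(rates)))
}
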
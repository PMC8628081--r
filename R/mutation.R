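## Replication-time mutation operators: the left-to-right scan, the
## single-element and large-scale events, and TE transposition-rate mutation.

#' Mutation-rate constructor
#'
#' Defaults are the standard parameterisation: every structural event at
#' 0.001 per position, phi-mutation at 0.01 per TE replication with a
#' uniform step of +/-0.1.
#'
#' @param singleDup,singleDel,inactivation,largeScale per-position event
#'   probabilities.
#' @param phiMut,phiStep TE transposition-rate mutation probability and step.
#' @return a [MutationRates-class].
#' @export
mutationRates <- function(singleDup = 0.001, singleDel = 0.001,
                          inactivation = 0.001, largeScale = 0.001,
                          phiMut = 0.01, phiStep = 0.1) {
  new("MutationRates", singleDup = singleDup, singleDel = singleDel,
      inactivation = inactivation, largeScale = largeScale,
      phiMut = phiMut, phiStep = phiStep)
}

## zero out the structural + phi rates, e.g. for the ecological sweeps
zeroRates <- function() {
  mutationRates(0, 0, 0, 0, 0, 0.1)
}

ratesList <- function(r) {
  list(singleDup = r@singleDup, singleDel = r@singleDel,
       inactivation = r@inactivation, largeScale = r@largeScale,
       phiMut = r@phiMut, phiStep = r@phiStep)
}

#' Replication-time genome scan
#'
#' Scans the genome left to right, offering each original position the
#' structural events in fixed order (large-scale event, single duplication,
#' single deletion, inactivation); the first event that fires is applied and
#' the scan moves on, so at most one structural mutation happens per scanned
#' position.  Copies created by duplications are not re-scanned within the
#' same pass.  Each surviving TE is additionally offered one phi-mutation
#' (replication of the genome replicates every TE it carries).
#'
#' @param genome a [Genome-class].
#' @param rates a [MutationRates-class].
#' @return the mutated [Genome-class] (the input is not modified).
#' @examples
#' set.seed(1)
#' mutateGenome(standardGenome(), mutationRates())
#' @export
mutateGenome <- function(genome, rates = mutationRates()) {
  Genome(cpp_mutate_genome(as.numeric(genome), ratesList(rates)))
}

#' Single-element events
#'
#' \code{applySingleDuplication} inserts a copy of the element at \code{pos}
#' immediately after it (tandem duplication).  \code{applyInactivation}
#' converts the element at \code{pos} to non-coding, which is how both gene
#' inactivation and TE inactivation are represented.
#'
#' @param genome a [Genome-class].
#' @param pos 1-based position, \code{1 <= pos <= length(genome)}.
#' @return the modified [Genome-class].
#' @export
applySingleDuplication <- function(genome, pos) {
  v <- as.numeric(genome)
  stopifnot(pos >= 1, pos <= length(v))
  Genome(append(v, v[pos], after = pos))
}

#' @rdname applySingleDuplication
#' @export
applyInactivation <- function(genome, pos) {
  v <- as.numeric(genome)
  stopifnot(pos >= 1, pos <= length(v))
  v[pos] <- 0
  Genome(v)
}

#' Large-scale duplication, deletion or inversion
#'
#' A contiguous segment starting at \code{pos} is tandem-duplicated, deleted,
#' or reversed in place.  If \code{segLen} is \code{NULL} the length is drawn
#' from the standard distribution (uniform on 1 to just under half the
#' genome, so a single event covers on average 25\% of the genome); segments
#' running past the genome end are truncated there (the genome is linear).
#'
#' @param genome a [Genome-class].
#' @param pos 1-based start of the segment.
#' @param kind \code{"duplication"}, \code{"deletion"} or \code{"inversion"}.
#' @param segLen segment length, or \code{NULL} to draw it.
#' @return the modified [Genome-class].
#' @examples
#' applyLargeScale(Genome(1:4), 1, "inversion", 4)  # reversed
#' @export
applyLargeScale <- function(genome, pos,
                            kind = c("duplication", "deletion", "inversion"),
                            segLen = NULL) {
  kind <- match.arg(kind)
  v <- as.numeric(genome)
  stopifnot(pos >= 1, pos <= length(v))
  code <- match(kind, c("duplication", "deletion", "inversion")) - 1L
  Genome(cpp_apply_large_scale(v, as.integer(pos) - 1L, code,
                               if (is.null(segLen)) -1L else as.integer(segLen)))
}

#' @describeIn applyLargeScale draw one segment length for a genome of the
#'   given length (exposed for calibration checks).
#' @param genomeLength current genome length.
#' @export
drawSegmentLength <- function(genomeLength) {
  cpp_draw_segment_length(as.integer(genomeLength))
}

#' TE transposition-rate mutation
#'
#' With probability \code{phiMut} the transposition rate of a TE changes by
#' exactly \code{phiStep} up or down (equal probability), clamped to
#' \[0, 1\] since phi is used as a probability.
#'
#' @param te an encoded TE element (see [teElement()]).
#' @param rates a [MutationRates-class].
#' @return the (possibly mutated) encoded TE element.
#' @export
mutatePhi <- function(te, rates = mutationRates()) {
  v <- as.numeric(te)
  stopifnot(length(v) == 1L)
  if (v >= -0.5) stop("mutatePhi() requires a transposon element")
  teElement(cpp_mutate_phi(-v - 1, rates@phiMut, rates@phiStep))
}
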
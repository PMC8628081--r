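## Genome construction, census, viability and fitness.

#' Construct a genome from encoded elements
#'
#' @param elements numeric vector of encoded elements (see
#'   [Genome-class]); usually built with [essentialElement()],
#'   [teElement()] and [nonCodingElement()].
#' @return a [Genome-class].
#' @examples
#' g <- Genome(c(essentialElement("a"), teElement(0.9), nonCodingElement()))
#' computeFitness(g, fitnessParams(nFunctions = 1))
#' @export
Genome <- function(elements = numeric(0)) {
  new("Genome", as.numeric(elements))
}

#' Encoded genetic elements
#'
#' Helpers producing single encoded elements: an essential gene of a given
#' type, a transposable element with transposition rate \code{phi}, or a
#' non-coding position.
#'
#' @param type gene type as a letter (\code{"a"}..\code{"z"}) or integer.
#' @param phi transposition rate in \[0, 1\].
#' @return a numeric scalar in the element encoding.
#' @export
essentialElement <- function(type) {
  k <- if (is.character(type)) match(tolower(type), letters) else as.integer(type)
  stopifnot(!is.na(k), k >= 1L, k <= 26L)
  as.numeric(k)
}

#' @rdname essentialElement
#' @export
teElement <- function(phi) {
  stopifnot(is.numeric(phi), phi >= 0, phi <= 1)
  -1 - phi
}

#' @rdname essentialElement
#' @export
nonCodingElement <- function() 0

#' Kind and transposition rate of encoded elements
#'
#' @param x numeric vector of encoded elements or a [Genome-class].
#' @return \code{elementKind}: character vector in
#'   \code{"essential"}, \code{"transposon"}, \code{"noncoding"};
#'   \code{elementPhi}: the transposition rate of each element (\code{NA}
#'   for non-TEs).
#' @export
elementKind <- function(x) {
  v <- as.numeric(x)
  ifelse(v < -0.5, "transposon", ifelse(v > 0.5, "essential", "noncoding"))
}

#' @rdname elementKind
#' @export
elementPhi <- function(x) {
  v <- as.numeric(x)
  ifelse(v < -0.5, -v - 1, NA_real_)
}

#' Founding genomes
#'
#' \code{standardGenome} builds the founding genome of the evolutionary
#' scenarios: \code{nEssential} essential genes (cycling through the
#' \code{nFunctions} gene types) with \code{nNonCoding} non-coding positions
#' interleaved evenly between them.  \code{minimalGenome} is the maximally
#' streamlined genome: exactly one copy of each essential gene type.
#'
#' @param nEssential number of essential genes.
#' @param nNonCoding number of non-coding positions.
#' @param nFunctions number of distinct essential gene types.
#' @return a [Genome-class].
#' @examples
#' length(standardGenome(10, 30))  # 40
#' isViable(minimalGenome())       # TRUE
#' @export
standardGenome <- function(nEssential = 10, nNonCoding = 30, nFunctions = 10) {
  nEssential <- as.integer(nEssential)
  nNonCoding <- as.integer(nNonCoding)
  if (nEssential == 0L) return(Genome(rep(0, nNonCoding)))
  ess <- rep(seq_len(nFunctions), length.out = nEssential)
  share <- diff(round(seq(0, nNonCoding, length.out = nEssential + 1)))
  Genome(unlist(Map(function(e, k) c(e, rep(0, k)), ess, share)))
}

#' @rdname standardGenome
#' @export
minimalGenome <- function(nFunctions = 10) {
  Genome(seq_len(nFunctions))
}

#' Fitness parameters constructor
#'
#' @param c per-TE fitness penalty.
#' @param nFunctions number of essential gene types required for viability.
#' @return a [FitnessParams-class].
#' @export
fitnessParams <- function(c = 0.005, nFunctions = 10) {
  new("FitnessParams", c = as.numeric(c), nFunctions = as.integer(nFunctions))
}

#' Census of genome elements
#'
#' Counts elements per class and essential genes per type.
#'
#' @param genome a [Genome-class] (or encoded numeric vector).
#' @param nFunctions number of essential gene types to tabulate.
#' @return a list with components \code{essential}, \code{transposon},
#'   \code{noncoding}, \code{total} and \code{perType} (named integer vector
#'   over the gene-type letters).
#' @export
countElements <- function(genome, nFunctions = 10) {
  v <- as.numeric(genome)
  te <- sum(v < -0.5)
  ess <- sum(v > 0.5)
  types <- tabulate(round(v[v > 0.5]), nbins = nFunctions)
  names(types) <- letters[seq_len(nFunctions)]
  list(essential = ess, transposon = te,
       noncoding = length(v) - te - ess,
       total = length(v), perType = types)
}

#' Genome viability
#'
#' A genome is viable iff every essential gene type is present at least once
#' among its (active) essential genes.  Inactivated genes are non-coding
#' elements and never count.
#'
#' @param genome a [Genome-class].
#' @param params a [FitnessParams-class].
#' @return logical scalar.
#' @export
isViable <- function(genome, params = fitnessParams()) {
  v <- as.numeric(genome)
  present <- unique(round(v[v > 0.5]))
  all(seq_len(params@nFunctions) %in% present)
}

#' Genome fitness
#'
#' Fitness is 0 for a non-viable genome (any essential gene type missing),
#' and otherwise \eqn{\max(0,\, 1 - c\,T)} where \eqn{T} is the number of
#' TEs.  Non-coding DNA and redundant gene copies carry no cost; the clamp
#' at zero keeps fitness usable as a competition weight for extreme TE
#' loads.
#'
#' @inheritParams isViable
#' @return numeric fitness in \[0, 1\].
#' @examples
#' computeFitness(minimalGenome())                       # 1
#' computeFitness(Genome(c(1:10, teElement(0.9))))       # 0.995
#' @export
computeFitness <- function(genome, params = fitnessParams()) {
  cpp_fitness(as.numeric(genome), params@c, params@nFunctions)
}

## ---------------------------------------------------------------- text form

#' Genome text serialisation
#'
#' One genome per line, elements comma-separated: an essential gene by its
#' letter, a TE as \code{T:<phi>} with phi printed to 3 decimals, a
#' non-coding position as \code{"."}.
#'
#' @param genome a [Genome-class].
#' @param x character scalar in the serialised form.
#' @param genomes list of genomes; \code{file} a path or connection.
#' @param file path to read from / write to.
#' @return \code{genomeToString}: character scalar; \code{genomeFromString}:
#'   a [Genome-class]; \code{readGenomes}: list of genomes.
#' @examples
#' genomeToString(Genome(c(1, 0, teElement(0.9))))  # "a,.,T:0.900"
#' @export
genomeToString <- function(genome) {
  v <- as.numeric(genome)
  if (!length(v)) return("")
  out <- character(length(v))
  te <- v < -0.5
  ess <- v > 0.5
  out[te] <- sprintf("T:%.3f", -v[te] - 1)
  out[ess] <- letters[round(v[ess])]
  out[!te & !ess] <- "."
  paste(out, collapse = ",")
}

#' @rdname genomeToString
#' @export
genomeFromString <- function(x) {
  x <- trimws(x)
  if (!nzchar(x)) return(Genome())
  tok <- strsplit(x, ",", fixed = TRUE)[[1]]
  tok <- trimws(tok)
  v <- numeric(length(tok))
  isTE <- startsWith(tok, "T:")
  v[isTE] <- -1 - as.numeric(substring(tok[isTE], 3))
  isNC <- tok == "."
  isEss <- !isTE & !isNC
  if (any(isEss)) {
    k <- match(tolower(tok[isEss]), letters)
    if (anyNA(k)) stop("unrecognised genome element token")
    v[isEss] <- k
  }
  Genome(v)
}

#' @rdname genomeToString
#' @export
writeGenomes <- function(genomes, file) {
  writeLines(vapply(genomes, genomeToString, character(1)), con = file)
}

#' @rdname genomeToString
#' @export
readGenomes <- function(file) {
  lapply(readLines(file), genomeFromString)
}

#' @describeIn Genome-class compact display of a genome
#' @param object a \code{Genome}.
#' @export
setMethod("show", "Genome", function(object) {
  cen <- countElements(object, 26)
  cat(sprintf("Genome of %d elements (%d essential, %d TE, %d non-coding)\n",
              cen$total, cen$essential, cen$transposon, cen$noncoding))
  s <- genomeToString(object)
  if (nchar(s) > 70) s <- paste0(substr(s, 1, 67), "...")
  if (nzchar(s)) cat(" ", s, "\n")
  invisible(object)
})
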
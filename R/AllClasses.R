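#' @import methods
#' @importFrom stats runif rnorm rpois sd cor setNames
#' @importFrom utils read.table write.table head tail
#' @useDynLib ChromStack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Genome assembly descriptor
#'
#' Holds chromosome names and lengths together with the bin size at which all
#' per-bin data structures (binary track matrices, segmentations, score
#' tracks) are laid out. Bin \code{i} (1-based) of a chromosome covers the
#' 0-based half-open interval \code{[(i-1)*binSize, i*binSize)}, with the
#' final bin clipped to the chromosome length on BED export only.
#'
#' @slot name single character identifier for the assembly.
#' @slot chromSizes named numeric vector of chromosome lengths in bp.
#' @slot binSize bin width in bp (default 200 throughout the package).
#'
#' @examples
#' asm <- GenomeAssembly("toy1", c(chr1 = 1e6, chr2 = 5e5))
#' nBins(asm)
#' @export
setClass("GenomeAssembly",
  representation(name = "character", chromSizes = "numeric", binSize = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@name) != 1L) msg <- c(msg, "'name' must be a single string")
    if (is.null(names(object@chromSizes)) || anyDuplicated(names(object@chromSizes)))
      msg <- c(msg, "'chromSizes' must have unique names")
    if (any(object@chromSizes <= 0)) msg <- c(msg, "all chromosome lengths must be > 0")
    if (length(object@binSize) != 1L || object@binSize <= 0)
      msg <- c(msg, "'binSize' must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname GenomeAssembly-class
#' @param name assembly identifier.
#' @param chromSizes named numeric vector of chromosome lengths (bp).
#' @param binSize bin width in bp.
#' @export
GenomeAssembly <- function(name, chromSizes, binSize = 200) {
  new("GenomeAssembly", name = name,
      chromSizes = setNames(as.numeric(chromSizes), names(chromSizes)),
      binSize = as.numeric(binSize))
}

#' Per-bin binary presence calls for many datasets
#'
#' The observation object of the stacked model: for each chromosome, a
#' bins-by-datasets integer matrix with values 1 (signal present), 0 (absent)
#' or \code{NA} (missing; serialized as \code{2} in the binarized text
#' dialect). Column order is identical across chromosomes and given by
#' \code{datasetNames}.
#'
#' @slot assembly a \linkS4class{GenomeAssembly}.
#' @slot datasetNames ordered character vector of dataset identifiers,
#'   conventionally \code{"celltype_mark_accession"}.
#' @slot tracks named list (one per chromosome) of integer matrices.
#' @export
setClass("BinaryTrackMatrix",
  representation(assembly = "GenomeAssembly", datasetNames = "character",
                 tracks = "list"),
  validity = function(object) {
    msg <- NULL
    asm <- object@assembly
    if (anyDuplicated(object@datasetNames))
      msg <- c(msg, "dataset names must be unique")
    if (!identical(sort(names(object@tracks)), sort(names(asm@chromSizes))))
      msg <- c(msg, "track chromosomes must match the assembly")
    for (chrom in names(object@tracks)) {
      m <- object@tracks[[chrom]]
      if (!is.matrix(m) || ncol(m) != length(object@datasetNames))
        msg <- c(msg, sprintf("chromosome '%s': matrix with %d columns expected",
                              chrom, length(object@datasetNames)))
      else {
        if (nrow(m) != nBins(asm)[chrom])
          msg <- c(msg, sprintf("chromosome '%s': %d bins expected, %d found",
                                chrom, nBins(asm)[chrom], nrow(m)))
        v <- m[!is.na(m)]
        if (length(v) && !all(v %in% c(0L, 1L)))
          msg <- c(msg, sprintf("chromosome '%s': values outside {0,1,NA}", chrom))
      }
    }
    if (is.null(msg)) TRUE else msg
  })

#' @rdname BinaryTrackMatrix-class
#' @param assembly a \linkS4class{GenomeAssembly}.
#' @param datasetNames character vector of dataset identifiers.
#' @param tracks named list of bins x datasets integer matrices.
#' @export
BinaryTrackMatrix <- function(assembly, datasetNames, tracks) {
  tracks <- lapply(tracks, function(m) {
    storage.mode(m) <- "integer"
    dimnames(m) <- NULL
    m
  })
  new("BinaryTrackMatrix", assembly = assembly,
      datasetNames = as.character(datasetNames), tracks = tracks)
}

#' K-state hidden Markov model with independent Bernoulli emissions
#'
#' The stacked chromatin-state model: a hidden Markov chain over genomic bins
#' whose emission distribution in state \code{k} is a product of independent
#' Bernoulli variables, one per dataset, with present-probability
#' \code{emissions[k, e]}.
#'
#' @slot initial length-K initial state distribution.
#' @slot transitions K x K row-stochastic transition matrix.
#' @slot emissions K x E matrix of Bernoulli present-probabilities.
#' @slot datasetNames ordered dataset identifiers (length E).
#' @export
setClass("StackedHMM",
  representation(initial = "numeric", transitions = "matrix",
                 emissions = "matrix", datasetNames = "character"),
  validity = function(object) {
    msg <- NULL
    K <- length(object@initial)
    if (abs(sum(object@initial) - 1) > 1e-9)
      msg <- c(msg, "initial distribution must sum to 1")
    if (!identical(dim(object@transitions), c(K, K)))
      msg <- c(msg, "transition matrix must be K x K")
    else if (any(abs(rowSums(object@transitions) - 1) > 1e-9))
      msg <- c(msg, "each transition row must sum to 1")
    if (nrow(object@emissions) != K)
      msg <- c(msg, "emissions must have one row per state")
    if (ncol(object@emissions) != length(object@datasetNames))
      msg <- c(msg, "emissions must have one column per dataset")
    if (any(object@emissions <= 0 | object@emissions >= 1))
      msg <- c(msg, "emission probabilities must lie strictly inside (0, 1)")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname StackedHMM-class
#' @param initial initial state distribution.
#' @param transitions row-stochastic transition matrix.
#' @param emissions K x E Bernoulli parameter matrix.
#' @param datasetNames dataset identifiers (defaults to \code{d1..dE}).
#' @export
StackedHMM <- function(initial, transitions, emissions,
                       datasetNames = paste0("d", seq_len(ncol(emissions)))) {
  emissions <- as.matrix(emissions)
  dimnames(emissions) <- NULL
  transitions <- as.matrix(transitions)
  dimnames(transitions) <- NULL
  new("StackedHMM", initial = as.numeric(initial), transitions = transitions,
      emissions = emissions, datasetNames = as.character(datasetNames))
}

#' Genome-wide state assignment
#'
#' One state label per bin per chromosome. A complete segmentation assigns a
#' state in \code{1..nStates} to every bin; a partial segmentation (e.g. a
#' foreign annotation carried over through a segment mapping) leaves
#' uncovered bins as \code{NA}.
#'
#' @slot assembly a \linkS4class{GenomeAssembly}.
#' @slot nStates number of states K.
#' @slot states named list (per chromosome) of integer vectors in
#'   \code{1..nStates} or \code{NA}.
#' @export
setClass("Segmentation",
  representation(assembly = "GenomeAssembly", nStates = "integer",
                 states = "list"),
  validity = function(object) {
    msg <- NULL
    asm <- object@assembly
    if (!identical(sort(names(object@states)), sort(names(asm@chromSizes))))
      msg <- c(msg, "state chromosomes must match the assembly")
    for (chrom in names(object@states)) {
      s <- object@states[[chrom]]
      if (length(s) != nBins(asm)[chrom])
        msg <- c(msg, sprintf("chromosome '%s': one state per bin required", chrom))
      v <- s[!is.na(s)]
      if (length(v) && (any(v < 1L) || any(v > object@nStates)))
        msg <- c(msg, sprintf("chromosome '%s': states outside 1..%d",
                              chrom, object@nStates))
    }
    if (is.null(msg)) TRUE else msg
  })

#' @rdname Segmentation-class
#' @param assembly a \linkS4class{GenomeAssembly}.
#' @param nStates number of states.
#' @param states named list of per-chromosome integer state vectors.
#' @export
Segmentation <- function(assembly, nStates, states) {
  states <- lapply(states, as.integer)
  new("Segmentation", assembly = assembly, nStates = as.integer(nStates),
      states = states)
}
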
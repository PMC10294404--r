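#' @name accessors
#' @title Accessors for ChromStack classes
#' @description Small accessor generics for the package's S4 classes; user
#'   code should use these rather than reaching into slots.
#' @param x an object.
#' @return The corresponding component.
NULL

#' @rdname accessors
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))
#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setGeneric("assembly", function(x) standardGeneric("assembly"))
#' @rdname accessors
#' @export
setGeneric("datasetNames", function(x) standardGeneric("datasetNames"))
#' @rdname accessors
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))
#' @rdname accessors
#' @export
setGeneric("stateSeqs", function(x) standardGeneric("stateSeqs"))
#' @rdname accessors
#' @export
setGeneric("binTracks", function(x) standardGeneric("binTracks"))
#' @rdname accessors
#' @export
setGeneric("initialProbs", function(x) standardGeneric("initialProbs"))
#' @rdname accessors
#' @export
setGeneric("transitionProbs", function(x) standardGeneric("transitionProbs"))
#' @rdname accessors
#' @export
setGeneric("emissionProbs", function(x) standardGeneric("emissionProbs"))

#' @rdname accessors
#' @export
setMethod("chromSizes", "GenomeAssembly", function(x) x@chromSizes)
#' @rdname accessors
#' @export
setMethod("binSize", "GenomeAssembly", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("nBins", "GenomeAssembly",
          function(x) setNames(as.integer(ceiling(x@chromSizes / x@binSize)),
                               names(x@chromSizes)))
#' @rdname accessors
#' @export
setMethod("assembly", "BinaryTrackMatrix", function(x) x@assembly)
#' @rdname accessors
#' @export
setMethod("assembly", "Segmentation", function(x) x@assembly)
#' @rdname accessors
#' @export
setMethod("datasetNames", "BinaryTrackMatrix", function(x) x@datasetNames)
#' @rdname accessors
#' @export
setMethod("datasetNames", "StackedHMM", function(x) x@datasetNames)
#' @rdname accessors
#' @export
setMethod("nStates", "StackedHMM", function(x) length(x@initial))
#' @rdname accessors
#' @export
setMethod("nStates", "Segmentation", function(x) x@nStates)
#' @rdname accessors
#' @export
setMethod("stateSeqs", "Segmentation", function(x) x@states)
#' @rdname accessors
#' @export
setMethod("binTracks", "BinaryTrackMatrix", function(x) x@tracks)
#' @rdname accessors
#' @export
setMethod("initialProbs", "StackedHMM", function(x) x@initial)
#' @rdname accessors
#' @export
setMethod("transitionProbs", "StackedHMM", function(x) x@transitions)
#' @rdname accessors
#' @export
setMethod("emissionProbs", "StackedHMM", function(x) x@emissions)

setMethod("show", "GenomeAssembly", function(object) {
  cat(sprintf("GenomeAssembly '%s': %d chromosome(s), %s bp, bin size %d bp\n",
              object@name, length(object@chromSizes),
              format(sum(object@chromSizes), big.mark = ","),
              as.integer(object@binSize)))
})

setMethod("show", "BinaryTrackMatrix", function(object) {
  nb <- sum(nBins(object@assembly))
  nmiss <- sum(vapply(object@tracks, function(m) sum(is.na(m)), numeric(1)))
  cat(sprintf("BinaryTrackMatrix: %d dataset(s) x %s bins on '%s' (%.2f%% missing)\n",
              length(object@datasetNames), format(nb, big.mark = ","),
              object@assembly@name,
              100 * nmiss / (nb * length(object@datasetNames))))
})

setMethod("show", "StackedHMM", function(object) {
  cat(sprintf("StackedHMM: %d states x %d datasets\n",
              nStates(object), length(object@datasetNames)))
  cat(sprintf("  mean self-transition %.3f; emission range [%.3f, %.3f]\n",
              mean(diag(object@transitions)), min(object@emissions),
              max(object@emissions)))
})

setMethod("show", "Segmentation", function(object) {
  n <- sum(nBins(object@assembly))
  na <- sum(vapply(object@states, function(s) sum(is.na(s)), numeric(1)))
  cat(sprintf("Segmentation: %d states over %s bins on '%s'%s\n",
              object@nStates, format(n, big.mark = ","), object@assembly@name,
              if (na > 0) sprintf(" (%s bins unassigned)",
                                  format(na, big.mark = ",")) else ""))
})
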
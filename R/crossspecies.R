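# Cross-genome state correspondence: map a foreign segmentation into the
# focal genome's coordinates through a per-bin segment mapping, compute the
# cross-state fold-enrichment matrix, extract reciprocal one-to-one state
# pairs, and summarize conservation evidence per state.

#' Map a foreign segmentation onto the focal assembly
#'
#' Per-bin independent mapping of the foreign annotation; focal positions
#' claimed by two or more distinct foreign segments are excluded from the
#' analysis. Thin wrapper over \code{\link{applySegmentMapping}} with the
#' foreign genome as source.
#'
#' @param foreignSeg the foreign \linkS4class{Segmentation}.
#' @param mapping mapping table from foreign to focal coordinates.
#' @param assemblyFocal the focal \linkS4class{GenomeAssembly}.
#' @return A partial \linkS4class{Segmentation} on the focal assembly.
#' @export
mapForeignAnnotation <- function(foreignSeg, mapping, assemblyFocal) {
  applySegmentMapping(foreignSeg, mapping, assemblyFocal)
}

#' Cross-state fold-enrichment matrix
#'
#' Fold enrichment of every focal state with the mapped territory of every
#' foreign state, computed base-level with the full focal genome as
#' background (the same convention as annotation enrichment applied to a
#' lifted segmentation).
#'
#' @param focalSeg focal \linkS4class{Segmentation}.
#' @param mappedForeign foreign segmentation mapped onto the focal assembly
#'   (see \code{\link{mapForeignAnnotation}}).
#' @return Object of class \code{"CrossEnrichmentMatrix"}: list with
#'   \code{fold} (focal states x foreign states), plus the marginals
#'   \code{focalFraction} and \code{foreignFraction}.
#' @export
crossEnrichment <- function(focalSeg, mappedForeign) {
  .checkAssemblyMatch(assembly(focalSeg), assembly(mappedForeign))
  gr <- .segmentationRanges(mappedForeign)
  KF <- nStates(mappedForeign)
  annotations <- lapply(seq_len(KF), function(h) gr[gr$state == h])
  names(annotations) <- paste0("F", seq_len(KF))
  et <- foldEnrichment(focalSeg, annotations)
  structure(list(fold = et$fold, percent = et$percent,
                 focalFraction = et$stateFraction,
                 foreignFraction = et$annotFraction),
            class = "CrossEnrichmentMatrix")
}

#' @export
print.CrossEnrichmentMatrix <- function(x, ...) {
  cat(sprintf("CrossEnrichmentMatrix: %d focal x %d foreign states\n",
              nrow(x$fold), ncol(x$fold)))
  invisible(x)
}

#' Reciprocal one-to-one state pairs
#'
#' A pair (focal m, foreign h) is reported iff h is the unique maximizer of
#' \code{fold[m, ]} and m is the unique maximizer of \code{fold[, h]}. Tied
#' maxima produce no pair and are reported via a message.
#'
#' @param x a \code{CrossEnrichmentMatrix} or a bare fold matrix.
#' @return \code{data.frame} with columns \code{focal}, \code{foreign},
#'   \code{fold}.
#' @export
oneToOnePairs <- function(x) {
  fold <- if (inherits(x, "CrossEnrichmentMatrix")) x$fold else x
  uniqueArgmax <- function(v) {
    if (all(is.na(v))) return(NA_integer_)
    m <- max(v, na.rm = TRUE)
    w <- which(v == m)
    if (length(w) != 1L) NA_integer_ else w
  }
  rowBest <- apply(fold, 1L, uniqueArgmax)
  colBest <- apply(fold, 2L, uniqueArgmax)
  nTies <- sum(is.na(rowBest) & apply(fold, 1L, function(v) !all(is.na(v)))) +
    sum(is.na(colBest) & apply(fold, 2L, function(v) !all(is.na(v))))
  if (nTies > 0) message(nTies, " state(s) with tied maxima: no pair reported")
  pairs <- list()
  for (m in seq_len(nrow(fold))) {
    h <- rowBest[m]
    if (!is.na(h) && !is.na(colBest[h]) && colBest[h] == m)
      pairs[[length(pairs) + 1L]] <- data.frame(focal = m, foreign = h,
                                                fold = fold[m, h])
  }
  if (!length(pairs))
    return(data.frame(focal = integer(0), foreign = integer(0),
                      fold = numeric(0)))
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}

#' Per-state conservation summary with rank columns
#'
#' Combines three conservation axes per focal state: the base-weighted
#' average of a conservation score track, the maximum cross-species fold
#' enrichment, and the fold enrichment for sequence-constraint elements.
#' Each axis gets a descending rank (average-rank ties); \code{inTopK}
#' marks states in the top \code{k} of all three axes.
#'
#' @param focalSeg focal \linkS4class{Segmentation}.
#' @param scores per-bin score track (list per chromosome).
#' @param crossMatrix a \code{CrossEnrichmentMatrix}.
#' @param constraintAnnot \code{GRanges} of constraint elements.
#' @param k top-k cutoff (default 20).
#' @return \code{data.frame}, one row per state.
#' @export
conservationReport <- function(focalSeg, scores, crossMatrix, constraintAnnot,
                               k = 20) {
  avgScore <- scoreAverage(focalSeg, scores)
  maxCross <- apply(crossMatrix$fold, 1L, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  constraintFold <- foldEnrichment(focalSeg, constraintAnnot)$fold[, 1L]
  rk <- function(v) rank(-v, ties.method = "average", na.last = "keep")
  df <- data.frame(state = paste0("E", seq_len(nStates(focalSeg))),
                   avgScore = avgScore, maxCrossFold = maxCross,
                   constraintFold = constraintFold,
                   rankScore = rk(avgScore), rankCross = rk(maxCross),
                   rankConstraint = rk(constraintFold))
  df$inTopK <- with(df, rankScore <= k & rankCross <= k & rankConstraint <= k)
  rownames(df) <- NULL
  df
}
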
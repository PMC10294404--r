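# Interval-overlap statistics used to characterize states: fold enrichment
# against annotation sets, positional profiles around stranded anchors,
# per-chromosome enrichment, geometric-mean summaries across datasets,
# Jaccard/percent overlap, per-cell-type chromatin-state summaries, and
# per-state score averages. All overlap counting is base-level: segmentation
# intervals are expanded to bases exactly as the BED representation would be.

.binWidths <- function(assembly, chrom) {
  n <- nBins(assembly)[[chrom]]
  w <- rep(binSize(assembly), n)
  w[n] <- chromSizes(assembly)[[chrom]] - (n - 1) * binSize(assembly)
  w
}

# Clip a GRanges to assembly bounds and merge overlaps.
#' @importFrom GenomicRanges reduce seqnames start end
#' @importFrom IRanges IRanges
.mergedClipped <- function(gr, assembly) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  keep <- chrom %in% names(chromSizes(assembly))
  gr <- gr[keep]
  chrom <- chrom[keep]
  if (length(gr)) {
    lim <- chromSizes(assembly)[chrom]
    gr <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = pmax(GenomicRanges::start(gr), 1),
                       end = pmin(GenomicRanges::end(gr), lim)))
    gr <- gr[GenomicRanges::start(gr) <= GenomicRanges::end(gr)]
  }
  GenomicRanges::reduce(gr)
}

#' Fold enrichment of every state with a set of annotations
#'
#' Base-level overlap statistics between a segmentation and one or more
#' interval annotations. With \code{T} the genome size,
#' \deqn{fold(s, a) = \frac{|s \cap a| / T}{(|s|/T)(|a|/T)}}
#' and \code{percent(s, a) = |s cap a| / |a|}. Overlapping annotation
#' intervals are merged (and clipped to assembly bounds) before counting.
#' Empty annotations give \code{NA} folds.
#'
#' @param seg a \linkS4class{Segmentation}.
#' @param annotations a \code{GRanges} or named list of \code{GRanges}.
#' @return An object of class \code{"EnrichmentTable"}: list with matrices
#'   \code{fold}, \code{percent}, \code{intersectionBases} (states x
#'   annotations) and vectors \code{stateFraction}, \code{annotFraction}.
#' @importFrom GenomicRanges intersect width
#' @export
foldEnrichment <- function(seg, annotations) {
  if (!is.list(annotations)) annotations <- list(annotation = annotations)
  if (is.null(names(annotations)))
    names(annotations) <- paste0("annotation", seq_along(annotations))
  asm <- assembly(seg)
  total <- sum(chromSizes(asm))
  segGr <- .segmentationRanges(seg)
  K <- nStates(seg)
  stateBases <- vapply(seq_len(K), function(s)
    sum(GenomicRanges::width(segGr[segGr$state == s])), numeric(1))
  nA <- length(annotations)
  fold <- percent <- inter <- matrix(NA_real_, K, nA,
                                     dimnames = list(paste0("E", seq_len(K)),
                                                     names(annotations)))
  annotFraction <- setNames(numeric(nA), names(annotations))
  for (a in seq_len(nA)) {
    merged <- .mergedClipped(annotations[[a]], asm)
    ab <- sum(GenomicRanges::width(merged))
    annotFraction[a] <- ab / total
    if (ab == 0) next
    for (s in seq_len(K)) {
      ib <- sum(GenomicRanges::width(suppressWarnings(
        GenomicRanges::intersect(segGr[segGr$state == s], merged,
                                 ignore.strand = TRUE))))
      inter[s, a] <- ib
      percent[s, a] <- ib / ab
      fold[s, a] <- if (stateBases[s] > 0)
        (ib / total) / ((stateBases[s] / total) * (ab / total)) else NA_real_
    }
  }
  structure(list(fold = fold, percent = percent, intersectionBases = inter,
                 stateFraction = setNames(stateBases / total,
                                          paste0("E", seq_len(K))),
                 annotFraction = annotFraction),
            class = "EnrichmentTable")
}

#' @export
print.EnrichmentTable <- function(x, ...) {
  cat(sprintf("EnrichmentTable: %d states x %d annotation(s)\n",
              nrow(x$fold), ncol(x$fold)))
  print(round(x$fold, 3))
  invisible(x)
}

#' Write an enrichment table as TSV
#'
#' One row per state, one fold column per annotation, plus the per-state
#' genome fraction; a final row carries each annotation's genome coverage.
#'
#' @param x an \code{EnrichmentTable}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeEnrichmentTable <- function(x, path) {
  df <- data.frame(state = rownames(x$fold),
                   genomeFraction = x$stateFraction, x$fold,
                   check.names = FALSE)
  covRow <- data.frame(state = "annotationCoverage", genomeFraction = NA,
                       t(x$annotFraction), check.names = FALSE)
  con <- .writeConn(path)
  on.exit(close(con))
  write.table(rbind(df, covRow), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Column-wise min-max scaling for heatmap display
#'
#' Reporting-layer helper: rescales each column of a fold matrix to [0, 1]
#' so the largest value per annotation is 1. Stored statistics are never
#' normalized.
#'
#' @param mat numeric matrix.
#' @return Rescaled matrix.
#' @export
normalizeColumns <- function(mat) {
  apply(mat, 2L, function(x) {
    r <- range(x, na.rm = TRUE)
    if (diff(r) == 0) return(rep(0, length(x)))
    (x - r[1]) / diff(r)
  })
}

#' Jaccard index from base-pair sizes or interval sets
#'
#' \code{jaccardIndex} takes the three sizes directly;
#' \code{jaccardSets} first computes them from two interval sets
#' (merged, base-level).
#'
#' @param sizeA,sizeB set sizes in bp.
#' @param sizeIntersection intersection size in bp (must not exceed either
#'   set).
#' @return Named list: \code{union} (bp) and \code{jaccard}.
#' @examples
#' jaccardIndex(413502000, 238977200, 193765600)
#' @export
jaccardIndex <- function(sizeA, sizeB, sizeIntersection) {
  if (sizeIntersection > min(sizeA, sizeB))
    stop("intersection cannot exceed either set")
  u <- sizeA + sizeB - sizeIntersection
  list(union = u, jaccard = if (u == 0) NA_real_ else sizeIntersection / u)
}

#' @rdname jaccardIndex
#' @param A,B \code{GRanges} interval sets.
#' @importFrom GenomicRanges reduce intersect width
#' @export
jaccardSets <- function(A, B) {
  A <- GenomicRanges::reduce(A, ignore.strand = TRUE)
  B <- GenomicRanges::reduce(B, ignore.strand = TRUE)
  i <- sum(GenomicRanges::width(suppressWarnings(
    GenomicRanges::intersect(A, B, ignore.strand = TRUE))))
  res <- jaccardIndex(sum(GenomicRanges::width(A)),
                      sum(GenomicRanges::width(B)), i)
  c(list(sizeA = sum(GenomicRanges::width(A)),
         sizeB = sum(GenomicRanges::width(B)), intersection = i), res)
}

#' Positional enrichment of states around stranded anchors
#'
#' For every bin offset \code{o} in \code{-windowBins..windowBins}, the
#' frequency of each state at (anchor + o), divided by the state's
#' genome-wide frequency. Anchors are snapped to the bin containing their
#' start coordinate; on minus-strand anchors offsets are flipped so positive
#' offsets always point downstream in the direction of transcription.
#' Anchors closer to a chromosome edge than the window contribute only their
#' valid offsets.
#'
#' @param seg a \linkS4class{Segmentation}.
#' @param anchors \code{GRanges} of anchor points (strand used when set).
#' @param windowBins window half-width in bins.
#' @return Object of class \code{"PositionalProfile"}: list with
#'   \code{offsets} (bp), \code{fold} (states x offsets matrix) and
#'   \code{anchorName}.
#' @importFrom GenomicRanges seqnames start strand
#' @export
positionalEnrichment <- function(seg, anchors, windowBins = 10) {
  if (length(anchors) == 0L) stop("empty anchor set")
  asm <- assembly(seg)
  bs <- binSize(asm)
  offsets <- seq(-windowBins, windowBins)
  K <- nStates(seg)
  counts <- matrix(0, K, length(offsets))
  valid <- numeric(length(offsets))
  chrom <- as.character(GenomicRanges::seqnames(anchors))
  bad <- setdiff(unique(chrom), names(chromSizes(asm)))
  if (length(bad)) stop("anchor(s) on unknown chromosome(s): ",
                        paste(bad, collapse = ", "))
  anchorBin <- floor((GenomicRanges::start(anchors) - 1) / bs) + 1L
  str <- as.character(GenomicRanges::strand(anchors))
  flip <- ifelse(str == "-", -1L, 1L)
  for (i in seq_along(anchors)) {
    states <- stateSeqs(seg)[[chrom[i]]]
    bins <- anchorBin[i] + flip[i] * offsets
    ok <- bins >= 1L & bins <= length(states)
    s <- states[bins[ok]]
    keep <- !is.na(s)
    oidx <- which(ok)[keep]
    counts[cbind(s[keep], oidx)] <- counts[cbind(s[keep], oidx)] + 1
    valid[oidx] <- valid[oidx] + 1
  }
  allStates <- unlist(stateSeqs(seg), use.names = FALSE)
  genomeFreq <- tabulate(allStates[!is.na(allStates)], nbins = K) /
    sum(!is.na(allStates))
  freq <- sweep(counts, 2L, pmax(valid, 1), "/")
  fold <- sweep(freq, 1L, genomeFreq, "/")
  fold[genomeFreq == 0, ] <- NA_real_
  dimnames(fold) <- list(paste0("E", seq_len(K)), offsets * bs)
  structure(list(offsets = offsets * bs, fold = fold,
                 anchorName = S4Vectors::metadata(anchors)$name),
            class = "PositionalProfile")
}

#' @export
print.PositionalProfile <- function(x, ...) {
  cat(sprintf("PositionalProfile around '%s': %d states x %d offsets\n",
              if (is.null(x$anchorName)) "anchors" else x$anchorName,
              nrow(x$fold), length(x$offsets)))
  invisible(x)
}

#' @rdname positionalEnrichment
#' @param x a \code{PositionalProfile}.
#' @param path output TSV.
#' @export
writePositionalProfile <- function(x, path) {
  df <- data.frame(state = rownames(x$fold), x$fold, check.names = FALSE)
  con <- .writeConn(path)
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Geometric mean and SD of fold values across datasets
#'
#' Summary used when one state's enrichment is measured against many
#' datasets of the same kind (e.g. factor peaks across cell types): zero
#' folds are replaced by the state's minimum non-zero fold, then the
#' geometric mean \code{exp(mean(log x))} and geometric SD
#' \code{exp(sd(log x))} are reported. With no non-zero value the summary is
#' undefined (\code{NA}).
#'
#' @param folds numeric vector of fold values (>= 0) for one state.
#' @return Named list \code{geoMean}, \code{geoSD}.
#' @export
groupedGeometricSummary <- function(folds) {
  if (any(folds < 0)) stop("folds must be non-negative")
  nz <- folds[folds > 0]
  if (!length(nz)) return(list(geoMean = NA_real_, geoSD = NA_real_))
  folds[folds == 0] <- min(nz)
  lx <- log(folds)
  list(geoMean = exp(mean(lx)),
       geoSD = if (length(lx) > 1) exp(sd(lx)) else NA_real_)
}

#' Per-chromosome enrichment of every state
#'
#' Delegates to \code{\link{foldEnrichment}} with each chromosome's full
#' extent as an annotation.
#'
#' @param seg a \linkS4class{Segmentation}.
#' @return An \code{EnrichmentTable} with one column per chromosome.
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @export
chromosomeEnrichment <- function(seg) {
  asm <- assembly(seg)
  annotations <- lapply(names(chromSizes(asm)), function(chrom)
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(1, chromSizes(asm)[[chrom]])))
  names(annotations) <- names(chromSizes(asm))
  foldEnrichment(seg, annotations)
}

#' Summarize states against per-cell-type chromatin-state annotations
#'
#' Two summaries of how a joint (full-stack) segmentation relates to a
#' collection of per-cell-type segmentations on the same assembly. First,
#' for every reference epigenome, the per-cell-type state maximally enriched
#' in each full-stack state (ties to the lowest per-cell-type state index).
#' Second, for every tissue group, the estimated probability that a
#' full-stack state overlaps each per-cell-type state: per epigenome the
#' fraction of the full-stack state's bases assigned to each per-cell-type
#' state, then averaged over the group's epigenomes, so every (state, group)
#' row sums to 1.
#'
#' @param fullstack the joint \linkS4class{Segmentation}.
#' @param percelltype named list of per-epigenome \linkS4class{Segmentation}
#'   objects on the same assembly.
#' @param groups named character vector mapping epigenome id to tissue
#'   group.
#' @return List with \code{maxEnriched} (full-stack states x epigenomes
#'   integer matrix) and \code{groupProbs} (per group, a states x
#'   per-cell-type-states probability matrix).
#' @export
perCellTypeSummary <- function(fullstack, percelltype, groups) {
  asm <- assembly(fullstack)
  K <- nStates(fullstack)
  if (is.null(names(percelltype))) stop("'percelltype' must be a named list")
  for (id in names(percelltype)) {
    seg <- percelltype[[id]]
    miss <- setdiff(names(stateSeqs(fullstack)), names(stateSeqs(seg)))
    if (length(miss))
      stop("epigenome '", id, "' is missing chromosome(s): ",
           paste(miss, collapse = ", "))
    .checkAssemblyMatch(asm, assembly(seg))
  }
  C <- max(vapply(percelltype, nStates, integer(1)))
  total <- sum(chromSizes(asm))

  crossBases <- function(seg) {
    m <- matrix(0, K, C)
    for (chrom in names(stateSeqs(fullstack))) {
      fs <- stateSeqs(fullstack)[[chrom]]
      cs <- stateSeqs(seg)[[chrom]]
      w <- .binWidths(asm, chrom)
      ok <- !is.na(fs) & !is.na(cs)
      if (!any(ok)) next
      t2 <- tapply(w[ok], list(factor(fs[ok], levels = seq_len(K)),
                               factor(cs[ok], levels = seq_len(C))), sum)
      t2[is.na(t2)] <- 0
      m <- m + t2
    }
    m
  }

  maxEnriched <- matrix(NA_integer_, K, length(percelltype),
                        dimnames = list(paste0("E", seq_len(K)),
                                        names(percelltype)))
  fracs <- list()
  for (id in names(percelltype)) {
    cb <- crossBases(percelltype[[id]])
    sBases <- rowSums(cb)
    cBases <- colSums(cb)
    fold <- (cb / total) / (outer(sBases, cBases) / total^2)
    fold[!is.finite(fold)] <- NA_real_
    maxEnriched[, id] <- apply(fold, 1L, function(x)
      if (all(is.na(x))) NA_integer_ else which.max(x))
    frac <- cb / ifelse(sBases > 0, sBases, NA_real_)
    fracs[[id]] <- frac
  }
  groupProbs <- lapply(split(names(percelltype), groups[names(percelltype)]),
                       function(ids) {
    m <- Reduce(`+`, fracs[ids]) / length(ids)
    dimnames(m) <- list(paste0("E", seq_len(K)), paste0("C", seq_len(C)))
    m
  })
  list(maxEnriched = maxEnriched, groupProbs = groupProbs)
}

#' Base-weighted average score per state
#'
#' Mean of a per-bin score over each state's territory, weighted by the
#' actual base width of each bin (the terminal bin of a chromosome may be
#' partial). Bins without a score are excluded from both numerator and
#' denominator; states with no scored bases get \code{NA}.
#'
#' @param seg a \linkS4class{Segmentation}.
#' @param scores named list of per-chromosome per-bin score vectors (as from
#'   \code{\link{readScoreTrack}}).
#' @return Numeric vector, one average per state.
#' @export
scoreAverage <- function(seg, scores) {
  asm <- assembly(seg)
  K <- nStates(seg)
  num <- den <- numeric(K)
  for (chrom in names(stateSeqs(seg))) {
    s <- stateSeqs(seg)[[chrom]]
    v <- scores[[chrom]]
    if (is.null(v)) next
    w <- .binWidths(asm, chrom)
    ok <- !is.na(s) & !is.na(v)
    if (!any(ok)) next
    num <- num + as.numeric(tapply(v[ok] * w[ok],
                                   factor(s[ok], levels = seq_len(K)), sum,
                                   default = 0))
    den <- den + as.numeric(tapply(w[ok], factor(s[ok], levels = seq_len(K)),
                                   sum, default = 0))
  }
  setNames(ifelse(den > 0, num / den, NA_real_), paste0("E", seq_len(K)))
}

#' Spearman rank correlation with average-rank ties
#'
#' Pearson correlation of mid-ranks, the convention used when comparing two
#' per-state summary vectors (e.g. a conservation-score average against a
#' constraint-element enrichment).
#'
#' @param x,y numeric vectors of equal length.
#' @return Correlation in [-1, 1].
#' @export
spearmanRank <- function(x, y) {
  stopifnot(length(x) == length(y))
  .safeCor(rank(x), rank(y))
}
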
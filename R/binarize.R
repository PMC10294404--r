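# Present/absent calling of per-bin read counts against a Poisson background,
# following the BinarizeBam logic: signal is called present when the bin count
# clears the upper tail of a Poisson whose mean is either the matched-control
# expectation (scaled, floored at the genome-wide uniform expectation) or,
# without a control, the uniform expectation itself.

#' Minimal count threshold for a Poisson upper-tail test
#'
#' Smallest integer \code{c} with \eqn{P(X \ge c) \le p} for
#' \eqn{X \sim Poisson(\lambda)}. The tail probability is accumulated by
#' direct summation of the probability mass function (terms computed by the
#' multiplicative recurrence), not via a closed-form tail approximation.
#'
#' @param lambda Poisson mean (> 0).
#' @param pCutoff tail probability cutoff in (0, 1].
#' @return Integer threshold.
#' @examples
#' poissonThreshold(1, 1e-4)
#' @export
poissonThreshold <- function(lambda, pCutoff) {
  if (lambda <= 0) stop("'lambda' must be positive")
  if (pCutoff <= 0 || pCutoff > 1) stop("'pCutoff' must lie in (0, 1]")
  if (pCutoff == 1) return(0L)
  # accumulate P(X <= c-1) until the remaining tail drops to pCutoff
  term <- exp(-lambda)  # P(X = 0)
  cdf <- term
  k <- 0L
  while (1 - cdf > pCutoff) {
    k <- k + 1L
    term <- term * lambda / k
    cdf <- cdf + term
    if (term == 0) break  # numerically exhausted tail
  }
  k + 1L
}

#' Per-bin read counts for many datasets
#'
#' A thin container mirroring \linkS4class{BinaryTrackMatrix} but holding
#' non-negative integer counts, with an optional bin- and column-aligned
#' control.
#'
#' @param assembly a \linkS4class{GenomeAssembly}.
#' @param datasetNames dataset identifiers.
#' @param counts named list of per-chromosome bins x datasets count matrices.
#' @param control optional parallel list of control count matrices.
#' @return A list of class \code{"CountMatrix"}.
#' @export
CountMatrix <- function(assembly, datasetNames, counts, control = NULL) {
  nb <- nBins(assembly)
  check <- function(lst, what) {
    if (!identical(sort(names(lst)), sort(names(nb))))
      stop(what, " chromosomes must match the assembly")
    for (chrom in names(lst)) {
      m <- lst[[chrom]]
      if (nrow(m) != nb[[chrom]] || ncol(m) != length(datasetNames))
        stop(what, " matrix dimensions wrong on ", chrom)
      if (any(m < 0)) stop(what, " counts must be non-negative")
    }
  }
  check(counts, "count")
  if (!is.null(control)) check(control, "control")
  structure(list(assembly = assembly, datasetNames = as.character(datasetNames),
                 counts = counts, control = control),
            class = "CountMatrix")
}

#' Binarize count matrices with a Poisson tail test
#'
#' For each dataset with a matched control, the per-bin Poisson mean is the
#' control count scaled by the signal/control total-read ratio, floored at
#' the genome-wide uniform expectation; without a control the mean is the
#' uniform expectation (total reads / bins) everywhere. A bin is called
#' present when its count reaches \code{\link{poissonThreshold}} at
#' \code{pCutoff}. Datasets with zero total reads yield an all-absent column
#' with a warning.
#'
#' @param x a \code{\link{CountMatrix}}.
#' @param pCutoff Poisson tail probability, default \code{1e-4}.
#' @return A \linkS4class{BinaryTrackMatrix}.
#' @export
binarizeCounts <- function(x, pCutoff = 1e-4) {
  stopifnot(inherits(x, "CountMatrix"))
  E <- length(x$datasetNames)
  nbins <- sum(nBins(x$assembly))
  totalSignal <- colSums(do.call(rbind, x$counts))
  totalControl <- if (is.null(x$control)) rep(NA_real_, E) else
    colSums(do.call(rbind, x$control))
  zero <- totalSignal == 0
  if (any(zero))
    warning("dataset(s) with zero total reads called all-absent: ",
            paste(x$datasetNames[zero], collapse = ", "))
  tracks <- lapply(names(x$counts), function(chrom) {
    m <- x$counts[[chrom]]
    out <- matrix(0L, nrow(m), E)
    for (e in seq_len(E)) {
      if (zero[e]) next
      uniform <- totalSignal[e] / nbins
      if (!is.null(x$control) && !is.na(totalControl[e]) && totalControl[e] > 0) {
        lam <- pmax(x$control[[chrom]][, e] * (totalSignal[e] / totalControl[e]),
                    uniform)
      } else {
        lam <- rep(uniform, nrow(m))
      }
      thr <- vapply(unique(lam), poissonThreshold, integer(1), pCutoff = pCutoff)
      names(thr) <- format(unique(lam), digits = 17)
      out[, e] <- as.integer(m[, e] >= thr[format(lam, digits = 17)])
    }
    out
  })
  names(tracks) <- names(x$counts)
  BinaryTrackMatrix(x$assembly, x$datasetNames, tracks)
}

#' Read a 4-column experiment table
#'
#' The tab-delimited experiment table has columns: genome label, experiment
#' name (\code{celltype_mark_accession}), signal count file, and control
#' count file (empty for assays binarized against the uniform background,
#' such as DNase- or ATAC-seq).
#'
#' @param path experiment table file (no header).
#' @return A \code{data.frame} with columns \code{genome}, \code{dataset},
#'   \code{signal}, \code{control} (\code{NA} when blank).
#' @export
readCellMarkTable <- function(path) {
  lines <- .readAllLines(path)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(toks) < 3L))
    stop("experiment table needs at least 3 tab-delimited columns")
  get <- function(i) vapply(toks, function(t) if (length(t) >= i) t[[i]] else "",
                            character(1))
  ctrl <- get(4L)
  data.frame(genome = get(1L), dataset = get(2L), signal = get(3L),
             control = ifelse(nzchar(ctrl), ctrl, NA_character_),
             stringsAsFactors = FALSE)
}

#' Read/write a per-bin count track
#'
#' Two-column tab-delimited format with a header: \code{chrom} and
#' \code{count}, one row per bin, bins in chromosome order. Used as the
#' signal/control inputs of the binarization step.
#'
#' @param path count track file.
#' @param assembly the \linkS4class{GenomeAssembly}; bin counts per
#'   chromosome must match.
#' @return Named list of per-chromosome integer count vectors.
#' @export
readCountTrack <- function(path, assembly) {
  con <- .readConn(path)
  on.exit(close(con))
  df <- read.table(con, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("chrom", "count") %in% names(df)))
    stop("count track needs 'chrom' and 'count' columns: ", path)
  if (any(df$count < 0)) stop("negative count in ", path)
  nb <- nBins(assembly)
  bad <- setdiff(unique(df$chrom), names(nb))
  if (length(bad)) stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  out <- split(as.integer(df$count), factor(df$chrom, levels = names(nb)))
  for (chrom in names(nb))
    if (length(out[[chrom]]) != nb[[chrom]])
      stop("bin count mismatch on ", chrom, " in ", path)
  out
}

#' @rdname readCountTrack
#' @param counts named list of per-chromosome count vectors.
#' @export
writeCountTrack <- function(counts, path) {
  df <- data.frame(chrom = rep(names(counts), lengths(counts)),
                   count = unlist(counts, use.names = FALSE))
  con <- .writeConn(path)
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
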
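#' Read per-chromosome binarized signal files
#'
#' Parses the two-header-line binarized text dialect used by ChromHMM-style
#' workflows: line 1 is \code{genome<TAB>chromosome}, line 2 the tab-separated
#' dataset names, and every following line one genomic bin with values
#' \code{0} (absent), \code{1} (present) or \code{2} (missing). Gzip input is
#' handled transparently.
#'
#' @param paths character vector of per-chromosome files.
#' @param binSize bin width in bp used to reconstruct the assembly when
#'   \code{assembly} is not given.
#' @param assembly optional \linkS4class{GenomeAssembly}; when supplied, the
#'   files must cover exactly its chromosomes with matching bin counts.
#' @return A \linkS4class{BinaryTrackMatrix}.
#' @examples
#' asm <- GenomeAssembly("toy", c(chr1 = 1000))
#' btm <- BinaryTrackMatrix(asm, c("a", "b"),
#'   list(chr1 = matrix(0L, nrow = 5, ncol = 2)))
#' dir <- tempfile(); dir.create(dir)
#' readBinarized(writeBinarized(btm, dir))
#' @export
readBinarized <- function(paths, binSize = 200, assembly = NULL) {
  if (length(paths) == 0L) stop("no binarized files given")
  genome <- NULL
  datasets <- NULL
  tracks <- list()
  for (path in paths) {
    lines <- .readAllLines(path)
    if (length(lines) < 2L) stop("malformed binarized file (needs 2 header lines): ", path)
    hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    if (length(hdr) != 2L)
      stop("malformed header (expected genome<TAB>chromosome): ", path)
    ds <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
    if (is.null(datasets)) {
      genome <- hdr[[1L]]
      datasets <- ds
      if (anyDuplicated(datasets)) stop("duplicated dataset names in ", path)
    } else if (!identical(ds, datasets)) {
      stop("dataset header of '", path, "' differs from the first file")
    }
    chrom <- hdr[[2L]]
    if (chrom %in% names(tracks)) stop("chromosome '", chrom, "' appears twice")
    body <- lines[-(1:2)]
    if (length(body) == 0L) stop("no data lines in ", path)
    toks <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(toks) != length(datasets)))
      stop("row with wrong number of columns in ", path)
    flat <- unlist(toks, use.names = FALSE)
    if (!all(flat %in% c("0", "1", "2")))
      stop("value outside {0,1,2} in ", path)
    m <- matrix(as.integer(flat), nrow = length(body),
                ncol = length(datasets), byrow = TRUE)
    m[m == 2L] <- NA_integer_
    tracks[[chrom]] <- m
  }
  if (is.null(assembly)) {
    sizes <- vapply(tracks, nrow, integer(1)) * binSize
    assembly <- GenomeAssembly(genome, sizes, binSize)
  } else {
    want <- nBins(assembly)
    if (!identical(sort(names(tracks)), sort(names(want))))
      stop("files do not cover the assembly's chromosomes")
    for (chrom in names(tracks))
      if (nrow(tracks[[chrom]]) != want[[chrom]])
        stop("bin count mismatch on ", chrom)
  }
  BinaryTrackMatrix(assembly, datasets, tracks[names(chromSizes(assembly))])
}

#' Write a binary track matrix in the binarized text dialect
#'
#' Inverse of \code{\link{readBinarized}}; missing values are serialized as
#' \code{2}. One file per chromosome, named
#' \code{<assembly>_<chrom>_binary.txt[.gz]}.
#'
#' @param x a \linkS4class{BinaryTrackMatrix}.
#' @param dir output directory (created if needed).
#' @param gzip compress output files.
#' @return Invisibly, the written paths.
#' @export
writeBinarized <- function(x, dir, gzip = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  asm <- assembly(x)
  paths <- character(0)
  for (chrom in names(chromSizes(asm))) {
    m <- binTracks(x)[[chrom]]
    m[is.na(m)] <- 2L
    path <- file.path(dir, sprintf("%s_%s_binary.txt%s", asm@name, chrom,
                                   if (gzip) ".gz" else ""))
    lines <- c(paste(asm@name, chrom, sep = "\t"),
               paste(datasetNames(x), collapse = "\t"),
               apply(m, 1L, paste, collapse = "\t"))
    .writeAllLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Column-bind single-dataset binary matrices in a stated order
#'
#' Emulates merging per-dataset binarization output into one observation
#' matrix: datasets are combined in the order given, never alphabetically.
#'
#' @param matrices list of \linkS4class{BinaryTrackMatrix} objects on the
#'   same assembly.
#' @return A combined \linkS4class{BinaryTrackMatrix}.
#' @export
mergeBinary <- function(matrices) {
  if (length(matrices) == 0L) stop("nothing to merge")
  asm <- assembly(matrices[[1L]])
  for (m in matrices[-1L]) .checkAssemblyMatch(asm, assembly(m))
  datasets <- unlist(lapply(matrices, datasetNames))
  if (anyDuplicated(datasets)) stop("duplicated dataset names across inputs")
  tracks <- lapply(names(chromSizes(asm)), function(chrom) {
    do.call(cbind, lapply(matrices, function(m) binTracks(m)[[chrom]]))
  })
  names(tracks) <- names(chromSizes(asm))
  BinaryTrackMatrix(asm, datasets, tracks)
}
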
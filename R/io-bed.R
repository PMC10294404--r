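#' Write a segmentation as a dense BED file
#'
#' Consecutive bins sharing a state are merged into one interval; the final
#' interval of each chromosome is clipped to the chromosome length so the BED
#' stays within assembly bounds. Coordinates are 0-based half-open. Unassigned
#' (\code{NA}) bins are omitted.
#'
#' @param seg a \linkS4class{Segmentation}.
#' @param path output file (\code{.gz} for compressed output).
#' @param labelPrefix prefix for state labels, default \code{"E"} giving
#'   labels \code{E1..EK}.
#' @param labels optional character vector of length \code{nStates} of
#'   mnemonic aliases overriding \code{labelPrefix} (e.g. \code{"mGapArtf1"}).
#' @return Invisibly, \code{path}.
#' @export
writeSegmentationBed <- function(seg, path, labelPrefix = "E", labels = NULL) {
  asm <- assembly(seg)
  if (!is.null(labels) && length(labels) != nStates(seg))
    stop("'labels' must have one entry per state")
  lines <- character(0)
  for (chrom in names(chromSizes(asm))) {
    runs <- .stateRuns(stateSeqs(seg)[[chrom]], chromSizes(asm)[[chrom]],
                       binSize(asm))
    if (nrow(runs) == 0L) next
    lab <- if (is.null(labels)) paste0(labelPrefix, runs$state) else labels[runs$state]
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", chrom, as.integer(runs$start),
                              as.integer(runs$end), lab))
  }
  .writeAllLines(lines, path)
}

#' Read a dense segmentation BED back into per-bin state labels
#'
#' Inverse of \code{\link{writeSegmentationBed}}. Bins not covered by any
#' interval are left \code{NA}.
#'
#' @param path BED file with labels \code{<labelPrefix><k>} in column 4.
#' @param assembly the \linkS4class{GenomeAssembly} the BED refers to.
#' @param nStates number of states; defaults to the maximum label seen.
#' @param labelPrefix label prefix used at export time.
#' @return A \linkS4class{Segmentation}.
#' @export
readSegmentationBed <- function(path, assembly, nStates = NULL,
                                labelPrefix = "E") {
  lines <- .readAllLines(path)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(toks) < 4L)) stop("segmentation BED needs 4 columns: ", path)
  chrom <- vapply(toks, `[[`, character(1), 1L)
  start <- as.numeric(vapply(toks, `[[`, character(1), 2L))
  end <- as.numeric(vapply(toks, `[[`, character(1), 3L))
  lab <- vapply(toks, `[[`, character(1), 4L)
  if (anyNA(start) || anyNA(end) || any(end <= start))
    stop("malformed coordinates in ", path)
  bad <- setdiff(unique(chrom), names(chromSizes(assembly)))
  if (length(bad)) stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  state <- suppressWarnings(as.integer(sub(paste0("^", labelPrefix), "", lab)))
  if (anyNA(state)) stop("unparseable state label in ", path)
  if (is.null(nStates)) nStates <- max(state)
  bs <- binSize(assembly)
  states <- lapply(nBins(assembly), function(n) rep(NA_integer_, n))
  for (i in seq_along(chrom)) {
    b0 <- floor(start[i] / bs) + 1L
    b1 <- ceiling(end[i] / bs)
    states[[chrom[i]]][b0:b1] <- state[i]
  }
  Segmentation(assembly, nStates, states)
}

#' Read a BED file as a set of genomic intervals
#'
#' Standard BED3/BED6 parsing into a \code{GRanges}; intervals are kept as
#' given (overlaps are merged only by operations that require it). When an
#' assembly is supplied, intervals on unknown chromosomes are an error.
#'
#' @param path BED file (plain or gzip).
#' @param assembly optional \linkS4class{GenomeAssembly} for validation.
#' @param name annotation name stored in \code{metadata(x)$name}.
#' @return A \code{GRanges} (1-based closed internally, as is the Bioconductor
#'   convention; the on-disk format stays 0-based half-open).
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors metadata metadata<-
#' @export
readBedAnnotation <- function(path, assembly = NULL, name = basename(path)) {
  lines <- .readAllLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    toks <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(toks) < 3L)) stop("BED line with fewer than 3 columns: ", path)
    chrom <- vapply(toks, `[[`, character(1), 1L)
    start <- as.numeric(vapply(toks, `[[`, character(1), 2L))
    end <- as.numeric(vapply(toks, `[[`, character(1), 3L))
    if (anyNA(start) || anyNA(end)) stop("malformed coordinate in ", path)
    if (any(end <= start)) stop("interval with end <= start in ", path)
    strand <- rep("*", length(chrom))
    if (all(lengths(toks) >= 6L)) {
      s <- vapply(toks, `[[`, character(1), 6L)
      strand <- ifelse(s %in% c("+", "-"), s, "*")
    }
    if (!is.null(assembly)) {
      bad <- setdiff(unique(chrom), names(chromSizes(assembly)))
      if (length(bad))
        stop("interval(s) on chromosome(s) absent from the assembly: ",
             paste(bad, collapse = ", "))
    }
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end),
                                 strand = strand)
  }
  S4Vectors::metadata(gr)$name <- name
  gr
}

#' Write a set of intervals as BED
#'
#' @param gr a \code{GRanges}.
#' @param path output file; strand is written as BED6 when any interval is
#'   stranded.
#' @return Invisibly, \code{path}.
#' @importFrom GenomicRanges seqnames start end strand
#' @export
writeBedAnnotation <- function(gr, path) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  s <- GenomicRanges::start(gr) - 1L
  e <- GenomicRanges::end(gr)
  str <- as.character(GenomicRanges::strand(gr))
  lines <- if (any(str != "*")) {
    sprintf("%s\t%d\t%d\t.\t0\t%s", chrom, s, e, ifelse(str == "*", "+", str))
  } else {
    sprintf("%s\t%d\t%d", chrom, s, e)
  }
  .writeAllLines(lines, path)
}

#' Read a two-column chrom.sizes file into a genome assembly
#'
#' @param path tab-delimited file of chromosome name and length.
#' @param name assembly name.
#' @param binSize bin width in bp.
#' @return A \linkS4class{GenomeAssembly}.
#' @export
readChromSizes <- function(path, name = basename(path), binSize = 200) {
  toks <- strsplit(.readAllLines(path), "\t", fixed = TRUE)
  toks <- toks[lengths(toks) > 0L]
  if (any(lengths(toks) < 2L)) stop("chrom.sizes line with fewer than 2 fields")
  sizes <- as.numeric(vapply(toks, `[[`, character(1), 2L))
  if (anyNA(sizes) || any(sizes <= 0)) stop("malformed chromosome length in ", path)
  GenomeAssembly(name, setNames(sizes, vapply(toks, `[[`, character(1), 1L)),
                 binSize)
}

#' @rdname readChromSizes
#' @param assembly a \linkS4class{GenomeAssembly} to serialize.
#' @export
writeChromSizes <- function(assembly, path) {
  .writeAllLines(sprintf("%s\t%d", names(chromSizes(assembly)),
                         as.integer(chromSizes(assembly))), path)
}

#' Read a bedGraph-like score track into per-bin values
#'
#' Each interval's value is assigned to every bin it covers (later lines
#' overwrite earlier ones); bins never covered stay \code{NA}. Values are
#' checked against \code{bounds} when given, matching score tracks that
#' declare a range (e.g. conservation scores in [0,1]).
#'
#' @param path 4-column file: chrom, start, end, value (0-based half-open).
#' @param assembly the \linkS4class{GenomeAssembly}.
#' @param bounds optional length-2 numeric of allowed value range.
#' @return Named list of per-chromosome numeric vectors, one value per bin.
#' @export
readScoreTrack <- function(path, assembly, bounds = NULL) {
  toks <- strsplit(.readAllLines(path), "\t", fixed = TRUE)
  toks <- toks[lengths(toks) > 0L]
  if (any(lengths(toks) < 4L)) stop("score track line with fewer than 4 fields")
  chrom <- vapply(toks, `[[`, character(1), 1L)
  start <- as.numeric(vapply(toks, `[[`, character(1), 2L))
  end <- as.numeric(vapply(toks, `[[`, character(1), 3L))
  val <- as.numeric(vapply(toks, `[[`, character(1), 4L))
  if (anyNA(start) || anyNA(end) || anyNA(val) || any(end <= start))
    stop("malformed score track line in ", path)
  bad <- setdiff(unique(chrom), names(chromSizes(assembly)))
  if (length(bad)) stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  if (!is.null(bounds) && (any(val < bounds[1]) || any(val > bounds[2])))
    stop(sprintf("score outside declared bounds [%g, %g]", bounds[1], bounds[2]))
  bs <- binSize(assembly)
  scores <- lapply(nBins(assembly), function(n) rep(NA_real_, n))
  for (i in seq_along(chrom)) {
    b0 <- floor(start[i] / bs) + 1L
    b1 <- min(ceiling(end[i] / bs), nBins(assembly)[[chrom[i]]])
    scores[[chrom[i]]][b0:b1] <- val[i]
  }
  scores
}

#' @rdname readScoreTrack
#' @param scores named list of per-bin numeric vectors, as returned by
#'   \code{readScoreTrack}.
#' @export
writeScoreTrack <- function(scores, assembly, path) {
  bs <- binSize(assembly)
  lines <- character(0)
  for (chrom in names(scores)) {
    v <- scores[[chrom]]
    keep <- !is.na(v)
    idx <- which(keep)
    if (!length(idx)) next
    ends <- pmin(idx * bs, chromSizes(assembly)[[chrom]])
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", chrom,
                              as.integer((idx - 1L) * bs), as.integer(ends),
                              format(v[idx], digits = 15, trim = TRUE,
                                     scientific = FALSE)))
  }
  .writeAllLines(lines, path)
}

#' Read a tab-delimited gene table
#'
#' Columns: \code{gene_id}, \code{chrom}, \code{strand} (+/-), \code{tss},
#' \code{tes}, \code{exon_starts}, \code{exon_ends} (comma-separated,
#' 0-based half-open), \code{length} (bp). TSS/TES are strand-oriented: on
#' the minus strand the TSS is the larger coordinate.
#'
#' @param path gene table file with a header line.
#' @param assembly optional assembly for chromosome validation.
#' @return A \code{data.frame} with one row per gene.
#' @export
readGeneTable <- function(path, assembly = NULL) {
  con <- .readConn(path)
  on.exit(close(con))
  df <- read.table(con, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "tes", "exon_starts",
            "exon_ends", "length")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(df$length <= 0)) stop("gene length must be positive")
  if (!is.null(assembly)) {
    bad <- setdiff(unique(df$chrom), names(chromSizes(assembly)))
    if (length(bad)) stop("gene(s) on unknown chromosome(s): ",
                          paste(bad, collapse = ", "))
  }
  df
}

#' @rdname readGeneTable
#' @param genes gene table \code{data.frame}.
#' @export
writeGeneTable <- function(genes, path) {
  con <- .writeConn(path)
  on.exit(close(con))
  write.table(genes, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a tab-delimited expression table
#'
#' First column \code{gene_id}; remaining columns one replicate dataset each,
#' holding FPKM values (transform with \code{\link{transformExpression}}
#' before state averaging).
#'
#' @param path expression table file with a header line.
#' @return A \code{data.frame}.
#' @export
readExpressionTable <- function(path) {
  con <- .readConn(path)
  on.exit(close(con))
  df <- read.table(con, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id") stop("first column must be 'gene_id'")
  if (ncol(df) < 2L) stop("expression table needs at least one dataset column")
  df
}

#' @rdname readExpressionTable
#' @param expr expression table \code{data.frame}.
#' @export
writeExpressionTable <- function(expr, path) {
  con <- .writeConn(path)
  on.exit(close(con))
  write.table(expr, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a segment-mapping table
#'
#' Emulates per-segment coordinate-conversion (liftOver-style) output: one
#' row per mapped source segment with columns \code{src_chrom},
#' \code{src_start}, \code{src_end}, \code{dst_chrom}, \code{dst_start},
#' \code{dst_end} (0-based half-open). Unmapped source segments simply have
#' no row.
#'
#' @param path mapping file with a header line.
#' @return A \code{data.frame}.
#' @export
readSegmentMapping <- function(path) {
  con <- .readConn(path)
  on.exit(close(con))
  df <- read.table(con, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("src_chrom", "src_start", "src_end", "dst_chrom", "dst_start",
            "dst_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mapping missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$src_end <= df$src_start) || any(df$dst_end <= df$dst_start))
    stop("mapping interval with end <= start")
  df
}

#' @rdname readSegmentMapping
#' @param mapping mapping \code{data.frame}.
#' @export
writeSegmentMapping <- function(mapping, path) {
  con <- .writeConn(path)
  on.exit(close(con))
  write.table(mapping, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
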
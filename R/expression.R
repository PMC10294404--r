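# Gene-length-normalized average expression per state, replicate/tissue
# averaging, and carrying a segmentation across genomes through a
# per-segment mapping with the multi-mapping exclusion rule.

#' Expression transform
#'
#' \code{log2(FPKM + 1)}, the standard variance-stabilizing transform applied
#' before state averaging.
#'
#' @param fpkm non-negative expression value(s).
#' @return Transformed value(s).
#' @export
transformExpression <- function(fpkm) {
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  log2(fpkm + 1)
}

# Bin range (1-based) covered by a 0-based half-open bp interval.
.binsOf <- function(start, end, bs, nb) {
  b0 <- floor(start / bs) + 1L
  b1 <- min(ceiling(end / bs), nb)
  if (b0 > b1) integer(0) else b0:b1
}

#' Gene-length-normalized average expression per state
#'
#' For state \code{s} with bin set \eqn{B_s} and \eqn{G_i} the genes whose
#' bodies overlap bin \code{i},
#' \deqn{avg_s = \frac{\sum_{i \in B_s} \sum_{g \in G_i} E_g / L_g}
#'                    {\sum_{i \in B_s} \sum_{g \in G_i} 1 / L_g}}
#' where \eqn{E_g} is the (transformed) expression and \eqn{L_g} the gene
#' length in bp. A gene contributes once per overlapping segment, exactly as
#' the double sum is written; any overlap of a gene body with a bin counts.
#' States whose denominator is empty are \code{NA}.
#'
#' @param seg a \linkS4class{Segmentation}.
#' @param genes gene table \code{data.frame} (see
#'   \code{\link{readGeneTable}}); the full gene body (TSS to TES including
#'   introns) defines overlap.
#' @param expression named numeric vector of per-gene expression values
#'   (already transformed), named by \code{gene_id}.
#' @return Numeric vector with one average per state.
#' @export
stateAvgExpression <- function(seg, genes, expression) {
  asm <- assembly(seg)
  bs <- binSize(asm)
  K <- nStates(seg)
  miss <- setdiff(genes$gene_id, names(expression))
  if (length(miss)) stop("expression missing for gene(s): ",
                         paste(head(miss, 3), collapse = ", "))
  num <- den <- numeric(K)
  nb <- nBins(asm)
  for (gi in seq_len(nrow(genes))) {
    chrom <- genes$chrom[gi]
    if (!chrom %in% names(nb)) stop("gene on unknown chromosome: ", chrom)
    lo <- min(genes$tss[gi], genes$tes[gi])
    hi <- max(genes$tss[gi], genes$tes[gi])
    bins <- .binsOf(lo, hi, bs, nb[[chrom]])
    s <- stateSeqs(seg)[[chrom]][bins]
    s <- s[!is.na(s)]
    if (!length(s)) next
    L <- genes$length[gi]
    Eg <- expression[[genes$gene_id[gi]]]
    cnt <- tabulate(s, nbins = K)
    num <- num + cnt * (Eg / L)
    den <- den + cnt * (1 / L)
  }
  setNames(ifelse(den > 0, num / den, NA_real_), paste0("E", seq_len(K)))
}

#' Per-state average expression across many datasets
#'
#' Applies \code{\link{stateAvgExpression}} to every dataset column of an
#' expression table (transforming FPKM first).
#'
#' @param seg a \linkS4class{Segmentation}.
#' @param genes gene table.
#' @param expr expression table (\code{gene_id} plus FPKM columns).
#' @return States x datasets numeric matrix.
#' @export
stateExpressionMatrix <- function(seg, genes, expr) {
  datasets <- setdiff(names(expr), "gene_id")
  out <- vapply(datasets, function(d) {
    stateAvgExpression(seg, genes,
                       setNames(transformExpression(expr[[d]]), expr$gene_id))
  }, numeric(nStates(seg)))
  out
}

#' Average replicate columns into tissue columns
#'
#' Arithmetic mean of the replicate datasets of each tissue. A state value
#' missing in one replicate falls back to the other replicate with a
#' warning; missing in all replicates stays \code{NA}.
#'
#' @param mat states x datasets matrix (e.g. from
#'   \code{\link{stateExpressionMatrix}}).
#' @param tissueOf named character vector mapping dataset column name to
#'   tissue.
#' @return States x tissues matrix.
#' @export
replicateTissueAverage <- function(mat, tissueOf) {
  miss <- setdiff(colnames(mat), names(tissueOf))
  if (length(miss)) stop("no tissue assignment for: ",
                         paste(miss, collapse = ", "))
  tissues <- unname(unique(tissueOf[colnames(mat)]))
  out <- sapply(tissues, function(tt) {
    cols <- colnames(mat)[tissueOf[colnames(mat)] == tt]
    sub <- mat[, cols, drop = FALSE]
    partial <- rowSums(is.na(sub)) > 0 & rowSums(!is.na(sub)) > 0
    if (any(partial))
      warning(sprintf("tissue '%s': %d state value(s) present in only one replicate",
                      tt, sum(partial)))
    rowMeans(sub, na.rm = TRUE)
  })
  out <- matrix(out, nrow = nrow(mat),
                dimnames = list(rownames(mat), tissues))
  out[is.nan(out)] <- NA_real_
  out
}

#' Carry a segmentation to another assembly through a segment mapping
#'
#' Every source segment (one bin) is mapped independently through the
#' mapping table; destination bins that receive two or more distinct source
#' segments are excluded entirely (the multi-mapping filter), and source
#' segments without a mapping row are dropped. Destination bins never
#' covered remain unassigned (\code{NA}).
#'
#' @param seg source \linkS4class{Segmentation}.
#' @param mapping mapping \code{data.frame} (see
#'   \code{\link{readSegmentMapping}}).
#' @param assemblyDst destination \linkS4class{GenomeAssembly}.
#' @return A partial \linkS4class{Segmentation} on \code{assemblyDst}; the
#'   number of excluded (collided) destination bins is in
#'   \code{attr(, "excludedBins")}.
#' @export
applySegmentMapping <- function(seg, mapping, assemblyDst) {
  asmSrc <- assembly(seg)
  bs <- binSize(asmSrc)
  if (binSize(assemblyDst) != bs) stop("assemblies must share the bin size")
  nbSrc <- nBins(asmSrc)
  nbDst <- nBins(assemblyDst)
  hits <- lapply(nbDst, function(n) integer(n))     # source segments per dst bin
  stateAt <- lapply(nbDst, function(n) rep(NA_integer_, n))
  for (i in seq_len(nrow(mapping))) {
    sc <- mapping$src_chrom[i]
    dc <- mapping$dst_chrom[i]
    if (!sc %in% names(nbSrc)) stop("mapping source chromosome unknown: ", sc)
    if (!dc %in% names(nbDst)) stop("mapping destination chromosome unknown: ", dc)
    srcBin <- floor(mapping$src_start[i] / bs) + 1L
    st <- stateSeqs(seg)[[sc]][srcBin]
    dBins <- .binsOf(mapping$dst_start[i], mapping$dst_end[i], bs, nbDst[[dc]])
    hits[[dc]][dBins] <- hits[[dc]][dBins] + 1L
    stateAt[[dc]][dBins] <- st
  }
  excluded <- 0L
  for (dc in names(nbDst)) {
    coll <- hits[[dc]] >= 2L
    excluded <- excluded + sum(coll)
    stateAt[[dc]][coll] <- NA_integer_
  }
  out <- Segmentation(assemblyDst, nStates(seg), stateAt)
  attr(out, "excludedBins") <- excluded
  out
}
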
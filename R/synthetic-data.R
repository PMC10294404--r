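# Ground-truth simulation of every input the pipeline consumes: a stacked
# model with mark x cell-group block structure, binary tracks sampled from
# it, toy gene models with state-correlated expression, toy cross-genome
# segment mappings with controlled multi-mapping, score tracks with
# state-dependent means, and interval annotations planted at a configured
# fold enrichment. One user seed fans out to per-component child streams
# (see utils.R) so regenerating one fixture leaves the others untouched.

#' Generate a ground-truth stacked model with block structure
#'
#' States emit one chromatin mark either constitutively (across all cell
#' groups) or in a single cell group, emulating the block patterns of real
#' stacked-model emission heatmaps. The last state is a designated quiescent
#' state with all emission probabilities at most 0.05. All emissions lie in
#' [0.01, 0.99]; transition rows are self-biased and sum to 1.
#'
#' @param K number of states (>= 1); state \code{K} is quiescent.
#' @param marks character vector of chromatin-mark names.
#' @param cellGroups character vector of cell-type-group names.
#' @param seed integer seed; identical seeds give identical models.
#' @return A \linkS4class{StackedHMM} with \code{E = length(marks) *
#'   length(cellGroups)} datasets named \code{group_mark_ACCn}, plus
#'   per-dataset metadata in \code{attr(, "datasetMeta")}.
#' @export
genModel <- function(K, marks = c("H3K4me3", "H3K27ac", "H3K36me3", "H3K9me3"),
                     cellGroups = c("brain", "blood", "liver", "embryo", "immune"),
                     seed = 1) {
  stopifnot(K >= 1, length(marks) >= 1, length(cellGroups) >= 1)
  set.seed(childSeed(seed, "model"))
  E <- length(marks) * length(cellGroups)
  meta <- expand.grid(mark = marks, group = cellGroups,
                      stringsAsFactors = FALSE)[, c("mark", "group")]
  datasets <- sprintf("%s_%s_ACC%03d", meta$group, meta$mark, seq_len(E))

  emis <- matrix(runif(K * E, 0.01, 0.08), K, E)
  if (K > 1) {
    # distinct block profiles: each non-quiescent state gets a unique
    # (mark, scope) combination, scope being "constitutive" or one cell
    # group, so no two states share an emission pattern
    profiles <- expand.grid(mark = marks, scope = c("constitutive", cellGroups),
                            stringsAsFactors = FALSE)
    if (K - 1L > nrow(profiles))
      stop("K too large for the mark/group grid: at most ",
           nrow(profiles) + 1L, " states supported")
    profiles <- profiles[sample.int(nrow(profiles), K - 1L), , drop = FALSE]
    for (s in seq_len(K - 1L)) {
      cols <- if (profiles$scope[s] == "constitutive")
        which(meta$mark == profiles$mark[s])
      else which(meta$mark == profiles$mark[s] & meta$group == profiles$scope[s])
      emis[s, cols] <- runif(length(cols), 0.6, 0.95)
    }
  }
  emis[K, ] <- runif(E, 0.01, 0.05)  # quiescent
  emis <- pmin(pmax(emis, 0.01), 0.99)

  if (K == 1) {
    trans <- matrix(1, 1, 1)
    init <- 1
  } else {
    trans <- matrix(runif(K * K, 0.2, 1), K, K)
    diag(trans) <- 0
    trans <- trans / rowSums(trans)
    self <- runif(K, 0.85, 0.97)
    trans <- trans * (1 - self)
    diag(trans) <- self
  }
  init <- rep(1 / K, K)
  model <- StackedHMM(init, trans, emis, datasets)
  attr(model, "datasetMeta") <- data.frame(dataset = datasets, meta,
                                           stringsAsFactors = FALSE)
  model
}

#' Simulate binary tracks from a stacked model
#'
#' Samples a hidden state path per chromosome from the model's initial and
#' transition distributions, then each observation independently per dataset
#' from the state's Bernoulli emission, finally masking a fraction of entries
#' as missing.
#'
#' @param model a \linkS4class{StackedHMM}.
#' @param assembly target \linkS4class{GenomeAssembly}.
#' @param missingRate probability in [0, 1) that any single observation is
#'   masked missing.
#' @param seed integer seed.
#' @return List with \code{tracks} (\linkS4class{BinaryTrackMatrix}) and
#'   \code{truePath} (named list of per-chromosome state vectors).
#' @export
simulateTracks <- function(model, assembly, missingRate = 0, seed = 1) {
  stopifnot(missingRate >= 0, missingRate < 1)
  set.seed(childSeed(seed, "tracks"))
  K <- nStates(model)
  E <- length(datasetNames(model))
  cumInit <- cumsum(initialProbs(model))
  cumTrans <- t(apply(transitionProbs(model), 1L, cumsum))
  if (K == 1) cumTrans <- matrix(1, 1, 1)
  truePath <- list()
  tracks <- list()
  for (chrom in names(chromSizes(assembly))) {
    n <- nBins(assembly)[[chrom]]
    path <- cpp_sample_markov(cumInit, cumTrans, runif(n))
    obs <- matrix(as.integer(runif(n * E) <
                               emissionProbs(model)[path, , drop = FALSE]),
                  n, E)
    if (missingRate > 0)
      obs[runif(n * E) < missingRate] <- NA_integer_
    truePath[[chrom]] <- path
    tracks[[chrom]] <- obs
  }
  list(tracks = BinaryTrackMatrix(assembly, datasetNames(model), tracks),
       truePath = truePath)
}

#' Generate a toy gene table with state-correlated expression
#'
#' Places non-overlapping genes on the assembly, assigns strands, builds a
#' simple exon structure, and draws per-replicate expression around the
#' state-conditional mean at the gene's TSS bin. Means are specified on the
#' log2(FPKM+1) scale; the written expression values are FPKM, so that the
#' standard transform recovers the planted scale.
#'
#' @param assembly a \linkS4class{GenomeAssembly}.
#' @param nGenes number of genes to place (fewer if the genome fills up).
#' @param expressionByState numeric vector, one log2(FPKM+1) mean per state.
#' @param truePath named list of per-chromosome state vectors (ground truth).
#' @param tissues character vector of tissue names; each gets 2 replicates.
#' @param sdLog replicate noise SD on the log2 scale.
#' @param seed integer seed.
#' @return List with \code{genes} (gene table \code{data.frame}) and
#'   \code{expr} (expression \code{data.frame}, columns
#'   \code{<tissue>_rep1/2} of FPKM values).
#' @export
genGeneTable <- function(assembly, nGenes, expressionByState, truePath,
                         tissues = c("tissueA", "tissueB"), sdLog = 0.2,
                         seed = 1) {
  set.seed(childSeed(seed, "genes"))
  bs <- binSize(assembly)
  rows <- list()
  chroms <- names(chromSizes(assembly))
  # round-robin over chromosomes, walking left to right with random gaps
  cursor <- setNames(rep(0L, length(chroms)), chroms)
  gi <- 0L
  while (gi < nGenes) {
    placed <- FALSE
    for (chrom in chroms) {
      if (gi >= nGenes) break
      nb <- nBins(assembly)[[chrom]]
      gap <- sample(1:5, 1L)
      lenBins <- sample(3:15, 1L)
      startBin <- cursor[[chrom]] + gap
      if (startBin + lenBins > nb) next
      cursor[[chrom]] <- startBin + lenBins
      gi <- gi + 1L
      placed <- TRUE
      start <- startBin * bs            # 0-based bp
      end <- (startBin + lenBins) * bs
      strand <- sample(c("+", "-"), 1L)
      tss <- if (strand == "+") start else end
      tes <- if (strand == "+") end else start
      nEx <- sample(seq_len(min(3L, floor(lenBins / 2))), 1L)
      bounds <- sort(sample(seq(start, end, by = bs), 2L * nEx))
      exS <- bounds[seq(1L, 2L * nEx, by = 2L)]
      exE <- pmax(bounds[seq(2L, 2L * nEx, by = 2L)], exS + 50)
      tssBin <- min(floor(tss / bs) + 1L, nb)
      rows[[gi]] <- data.frame(
        gene_id = sprintf("g%05d", gi), chrom = chrom, strand = strand,
        tss = as.integer(tss), tes = as.integer(tes),
        exon_starts = paste(as.integer(exS), collapse = ","),
        exon_ends = paste(as.integer(exE), collapse = ","),
        length = as.integer(end - start),
        state = truePath[[chrom]][tssBin], stringsAsFactors = FALSE)
    }
    if (!placed) break  # genome full
  }
  genes <- do.call(rbind, rows)
  mu <- expressionByState[genes$state]
  expr <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (tissue in tissues)
    for (rep in 1:2) {
      x <- pmax(rnorm(nrow(genes), mu, sdLog), 0)
      expr[[sprintf("%s_rep%d", tissue, rep)]] <- 2^x - 1  # back to FPKM
    }
  genes$state <- NULL
  list(genes = genes, expr = expr)
}

#' Generate a toy cross-genome segment mapping
#'
#' Emulates per-segment coordinate-conversion output: every source bin maps
#' to at most one destination interval (a constant per-chromosome bin shift),
#' a configured fraction of source segments is dropped (unmapped), and a
#' configured fraction is redirected onto a destination bin already claimed
#' by another segment, so that those destination positions receive >= 2
#' source segments and exercise the downstream exclusion rule.
#'
#' @param assemblySrc,assemblyDst source and destination assemblies with the
#'   same chromosome names and bin size.
#' @param multimapRate fraction of mapped segments redirected onto an
#'   already-claimed destination bin.
#' @param dropRate fraction of source segments left unmapped.
#' @param shiftBins constant destination shift in bins.
#' @param seed integer seed.
#' @return Mapping \code{data.frame} (see \code{\link{readSegmentMapping}}).
#' @export
genMapping <- function(assemblySrc, assemblyDst, multimapRate = 0,
                       dropRate = 0, shiftBins = 0, seed = 1) {
  stopifnot(identical(names(chromSizes(assemblySrc)),
                      names(chromSizes(assemblyDst))),
            binSize(assemblySrc) == binSize(assemblyDst))
  set.seed(childSeed(seed, "mapping"))
  bs <- binSize(assemblySrc)
  parts <- list()
  for (chrom in names(chromSizes(assemblySrc))) {
    nSrc <- nBins(assemblySrc)[[chrom]]
    nDst <- nBins(assemblyDst)[[chrom]]
    srcBin <- seq_len(nSrc)
    dstBin <- srcBin + shiftBins
    keep <- dstBin >= 1L & dstBin <= nDst
    if (dropRate > 0) keep <- keep & runif(nSrc) >= dropRate
    srcBin <- srcBin[keep]
    dstBin <- dstBin[keep]
    if (multimapRate > 0 && length(srcBin) > 1L) {
      nRedir <- round(multimapRate * length(srcBin))
      if (nRedir > 0) {
        redir <- sample(seq_along(srcBin), nRedir)
        partner <- sample(setdiff(seq_along(srcBin), redir), nRedir,
                          replace = nRedir > length(srcBin) - nRedir)
        dstBin[redir] <- dstBin[partner]
      }
    }
    parts[[chrom]] <- data.frame(
      src_chrom = chrom, src_start = as.integer((srcBin - 1L) * bs),
      src_end = as.integer(srcBin * bs),
      dst_chrom = chrom, dst_start = as.integer((dstBin - 1L) * bs),
      dst_end = as.integer(dstBin * bs), stringsAsFactors = FALSE)
  }
  mapping <- do.call(rbind, parts)
  rownames(mapping) <- NULL
  mapping
}

#' Generate a per-bin score track with state-dependent means
#'
#' Emulates a conservation-style score in [0, 1]: each bin's value is drawn
#' around the mean configured for its true state and clipped to [0, 1].
#'
#' @param assembly a \linkS4class{GenomeAssembly}.
#' @param perStateMean numeric vector, one mean per state.
#' @param truePath named list of per-chromosome state vectors.
#' @param sdScore Gaussian noise SD before clipping.
#' @param seed integer seed.
#' @return Named list of per-chromosome per-bin score vectors.
#' @export
genScoreTrack <- function(assembly, perStateMean, truePath, sdScore = 0.05,
                          seed = 1) {
  set.seed(childSeed(seed, "scores"))
  scores <- lapply(names(chromSizes(assembly)), function(chrom) {
    mu <- perStateMean[truePath[[chrom]]]
    pmin(pmax(rnorm(length(mu), mu, sdScore), 0), 1)
  })
  names(scores) <- names(chromSizes(assembly))
  scores
}

#' Plant an annotation at a configured fold enrichment for one state
#'
#' Builds an interval set of single bins whose overlap with the chosen
#' state's territory is calibrated so the expected fold enrichment equals
#' \code{fold}: each annotation bin is drawn from the state's bins with
#' probability \code{fold * stateFraction} and from the complement otherwise
#' (rejection placement against the true path), giving an analytic expected
#' fold for enrichment tests.
#'
#' @param assembly a \linkS4class{GenomeAssembly}.
#' @param truePath named list of per-chromosome state vectors.
#' @param state state index the annotation is enriched in.
#' @param fold target expected fold enrichment (\code{fold * stateFraction}
#'   must be <= 1).
#' @param nIntervals number of annotation bins.
#' @param seed integer seed.
#' @return A \code{GRanges} of bin-sized intervals.
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @export
genPlantedAnnotation <- function(assembly, truePath, state, fold, nIntervals,
                                 seed = 1) {
  set.seed(childSeed(seed, "annotations") + state)
  bs <- binSize(assembly)
  bins <- do.call(rbind, lapply(names(truePath), function(chrom) {
    data.frame(chrom = chrom, bin = seq_along(truePath[[chrom]]),
               state = truePath[[chrom]], stringsAsFactors = FALSE)
  }))
  frac <- mean(bins$state == state)
  q <- fold * frac
  if (q > 1) stop(sprintf("fold %g infeasible: state fraction is %.3f", fold, frac))
  inState <- which(bins$state == state)
  outState <- which(bins$state != state)
  nIn <- rbinom(1L, nIntervals, q)
  nIn <- min(nIn, length(inState))
  nOut <- min(nIntervals - nIn, length(outState))
  pick <- c(sample(inState, nIn), sample(outState, nOut))
  sel <- bins[pick, ]
  GenomicRanges::GRanges(sel$chrom,
                         IRanges::IRanges(start = (sel$bin - 1L) * bs + 1L,
                                          end = sel$bin * bs))
}

#' Default synthetic-study configuration
#'
#' The study conditions used throughout the package's tests and examples:
#' a 10-Mb toy genome of 3 chromosomes (50,000 bins of 200 bp), 20 datasets
#' (4 marks x 5 cell groups), an 8-state ground-truth model with a quiescent
#' state, 1\% missing data, expression means rising with state index, and
#' one annotation planted at 5-fold for state 1.
#'
#' @param seed integer master seed.
#' @return Named list of generator settings.
#' @export
studyConfig <- function(seed = 1) {
  list(seed = seed,
       K = 8,
       marks = c("H3K4me3", "H3K27ac", "H3K36me3", "H3K9me3"),
       cellGroups = c("brain", "blood", "liver", "embryo", "immune"),
       chromSizes = c(chr1 = 4e6, chr2 = 3.5e6, chr3 = 2.5e6),
       binSize = 200,
       missingRate = 0.01,
       nGenes = 2000,
       expressionByState = NULL,   # default: seq(6, 1, length K-1), then 0.5
       scoreByState = NULL,        # default: seq(0.8, 0.2, length K-1), then 0.1
       planted = list(list(state = 1, fold = 5, n = 400)))
}

#' Generate a complete synthetic study with known ground truth
#'
#' Runs every generator under one master seed: the ground-truth model,
#' simulated binary tracks with the true state path, a gene table with
#' state-correlated expression, a cross-genome segment mapping, a
#' conservation-style score track, and planted annotations.
#'
#' @param config list as returned by \code{\link{studyConfig}}.
#' @return Named list: \code{assembly}, \code{model}, \code{tracks},
#'   \code{truePath}, \code{trueSegmentation}, \code{genes}, \code{expr},
#'   \code{mapping}, \code{scores}, \code{annotations} (named list of
#'   \code{GRanges} with the planted fold in \code{attr(, "plantedFold")}),
#'   and the resolved \code{config}.
#' @export
generateStudy <- function(config = studyConfig()) {
  cfg <- config
  asm <- GenomeAssembly("toy1", cfg$chromSizes, cfg$binSize)
  K <- cfg$K
  if (is.null(cfg$expressionByState))
    cfg$expressionByState <- c(seq(6, 1, length.out = K - 1), 0.5)
  if (is.null(cfg$scoreByState))
    cfg$scoreByState <- c(seq(0.8, 0.2, length.out = K - 1), 0.1)
  model <- genModel(K, cfg$marks, cfg$cellGroups, seed = cfg$seed)
  sim <- simulateTracks(model, asm, cfg$missingRate, seed = cfg$seed)
  genes <- genGeneTable(asm, cfg$nGenes, cfg$expressionByState, sim$truePath,
                        seed = cfg$seed)
  mapping <- genMapping(asm, asm, multimapRate = 0.05, dropRate = 0.05,
                        seed = cfg$seed)
  scores <- genScoreTrack(asm, cfg$scoreByState, sim$truePath, seed = cfg$seed)
  annotations <- list()
  stateFrac <- tabulate(unlist(sim$truePath), nbins = K) /
    sum(nBins(asm))
  for (pl in cfg$planted) {
    # clamp the requested fold to the feasible range (fold * fraction <= 1)
    # so the analytic expected fold stays exact for any generated path
    fold <- min(pl$fold, 0.95 / stateFrac[pl$state])
    gr <- genPlantedAnnotation(asm, sim$truePath, pl$state, fold, pl$n,
                               seed = cfg$seed)
    attr(gr, "plantedFold") <- fold
    attr(gr, "plantedState") <- pl$state
    annotations[[sprintf("planted_state%d", pl$state)]] <- gr
  }
  list(assembly = asm, model = model, tracks = sim$tracks,
       truePath = sim$truePath,
       trueSegmentation = Segmentation(asm, K, sim$truePath),
       genes = genes$genes, expr = genes$expr, mapping = mapping,
       scores = scores, annotations = annotations, config = cfg)
}
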
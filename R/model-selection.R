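# Model selection over the number of states: held-out likelihood on randomly
# sampled fixed-length regions, information criteria, and emission-profile
# comparison of a focal model against every alternative.

#' Sample non-overlapping fixed-length genomic regions
#'
#' Uniform sampling of bin-aligned, non-overlapping regions. Chromosomes
#' shorter than the region length are excluded with a warning. If the
#' requested number of regions cannot be packed into the genome, the error
#' reports the maximum feasible count.
#'
#' @param assembly a \linkS4class{GenomeAssembly}.
#' @param nRegions number of regions.
#' @param regionLength region length in bp (rounded up to whole bins).
#' @param seed integer seed.
#' @return \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open bp).
#' @export
sampleRegions <- function(assembly, nRegions, regionLength, seed = 1) {
  set.seed(childSeed(seed, "regions"))
  bs <- binSize(assembly)
  L <- as.integer(ceiling(regionLength / bs))  # region length in bins
  nb <- nBins(assembly)
  short <- names(nb)[nb < L]
  if (length(short)) {
    warning("chromosome(s) shorter than the region length excluded: ",
            paste(short, collapse = ", "))
    nb <- nb[nb >= L]
  }
  if (!length(nb)) stop("no chromosome can hold a region of the requested length")
  capacity <- floor(nb / L)
  if (nRegions > sum(capacity))
    stop(sprintf("cannot place %d non-overlapping regions; maximum feasible is %d",
                 nRegions, sum(capacity)))
  # allocate regions to chromosomes proportionally to bin counts, respecting
  # per-chromosome packing capacity
  repeat {
    alloc <- tabulate(sample(seq_along(nb), nRegions, replace = TRUE,
                             prob = nb), nbins = length(nb))
    if (all(alloc <= capacity)) break
  }
  out <- list()
  for (i in seq_along(nb)) {
    c_i <- alloc[i]
    if (c_i == 0L) next
    # uniform non-overlapping placement via the gap construction
    slack <- nb[[i]] - c_i * L
    starts <- sort(sample.int(slack + 1L, c_i, replace = TRUE) - 1L) +
      (seq_len(c_i) - 1L) * L
    out[[names(nb)[i]]] <- data.frame(chrom = names(nb)[i],
                                      start = starts * bs,
                                      end = (starts + L) * bs,
                                      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Free-parameter count of a stacked model
#'
#' \code{K*E} emission parameters plus \code{K*(K-1)} free transition
#' parameters plus \code{K-1} free initial-distribution parameters.
#'
#' @param K number of states.
#' @param E number of datasets.
#' @return Integer parameter count.
#' @export
nModelParams <- function(K, E) as.integer(K * E + K * (K - 1) + (K - 1))

#' Negative log-likelihood, AIC and BIC
#'
#' \code{AIC = 2 p - 2 logLik}; \code{BIC = p ln(n) - 2 logLik} with \code{p}
#' the free-parameter count and \code{n} the number of observation bins.
#'
#' @param loglik model log-likelihood on the evaluation data.
#' @param K number of states.
#' @param E number of datasets.
#' @param nBins number of observation bins the likelihood covers.
#' @return Named list: \code{nParams}, \code{NLL}, \code{AIC}, \code{BIC}.
#' @export
informationCriteria <- function(loglik, K, E, nBins) {
  p <- nModelParams(K, E)
  list(nParams = p, NLL = -loglik, AIC = 2 * p - 2 * loglik,
       BIC = p * log(nBins) - 2 * loglik)
}

# Extract the observation sub-matrices covered by sampled regions, one
# independent sequence per region.
.regionObs <- function(obs, regions) {
  bs <- binSize(assembly(obs))
  lapply(seq_len(nrow(regions)), function(i) {
    b0 <- floor(regions$start[i] / bs) + 1L
    b1 <- ceiling(regions$end[i] / bs)
    binTracks(obs)[[regions$chrom[i]]][b0:b1, , drop = FALSE]
  })
}

#' Evaluate a model's log-likelihood on sampled regions
#'
#' @param model a \linkS4class{StackedHMM}.
#' @param obs a \linkS4class{BinaryTrackMatrix}.
#' @param regions region \code{data.frame} from \code{\link{sampleRegions}};
#'   each region is scored as an independent sequence.
#' @return Total log-likelihood over the regions.
#' @export
regionLogLikelihood <- function(model, obs, regions) {
  .checkObsModel(model, obs)
  sum(vapply(.regionObs(obs, regions), function(m) {
    lb <- .logEmis(.obsParts(m), emissionProbs(model))
    cpp_loglik(lb, initialProbs(model), transitionProbs(model))
  }, numeric(1)))
}

#' Train and score models across a range of state counts
#'
#' Trains one model per entry of \code{kList} on the full observation matrix,
#' evaluates NLL/AIC/BIC on the sampled regions only (the model is not
#' retrained per region set), and compares the focal model's emission
#' profiles against every alternative via \code{\link{compareEmissions}}.
#'
#' @param obs a \linkS4class{BinaryTrackMatrix}.
#' @param kList integer vector of state counts to sweep.
#' @param cfg a \code{\link{trainConfig}} template; its \code{K} is replaced
#'   per sweep entry.
#' @param regions evaluation regions; default 30 regions of 100 kb.
#' @param focalK state count of the focal model (default the largest in
#'   \code{kList}).
#' @return List with \code{report} (one row per K: K, nParams, NLL, AIC,
#'   BIC), \code{regions}, \code{models}, and \code{comparison} (per K, the
#'   minimum over focal states of the maximum emission correlation).
#' @export
stateSweep <- function(obs, kList, cfg, regions = NULL, focalK = max(kList)) {
  if (is.null(regions))
    regions <- sampleRegions(assembly(obs), 30, 1e5, seed = cfg$seed)
  nRegionBins <- sum(ceiling(regions$end / binSize(assembly(obs))) -
                       floor(regions$start / binSize(assembly(obs))))
  E <- length(datasetNames(obs))
  models <- list()
  rows <- list()
  for (K in kList) {
    cfgK <- cfg
    cfgK$K <- as.integer(K)
    fit <- baumWelch(obs, cfgK)
    models[[as.character(K)]] <- fit$model
    ll <- regionLogLikelihood(fit$model, obs, regions)
    ic <- informationCriteria(ll, K, E, nRegionBins)
    rows[[as.character(K)]] <- data.frame(K = K, nParams = ic$nParams,
                                          NLL = ic$NLL, AIC = ic$AIC,
                                          BIC = ic$BIC)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  focal <- models[[as.character(focalK)]]
  comparison <- do.call(rbind, lapply(kList, function(K) {
    mx <- compareEmissions(focal, models[[as.character(K)]])
    data.frame(K = K, minMaxCorrelation = min(mx, na.rm = TRUE))
  }))
  list(report = report, regions = regions, models = models,
       comparison = comparison)
}
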
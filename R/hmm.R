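# Stacked HMM core: likelihood, inference, EM training, decoding, and model
# comparison. The numerical scheme is a scaled forward/backward recursion
# (src/hmm.cpp); its contract is agreement with exhaustive path enumeration,
# exercised in the test suite on small instances.

#' Training configuration for the stacked model
#'
#' Bundles the knobs of \code{\link{baumWelch}}. Defaults follow the
#' conventions of ChromHMM-style stacked training: no likelihood-delta early
#' stop (\code{convergenceDelta = NA}), a fixed iteration budget, smoothing
#' pseudocounts on every multinomial/Bernoulli update, training on
#' fixed-length row chunks treated as independent sequences, and multiple
#' random restarts keeping the best final likelihood.
#'
#' @param K number of states.
#' @param maxIterations EM iteration budget per restart.
#' @param convergenceDelta relative log-likelihood change below which EM
#'   stops early; \code{NA} (or any value < 0) disables early stopping.
#' @param pseudocount smoothing mass added to every count in the M-step
#'   (must be > 0 so emissions stay strictly inside (0,1)).
#' @param chunkLength training-sequence chunk length in bins; each chunk is
#'   an independent sequence sharing the initial distribution.
#' @param nRandomInits number of random restarts.
#' @param burnInIterations when set, every restart first runs only this many
#'   EM iterations and only the restart with the best burn-in likelihood is
#'   continued to the full budget (the screening strategy large
#'   initialization searches use); \code{NA} trains every restart fully.
#' @param seed integer seed controlling restart initializations.
#' @return A list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(K, maxIterations = 200, convergenceDelta = NA,
                        pseudocount = 0.02, chunkLength = 5000,
                        nRandomInits = 10, burnInIterations = NA, seed = 1) {
  stopifnot(K >= 1, maxIterations >= 1, pseudocount > 0, chunkLength >= 1,
            nRandomInits >= 1,
            is.na(burnInIterations) || burnInIterations >= 1)
  structure(list(K = as.integer(K), maxIterations = as.integer(maxIterations),
                 convergenceDelta = convergenceDelta,
                 pseudocount = pseudocount,
                 chunkLength = as.integer(chunkLength),
                 nRandomInits = as.integer(nRandomInits),
                 burnInIterations = as.integer(burnInIterations),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

.checkObsModel <- function(model, obs) {
  a <- datasetNames(model)
  b <- datasetNames(obs)
  if (!identical(a, b)) {
    i <- which(a != b[seq_along(a)])[1]
    if (is.na(i)) i <- min(length(a), length(b)) + 1L
    stop("dataset order mismatch at position ", i, ": model has '",
         a[min(i, length(a))], "'")
  }
  invisible(TRUE)
}

# Split every chromosome's matrix into chunks of at most chunkLength bins.
.obsChunks <- function(obs, chunkLength = Inf) {
  chunks <- list()
  for (chrom in names(binTracks(obs))) {
    m <- binTracks(obs)[[chrom]]
    n <- nrow(m)
    starts <- seq(1L, n, by = min(chunkLength, n))
    for (s in starts) {
      e <- min(s + chunkLength - 1L, n)
      chunks[[length(chunks) + 1L]] <- m[s:e, , drop = FALSE]
    }
  }
  chunks
}

# Decompose an observation matrix into the dense pieces the log-emission
# BLAS products need: O (present calls, missing as 0) and M0 (absent calls,
# missing as 0), both double.
.obsParts <- function(m) {
  O <- m
  O[is.na(O)] <- 0L
  M0 <- 1L - m
  M0[is.na(M0)] <- 0L
  storage.mode(O) <- "double"
  storage.mode(M0) <- "double"
  list(O = O, M0 = M0)
}

# Bins x states log emission-likelihood matrix under independent Bernoulli
# emissions; missing observations contribute 0 (a factor of 1).
.logEmis <- function(parts, emis) {
  parts$O %*% t(log(emis)) + parts$M0 %*% t(log1p(-emis))
}

#' Total log-likelihood of binary tracks under a stacked model
#'
#' Computed by the scaled forward recursion, one independent sequence per
#' chromosome; missing observations contribute a factor of 1
#' (marginalized out).
#'
#' @param model a \linkS4class{StackedHMM}.
#' @param obs a \linkS4class{BinaryTrackMatrix} with matching dataset order.
#' @return Total log-likelihood, with per-chromosome terms in
#'   \code{attr(, "perChrom")}.
#' @export
logLikelihood <- function(model, obs) {
  .checkObsModel(model, obs)
  per <- vapply(binTracks(obs), function(m) {
    lb <- .logEmis(.obsParts(m), emissionProbs(model))
    cpp_loglik(lb, initialProbs(model), transitionProbs(model))
  }, numeric(1))
  structure(sum(per), perChrom = per)
}

#' Posterior state probabilities per bin
#'
#' @inheritParams logLikelihood
#' @return Named list of per-chromosome bins x K posterior matrices; each row
#'   sums to 1.
#' @export
forwardBackward <- function(model, obs) {
  .checkObsModel(model, obs)
  lapply(binTracks(obs), function(m) {
    lb <- .logEmis(.obsParts(m), emissionProbs(model))
    cpp_forward_backward(lb, initialProbs(model), transitionProbs(model))$gamma
  })
}

# One random restart initialization: uniform initial distribution,
# self-biased transitions with small jitter, uniform random emissions.
.randomInit <- function(K, E) {
  emis <- matrix(runif(K * E, 0.05, 0.95), K, E)
  trans <- matrix(0.1 / max(K - 1, 1), K, K)
  diag(trans) <- if (K > 1) 0.9 else 1
  jitter <- matrix(runif(K * K, 0, 0.02), K, K)
  trans <- trans + jitter
  trans <- trans / rowSums(trans)
  list(initial = rep(1 / K, K), trans = trans, emis = emis)
}

#' Baum-Welch training of the stacked model
#'
#' Expectation-maximization with pseudocount-smoothed updates of the initial
#' distribution, transition matrix and Bernoulli emissions, run over
#' fixed-length chunks of the genome treated as independent sequences.
#' Among \code{nRandomInits} random restarts the model with the highest final
#' log-likelihood is returned.
#'
#' @param obs a \linkS4class{BinaryTrackMatrix}.
#' @param cfg a \code{\link{trainConfig}}.
#' @return List with \code{model} (\linkS4class{StackedHMM}), \code{trace}
#'   (per-iteration log-likelihood of the winning restart) and
#'   \code{restartLogLik} (final log-likelihood of every restart).
#' @export
baumWelch <- function(obs, cfg) {
  stopifnot(inherits(cfg, "TrainConfig"))
  chunks <- .obsChunks(obs, cfg$chunkLength)
  totalBins <- sum(vapply(chunks, nrow, integer(1)))
  K <- cfg$K
  E <- length(datasetNames(obs))
  if (K > totalBins) stop("more states than observation bins")
  p <- cfg$pseudocount

  parts <- lapply(chunks, .obsParts)

  runEM <- function(par, nIterations, delta) {
    trace <- numeric(0)
    for (iter in seq_len(nIterations)) {
      ll <- 0
      g1 <- numeric(K)
      xi <- matrix(0, K, K)
      en <- matrix(0, K, E)
      ed <- matrix(0, K, E)
      for (pt in parts) {
        lb <- .logEmis(pt, par$emis)
        fb <- cpp_forward_backward(lb, par$initial, par$trans)
        ll <- ll + fb$loglik
        g1 <- g1 + fb$gamma[1L, ]
        xi <- xi + fb$xi
        en <- en + crossprod(fb$gamma, pt$O)
        ed <- ed + crossprod(fb$gamma, pt$O + pt$M0)
      }
      trace <- c(trace, ll)
      par$initial <- (g1 + p) / (sum(g1) + K * p)
      par$trans <- (xi + p) / (rowSums(xi) + K * p)
      par$emis <- (en + p) / (ed + 2 * p)
      if (!is.na(delta) && delta >= 0 && iter > 1) {
        rel <- abs(trace[iter] - trace[iter - 1]) / abs(trace[iter - 1])
        if (rel < delta) break
      }
    }
    list(par = par, trace = trace)
  }

  burnIn <- if (is.na(cfg$burnInIterations)) cfg$maxIterations else
    min(cfg$burnInIterations, cfg$maxIterations)
  best <- NULL
  restartLL <- numeric(cfg$nRandomInits)
  for (r in seq_len(cfg$nRandomInits)) {
    set.seed((childSeed(cfg$seed, "train") + r) %% (2^31 - 1))
    fit <- runEM(.randomInit(K, E), burnIn,
                 if (burnIn == cfg$maxIterations) cfg$convergenceDelta else NA)
    restartLL[r] <- tail(fit$trace, 1)
    if (is.null(best) || restartLL[r] > tail(best$trace, 1)) best <- fit
  }
  if (burnIn < cfg$maxIterations) {
    # continue EM on the winning restart from its own parameters, so the
    # combined trace stays an uninterrupted EM trajectory
    more <- runEM(best$par, cfg$maxIterations - burnIn, cfg$convergenceDelta)
    best <- list(par = more$par, trace = c(best$trace, more$trace))
  }
  model <- StackedHMM(best$par$initial, best$par$trans, best$par$emis,
                      datasetNames(obs))
  list(model = model, trace = best$trace, restartLogLik = restartLL)
}

#' Genome-wide state assignment by posterior maximum or Viterbi path
#'
#' @inheritParams logLikelihood
#' @param mode \code{"posterior"} assigns each bin its maximum-posterior
#'   state; \code{"viterbi"} returns the jointly most probable path. Ties go
#'   to the lowest state index in both modes.
#' @return A \linkS4class{Segmentation}.
#' @export
segmentGenome <- function(model, obs, mode = c("posterior", "viterbi")) {
  mode <- match.arg(mode)
  .checkObsModel(model, obs)
  states <- lapply(binTracks(obs), function(m) {
    lb <- .logEmis(.obsParts(m), emissionProbs(model))
    if (mode == "viterbi") {
      cpp_viterbi(lb, initialProbs(model), transitionProbs(model))
    } else {
      g <- cpp_forward_backward(lb, initialProbs(model),
                                transitionProbs(model))$gamma
      max.col(g, ties.method = "first")
    }
  })
  Segmentation(assembly(obs), nStates(model), states)
}

#' Best emission-profile correlation of each state against another model
#'
#' For each state of \code{a}, the maximum Pearson correlation between its
#' length-E emission vector and any state of \code{b}. States with constant
#' emission vectors have undefined correlation and are reported \code{NA}
#' with a warning.
#'
#' @param a,b \linkS4class{StackedHMM} objects sharing the same dataset order.
#' @return Numeric vector, one maximum correlation per state of \code{a};
#'   the full cross-correlation matrix is in \code{attr(, "matrix")}.
#' @export
compareEmissions <- function(a, b) {
  if (!identical(datasetNames(a), datasetNames(b)))
    stop("models must share the same dataset order")
  ea <- emissionProbs(a)
  eb <- emissionProbs(b)
  cc <- matrix(NA_real_, nrow(ea), nrow(eb))
  for (i in seq_len(nrow(ea)))
    for (j in seq_len(nrow(eb)))
      cc[i, j] <- .safeCor(ea[i, ], eb[j, ])
  if (anyNA(cc))
    warning("state(s) with constant emission vector: correlation undefined")
  best <- apply(cc, 1L, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  structure(best, matrix = cc)
}

#' Match estimated states to reference states by emission correlation
#'
#' Finds the state relabeling of \code{est} that best aligns it with
#' \code{ref}: for K <= 8 the exact permutation maximizing the summed
#' Pearson correlation of emission vectors, greedy best-first matching
#' otherwise.
#'
#' @param est,ref \linkS4class{StackedHMM} objects with equal K and dataset
#'   order.
#' @return Integer vector \code{perm} with \code{perm[k]} = state of
#'   \code{est} matched to state \code{k} of \code{ref}.
#' @export
matchStates <- function(est, ref) {
  K <- nStates(ref)
  if (nStates(est) != K) stop("models must have the same number of states")
  cc <- t(attr(compareEmissions(ref, est), "matrix"))  # est x ref
  cc[is.na(cc)] <- -2
  if (K <= 8) {
    perms <- .permutations(K)
    scores <- vapply(seq_len(nrow(perms)), function(i) {
      sum(cc[cbind(perms[i, ], seq_len(K))])
    }, numeric(1))
    unname(perms[which.max(scores), ])
  } else {
    perm <- integer(K)
    used <- logical(K)
    for (k in order(apply(cc, 2L, max), decreasing = TRUE)) {
      j <- which.max(ifelse(used, -Inf, cc[, k]))
      perm[k] <- j
      used[j] <- TRUE
    }
    perm
  }
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Serialize / restore a stacked model as a tab-delimited text bundle
#'
#' One text file holding a JSON-style metadata header followed by the
#' initial distribution, transition matrix, emission matrix and dataset
#' names, each introduced by a section line.
#'
#' @param model a \linkS4class{StackedHMM}.
#' @param path output (input) file; \code{.gz} accepted.
#' @return \code{writeStackedHMM}: invisibly, \code{path};
#'   \code{readStackedHMM}: the restored model.
#' @export
writeStackedHMM <- function(model, path) {
  K <- nStates(model)
  E <- length(datasetNames(model))
  fmtRow <- function(x) paste(format(x, digits = 17, trim = TRUE,
                                     scientific = TRUE), collapse = "\t")
  lines <- c(sprintf("{\"format\": \"stacked-hmm\", \"K\": %d, \"E\": %d}", K, E),
             "#datasets", paste(datasetNames(model), collapse = "\t"),
             "#initial", fmtRow(initialProbs(model)),
             "#transitions",
             vapply(seq_len(K), function(i) fmtRow(transitionProbs(model)[i, ]),
                    character(1)),
             "#emissions",
             vapply(seq_len(K), function(i) fmtRow(emissionProbs(model)[i, ]),
                    character(1)))
  .writeAllLines(lines, path)
}

#' @rdname writeStackedHMM
#' @export
readStackedHMM <- function(path) {
  lines <- .readAllLines(path)
  meta <- lines[[1L]]
  K <- as.integer(sub('.*"K": *([0-9]+).*', "\\1", meta))
  E <- as.integer(sub('.*"E": *([0-9]+).*', "\\1", meta))
  if (is.na(K) || is.na(E)) stop("malformed model header: ", path)
  sec <- function(tag) which(lines == tag)[1]
  parseRow <- function(l) as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]])
  datasets <- strsplit(lines[sec("#datasets") + 1L], "\t", fixed = TRUE)[[1L]]
  init <- parseRow(lines[sec("#initial") + 1L])
  trans <- do.call(rbind, lapply(seq_len(K), function(i)
    parseRow(lines[sec("#transitions") + i])))
  emis <- do.call(rbind, lapply(seq_len(K), function(i)
    parseRow(lines[sec("#emissions") + i])))
  if (length(datasets) != E) stop("dataset count mismatch in ", path)
  StackedHMM(init, trans, emis, datasets)
}
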
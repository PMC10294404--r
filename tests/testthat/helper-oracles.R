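# Independent brute-force oracles. Everything here enumerates or counts
# directly and never calls the code paths it is used to check.

.allPaths <- function(K, T_) {
  # lexicographic order: earlier paths have lower state indices
  as.matrix(expand.grid(rep(list(seq_len(K)), T_)))[, T_:1, drop = FALSE]
}

# One exhaustive enumeration of all K^T hidden paths, returning the joint
# probability of each path with the observations (NA = missing), plus the
# quantities derived from it: total log-likelihood, per-bin posterior, and
# the maximum-probability path (ties toward the lexicographically smallest
# path, i.e. lowest state indices).
oracleEnumerate <- function(obs, init, trans, emis) {
  K <- length(init)
  T_ <- nrow(obs)
  paths <- .allPaths(K, T_)
  # per-bin per-state emission likelihood by direct product over datasets
  P <- matrix(1, T_, K)
  for (t in seq_len(T_))
    for (k in seq_len(K))
      for (e in seq_len(ncol(obs))) {
        o <- obs[t, e]
        if (is.na(o)) next
        P[t, k] <- P[t, k] * (if (o == 1) emis[k, e] else 1 - emis[k, e])
      }
  w <- init[paths[, 1]] * P[cbind(1L, paths[, 1])]
  if (T_ > 1)
    for (t in 2:T_)
      w <- w * trans[cbind(paths[, t - 1], paths[, t])] *
        P[cbind(t, paths[, t])]
  post <- matrix(0, T_, K)
  for (t in seq_len(T_)) {
    sums <- tapply(w, paths[, t], sum)
    post[t, as.integer(names(sums))] <- sums
  }
  post <- post / rowSums(post)
  list(loglik = log(sum(w)), posterior = post,
       viterbi = paths[which.max(w), ])
}

oracleLogLik <- function(obs, init, trans, emis)
  oracleEnumerate(obs, init, trans, emis)$loglik

oraclePosterior <- function(obs, init, trans, emis)
  oracleEnumerate(obs, init, trans, emis)$posterior

oracleViterbi <- function(obs, init, trans, emis)
  oracleEnumerate(obs, init, trans, emis)$viterbi

# Per-base fold enrichment: expand every bin of the segmentation and the
# annotation to base vectors and count.
oracleFoldEnrichment <- function(seg, annot) {
  asm <- assembly(seg)
  bs <- binSize(asm)
  K <- nStates(seg)
  inter <- numeric(K)
  stateBases <- numeric(K)
  annotBases <- 0
  total <- 0
  chromA <- as.character(GenomicRanges::seqnames(annot))
  for (chrom in names(chromSizes(asm))) {
    L <- chromSizes(asm)[[chrom]]
    total <- total + L
    states <- stateSeqs(seg)[[chrom]]
    stateOfBase <- states[pmin(floor(seq_len(L) - 1) %/% bs + 1, length(states))]
    mask <- logical(L)
    sel <- which(chromA == chrom)
    for (i in sel) {
      s <- max(GenomicRanges::start(annot)[i], 1)
      e <- min(GenomicRanges::end(annot)[i], L)
      if (s <= e) mask[s:e] <- TRUE
    }
    annotBases <- annotBases + sum(mask)
    for (k in seq_len(K)) {
      inState <- !is.na(stateOfBase) & stateOfBase == k
      stateBases[k] <- stateBases[k] + sum(inState)
      inter[k] <- inter[k] + sum(inState & mask)
    }
  }
  fold <- (inter / total) / ((stateBases / total) * (annotBases / total))
  list(fold = fold, inter = inter, stateBases = stateBases,
       annotBases = annotBases)
}

# Gene-length-normalized expression by a naive triple loop over states,
# bins, and genes.
oracleStateExpression <- function(seg, genes, expression) {
  asm <- assembly(seg)
  bs <- binSize(asm)
  K <- nStates(seg)
  out <- rep(NA_real_, K)
  for (s in seq_len(K)) {
    num <- 0
    den <- 0
    for (chrom in names(chromSizes(asm))) {
      states <- stateSeqs(seg)[[chrom]]
      for (i in seq_along(states)) {
        if (is.na(states[i]) || states[i] != s) next
        binStart <- (i - 1) * bs
        binEnd <- i * bs
        for (g in seq_len(nrow(genes))) {
          if (genes$chrom[g] != chrom) next
          lo <- min(genes$tss[g], genes$tes[g])
          hi <- max(genes$tss[g], genes$tes[g])
          if (lo < binEnd && hi > binStart) {
            num <- num + expression[[genes$gene_id[g]]] / genes$length[g]
            den <- den + 1 / genes$length[g]
          }
        }
      }
    }
    if (den > 0) out[s] <- num / den
  }
  out
}

# Destination bins hit by >= 2 distinct source segments in a mapping table.
oracleCollisionBins <- function(mapping, binSize) {
  key <- paste(mapping$dst_chrom, mapping$dst_start %/% binSize)
  sum(table(key) >= 2)
}
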
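# Small programmatic fixtures shared across test files.

tinyAssembly <- function(sizes = c(chr1 = 1000, chr2 = 800), binSize = 10)
  GenomeAssembly("tiny", sizes, binSize)

randomBinaryTracks <- function(assembly, E = 3, missingRate = 0, seed = 1) {
  set.seed(seed)
  tracks <- lapply(nBins(assembly), function(n) {
    m <- matrix(sample(0:1, n * E, replace = TRUE), n, E)
    if (missingRate > 0) m[runif(n * E) < missingRate] <- NA_integer_
    m
  })
  BinaryTrackMatrix(assembly, paste0("ct_mark_A", seq_len(E)), tracks)
}

randomSegmentation <- function(assembly, K = 4, seed = 1) {
  set.seed(seed)
  Segmentation(assembly, K,
               lapply(nBins(assembly), function(n)
                 sample.int(K, n, replace = TRUE)))
}

randomSmallHMM <- function(K, E, seed = 1) {
  set.seed(seed)
  init <- runif(K)
  init <- init / sum(init)
  trans <- matrix(runif(K * K, 0.05, 1), K, K)
  trans <- trans / rowSums(trans)
  emis <- matrix(runif(K * E, 0.05, 0.95), K, E)
  StackedHMM(init, trans, emis)
}

randomSmallObs <- function(T_, E, missingRate = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(0:1, T_ * E, replace = TRUE), T_, E)
  if (missingRate > 0) m[runif(T_ * E) < missingRate] <- NA_integer_
  m
}

# Wrap a bare observation matrix as a one-chromosome BinaryTrackMatrix
# matching a model's dataset names.
asTracks <- function(m, model, binSize = 200) {
  asm <- GenomeAssembly("tiny", c(chr1 = nrow(m) * binSize), binSize)
  BinaryTrackMatrix(asm, datasetNames(model), list(chr1 = m))
}
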
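# The stacked HMM core against closed forms and exhaustive path enumeration.

test_that("single-state log-likelihood equals the closed form", {
  model <- StackedHMM(1, matrix(1, 1, 1), matrix(c(0.3, 0.8), 1, 2),
                      c("d1", "d2"))
  m <- randomSmallObs(20, 2, seed = 1)
  obs <- asTracks(m, model)
  p <- emissionProbs(model)[1, ]
  closed <- sum(t(m) * log(p) + t(1 - m) * log(1 - p))
  expect_equal(as.numeric(logLikelihood(model, obs)), closed, tolerance = 1e-12)
  # posterior is trivially 1 and every bin is state 1
  expect_true(all(forwardBackward(model, obs)$chr1 == 1))
  expect_true(all(stateSeqs(segmentGenome(model, obs))$chr1 == 1L))
})

test_that("likelihood, posteriors and Viterbi agree with path enumeration", {
  set.seed(99)
  for (i in 1:40) {
    K <- sample(2:4, 1)
    T_ <- sample(2:6, 1)
    E <- sample(1:3, 1)
    model <- randomSmallHMM(K, E, seed = i)
    m <- randomSmallObs(T_, E, missingRate = 0.15, seed = i + 1000)
    obs <- asTracks(m, model)
    init <- initialProbs(model)
    trans <- transitionProbs(model)
    emis <- emissionProbs(model)

    oracle <- oracleEnumerate(m, init, trans, emis)
    expect_equal(as.numeric(logLikelihood(model, obs)), oracle$loglik,
                 tolerance = 1e-9)
    post <- forwardBackward(model, obs)$chr1
    expect_true(max(abs(post - oracle$posterior)) < 1e-9)
    expect_equal(rowSums(post), rep(1, T_), tolerance = 1e-9)
    vit <- stateSeqs(segmentGenome(model, obs, mode = "viterbi"))$chr1
    expect_identical(as.integer(vit), as.integer(oracle$viterbi))
  }
})

test_that("fully missing observations carry no likelihood and a flat posterior", {
  model <- randomSmallHMM(3, 2, seed = 5)
  m <- matrix(NA_integer_, 4, 2)
  obs <- asTracks(m, model)
  expect_equal(as.numeric(logLikelihood(model, obs)), 0, tolerance = 1e-12)
  post <- forwardBackward(model, obs)$chr1
  expect_equal(rowSums(post), rep(1, 4), tolerance = 1e-9)
})

test_that("a symmetric two-state model gives a symmetric posterior", {
  model <- StackedHMM(c(0.5, 0.5), matrix(0.5, 2, 2),
                      matrix(c(0.3, 0.7, 0.7, 0.3), 2, 2), c("d1", "d2"))
  # observation (1, 1) is equally likely under both states by symmetry
  obs <- asTracks(matrix(c(1L, 1L), 1, 2), model)
  expect_equal(forwardBackward(model, obs)$chr1[1, ], c(0.5, 0.5),
               tolerance = 1e-12)
})

test_that("EM at K = 1 lands on the empirical column means", {
  asm <- GenomeAssembly("toy", c(chr1 = 4e5), 200)  # 2000 bins
  set.seed(21)
  m <- matrix(as.integer(runif(2000 * 3) < rep(c(0.2, 0.5, 0.9), each = 2000)),
              2000, 3)
  obs <- BinaryTrackMatrix(asm, paste0("d", 1:3), list(chr1 = m))
  fit <- baumWelch(obs, trainConfig(K = 1, maxIterations = 5,
                                    nRandomInits = 1, seed = 1))
  expect_equal(as.numeric(emissionProbs(fit$model)), colMeans(m),
               tolerance = 1e-3)  # within the pseudocount effect
})

test_that("the EM log-likelihood trace is non-decreasing (relative 1e-6)", {
  asm <- GenomeAssembly("toy", c(chr1 = 1e6), 200)  # 5000 bins
  model <- genModel(3, marks = c("m1", "m2"), cellGroups = "g1", seed = 6)
  sim <- simulateTracks(model, asm, 0.05, seed = 6)
  fit <- baumWelch(sim$tracks, trainConfig(K = 3, maxIterations = 40,
                                           nRandomInits = 2, seed = 6))
  d <- diff(fit$trace)
  expect_true(all(d >= -1e-6 * abs(fit$trace[-length(fit$trace)])))
})

test_that("relabeling the generating states leaves matched parameters unchanged", {
  asm <- GenomeAssembly("toy", c(chr1 = 1e6), 200)
  truth <- genModel(4, marks = c("m1", "m2"), cellGroups = c("g1", "g2"),
                    seed = 7)
  sim <- simulateTracks(truth, asm, 0, seed = 7)
  fit <- baumWelch(sim$tracks, trainConfig(K = 4, maxIterations = 60,
                                           nRandomInits = 3, seed = 7))
  perm <- sample(4)
  shuffled <- StackedHMM(initialProbs(truth)[perm],
                         transitionProbs(truth)[perm, perm],
                         emissionProbs(truth)[perm, ], datasetNames(truth))
  mA <- matchStates(fit$model, truth)
  mB <- matchStates(fit$model, shuffled)
  expect_identical(mB, mA[perm])
  expect_equal(emissionProbs(fit$model)[mB, ],
               emissionProbs(fit$model)[mA, , drop = FALSE][perm, ])
})

test_that("training rejects more states than bins and mismatched columns", {
  asm <- GenomeAssembly("toy", c(chr1 = 600), 200)
  obs <- randomBinaryTracks(asm, E = 2, seed = 1)
  expect_error(baumWelch(obs, trainConfig(K = 10, nRandomInits = 1)),
               "more states than")
  model <- StackedHMM(c(1), matrix(1, 1, 1), matrix(0.5, 1, 2),
                      c("other_a", "other_b"))
  expect_error(logLikelihood(model, obs), "mismatch at position 1")
})

test_that("emission comparison finds exact self-matches and flags zero variance", {
  model <- genModel(5, seed = 8)
  expect_equal(as.numeric(compareEmissions(model, model)), rep(1, 5),
               tolerance = 1e-12)

  flat <- StackedHMM(c(0.5, 0.5), matrix(0.5, 2, 2),
                     matrix(c(0.5, 0.2, 0.5, 0.8), 2, 2), c("d1", "d2"))
  other <- StackedHMM(c(0.5, 0.5), matrix(0.5, 2, 2),
                      matrix(runif(4, 0.1, 0.9), 2, 2), c("d1", "d2"))
  expect_warning(res <- compareEmissions(flat, other), "constant emission")
  expect_true(is.na(res[1]))

  # maxima reproduced by a brute-force all-pairs scan
  a <- genModel(6, seed = 10)
  b <- genModel(3, seed = 11)
  res <- compareEmissions(a, b)
  brute <- vapply(seq_len(6), function(i)
    max(vapply(seq_len(3), function(j)
      cor(emissionProbs(a)[i, ], emissionProbs(b)[j, ]), numeric(1))),
    numeric(1))
  expect_equal(as.numeric(res), brute, tolerance = 1e-12)
})

test_that("posterior and Viterbi decoding agree on high-signal data", {
  asm <- GenomeAssembly("toy", c(chr1 = 2e5), 200)
  emis <- matrix(c(0.995, 0.005, 0.005, 0.995), 2, 2)
  model <- StackedHMM(c(0.5, 0.5),
                      matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2), emis,
                      c("d1", "d2"))
  sim <- simulateTracks(model, asm, 0, seed = 13)
  post <- segmentGenome(model, sim$tracks, mode = "posterior")
  vit <- segmentGenome(model, sim$tracks, mode = "viterbi")
  expect_gt(mean(stateSeqs(post)$chr1 == stateSeqs(vit)$chr1), 0.999)
})

test_that("model text bundles round-trip to full precision", {
  model <- genModel(4, seed = 14)
  p <- withr::local_tempfile(fileext = ".txt.gz")
  writeStackedHMM(model, p)
  back <- readStackedHMM(p)
  expect_equal(initialProbs(back), initialProbs(model), tolerance = 1e-15)
  expect_equal(transitionProbs(back), transitionProbs(model), tolerance = 1e-15)
  expect_equal(emissionProbs(back), emissionProbs(model), tolerance = 1e-15)
  expect_identical(datasetNames(back), datasetNames(model))
})
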